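# Material compositions: mass density (g/cm3) and elemental mass fractions.
# Gd denotes the 157 isotope (157 g/mol).
tissue:
  density_g_cm3: 1.1
  composition: {H: 0.10, O: 0.70, C: 0.20}
carbon:
  density_g_cm3: 2.2
  composition: {C: 1.0}
GdF4:
  density_g_cm3: 7.1
  composition: {Gd: 0.68, F: 0.32}
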