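# Reaction channels: plateau cross-sections (barns) above the kinematic
# threshold. Q-values of the two proton channels are standard nuclear-data
# constants. "Gd157"/"B10" absorption values are the quoted thermal-point
# capture cross-sections (1/v-scaled by the neutron model).
C12_p_3alpha:
  projectile: p
  target_nuclide: C12
  products: [alpha, alpha, alpha, p]
  sigma_barn: 0.400
  alpha_multiplicity: 3
  q_value_mev: -7.275
F19_p_alpha:
  projectile: p
  target_nuclide: F19
  products: [alpha, O16]
  sigma_barn: 0.500
  alpha_multiplicity: 1
  q_value_mev: 8.114
Gd157_n_gamma:
  projectile: n
  target_nuclide: Gd157
  products: [gamma, Gd158]
  sigma_barn: 250000
  alpha_multiplicity: 0
  q_value_mev: 7.937
B10_n_alpha:
  projectile: n
  target_nuclide: B10
  products: [alpha, Li7]
  sigma_barn: 4000
  alpha_multiplicity: 1
  q_value_mev: 2.790
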