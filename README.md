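# nanodosim

Proton therapy has two standing problems: its biological effectiveness is
only ~10% above that of gamma-ray therapy, and its secondary neutrons carry
a second-cancer risk. One proposed remedy places nanometre-scale targets of
carbon or gadolinium fluoride (GdF₄), doped with ¹⁵⁷Gd, inside the tumor:
protons striking the nano-target produce high-LET alpha particles through

- ¹²C(p, 3α)p (≈400 mb) and
- ¹⁹F(p, α)¹⁶O (≈500 mb),

which raise the local dose and DNA strand-break yield, while the enormous
thermal capture cross-section of ¹⁵⁷Gd(n, γ)¹⁵⁸Gd (≈250 000 b) removes the
slow secondary neutrons.

`nanodosim` is a desk-scale, fully tested R implementation of that
evaluation chain. It models a 50–60 MeV spread-out Bragg peak (SOBP)
covering a tumor at 2–3 cm depth, samples alpha production at a 50 nm
nano-target in front of a 0.5 µm tissue cube, and scores two
spectrum-weighted effectiveness metrics over the alpha fluence
`Φ(Eᵢ)` (particles per incident proton per 1 MeV bin):

```
Dose_tot (Gy/proton) = Σᵢ Φ(Eᵢ) · LET(Eᵢ) · 1.6×10⁻¹³
SSB_tot, DSB_tot     = Σᵢ Φ(Eᵢ) · SSB(Eᵢ),  Σᵢ Φ(Eᵢ) · DSB(Eᵢ)
```

with LET(E) and RBE(LET) from a tabulated 1–12 MeV lookup, and a
multigroup slowing-down model of neutron capture competition that compares
tumor and healthy-tissue fluences with and without 3000 ppm ¹⁵⁷Gd at a
70:1 tumor-to-healthy partition. Full-transport Monte Carlo outputs are
not reproducible at desk scale, so a calibrated synthetic-spectrum
generator (`spectrum_recipe()`, `calibrate_recipe()`) stands in for them:
its scale factors are solved deterministically so the no-target spectrum
reproduces the published per-proton dose and strand-break totals, and the
per-agent excesses are exactly-determined 3×3 linear solves.

## A worked example

```r
library(nanodosim)

report <- run_pipeline()
report$dose_table
#> # A tibble: 3 × 3
#>   agent dose_gy_per_proton enhancement_pct
#>   <chr>              <dbl>           <dbl>
#> 1 none       0.00000000700               0
#> 2 C          0.0000000150              114
#> 3 GdF4       0.0000000140              100

report$damage_table
#> # A tibble: 3 × 5
#>   agent ssb_per_proton ssb_enhancement_pct dsb_per_proton dsb_enhancement_pct
#>   <chr>          <dbl>               <dbl>          <dbl>               <dbl>
#> 1 none          21000.                   0          8800.                   0
#> 2 C             47000.                 124         19200.                 118
#> 3 GdF4          40000.                  90         17000.                  93

report$neutron_table
#> # A tibble: 2 × 5
#>   region  flux_without   flux_with reduction_pct factor
#>   <chr>          <dbl>       <dbl>         <dbl>  <dbl>
#> 1 healthy    0.0000004 0.000000158          60.4   2.53
#> 2 tumor      0.000002  0.000000164          91.8  12.2
```

Reading: one carbon nano-target roughly doubles the alpha dose per
incident proton (7×10⁻⁹ → 1.5×10⁻⁸ Gy/proton, +114% at nearest-integer
rounding; +110% at two significant figures) and raises single/double
strand breaks by 124%/118%; GdF₄ gives +100% dose. With 3000 ppm ¹⁵⁷Gd
the thermal-to-1 keV neutron fluence falls by a factor ≈12 inside the
tumor and ≈60% in the surrounding healthy tissue. Baseline (without-Gd)
fluences are calibration anchors; the with-Gd values are computed by the
capture model.

Lower-level stages are exposed directly and chain on tibbles:

```r
beam <- build_sobp(n_peaks = 11)                      # 0.7% flat over the target window
ps   <- in_tumor_proton_spectrum(beam, seed = 1)      # protons, bounded by 32 MeV
pair <- alpha_spectrum_pair(ps, nano_geometry(), seed = 1)
total_dose(pair$with)                                  # Eq-style fluence x LET sum
ggplot2::autoplot(pair$with)                           # step-histogram quick look
```

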