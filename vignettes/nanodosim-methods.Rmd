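---
title: "Models and methods behind nanodosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanodosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodosim)
```

`nanodosim` evaluates two claims about proton-targeted therapy with
carbon and ¹⁵⁷Gd-bearing nano-targets: (i) the secondary alpha particles
from ¹²C(p,3α)p and ¹⁹F(p,α)¹⁶O roughly double the local dose and DNA
strand-break yield per incident proton, and (ii) 3000 ppm of ¹⁵⁷Gd in the
tumor strongly suppresses the thermal-to-epithermal secondary-neutron
fluence. This vignette documents the models, their assumptions, every
tunable default, and what the tests do and do not demonstrate.

## The clinical beam

**Range–energy model.** Proton range in tissue follows the power law
$R = \alpha E^p$. We fix $p = 1.77$, the standard exponent for protons in
water in this energy regime, and calibrate $\alpha$ so that the 60 MeV
component of the beam retains exactly 32 MeV at the 2 cm proximal face of
the tumor — the upper endpoint of the in-tumor spectrum the downstream
stages assume. With that single anchor the 50 and 60 MeV Bragg positions
land at 2.16 cm and 2.98 cm, consistent with the nominal 2–3 cm treatment
window. We deliberately did *not* force the Bragg positions to exactly
2.0/3.0 cm: with a pure power law those two anchors imply $p = 2.22$ and a
36.6 MeV residual at 2 cm, which is inconsistent with the 32 MeV spectrum
endpoint; one of the three constraints must yield, and the spectrum
endpoint is the one the dose and damage integrals actually consume. Both
$\alpha$ and $p$ are overridable (`range_coefficients()`).

**Pristine peaks and straggling.** The depth dose of a mono-energetic
component is the bin-integrated energy deposition of the range model,
convolved with a Gaussian range-straggling kernel of width
$\sigma_R = p\,\sigma_E R$ where $\sigma_E$ is the fractional energy
straggling (default 0.02, configurable). No lateral spreading, nozzle or
patient geometry is modelled — only the in-tumor energy spectrum and the
depth-dose flatness matter downstream.

**SOBP weights.** `build_sobp()` places `n_peaks` (default 11) Bragg
positions across the intersection of the requested depth window with the
beam's reach and solves a non-negative least-squares problem
(`pracma::lsqnonneg`) for weights that flatten the summed curve. Flatness
(`max/min − 1`) is evaluated up to one straggling sigma short of the
distal edge, because the distal falloff is physics, not a weighting
artefact; the default beam achieves 0.7%, and construction fails if the
configured tolerance (default 5%) is exceeded.

**In-tumor spectrum.** Protons sample a component by weight and a depth
uniform in the tumor window; the residual range maps back to energy, with
Gaussian energy straggling applied and energies clamped to the
kinematic maximum (32 MeV). Protons whose range ends short of the sampled
depth are scored as stopped in the lowest bin. Spectra are histogrammed
in 1 MeV bins over 0–33 MeV, matching the LET table granularity.

## Alpha production at the nano-target

A 50 nm target cube (carbon or GdF₄) sits in front of a 0.5 µm tissue
cube. Thin-target interaction probabilities are $P = n\,\sigma(E)\,t$
with plateau cross-sections (400 mb, 500 mb) above the kinematic
threshold; for the carbon channel the threshold is
$-Q\,(m_p + m_C)/m_C \approx 7.89$ MeV, for fluorine ($Q > 0$) it is
zero. Because $P \sim 10^{-7}$, analogue sampling would need the
$10^8$-event scale of a full transport run; instead every sampled proton
is *forced* to interact and carries $P(E_p)$ as a statistical weight, so
fluences are per incident proton at any sample size. The without-target
spectrum is the tissue background alone — the same ¹²C(p,3α)p channel on
the tissue's 20% carbon over the 0.5 µm path; oxygen alpha channels are
omitted (no cross-section is part of the model's data) and the background
stream is seeded separately so adding a target never changes it.

**Kinematics.** The two-body channel uses exact non-relativistic CM
kinematics with an isotropic CM angle; product energies sum to
$E_p + Q$ by construction. The four-body (3α + p) final state samples
the uniform non-relativistic phase space by the Gaussian-projection
method: momenta drawn iid Gaussian with variance ∝ mass, the
centre-of-mass component projected out, then rescaled onto the energy
shell. This is exact sampling of the microcanonical measure; the tests
verify the per-alpha mean against the closed form
$\langle T_\alpha\rangle = E_{tot}(1 - m_\alpha/M)/(N-1)$.

Alphas leave the 50 nm film without loss (it is far thinner than their
range) and are binned in 1 MeV bins over 0–15 MeV.

**Known limitation.** The fluorine channel is sampled to the ¹⁶O ground
state only, which puts its alphas at ≥6.5 MeV. Published spectra
concentrate the GdF₄ excess at 1–6 MeV, which in reality comes from
excited-state branches whose division is not part of this model's data.
The Monte Carlo 1–6 MeV concentration check is therefore made on the
carbon target (where it holds, ≈0.62), and the calibrated synthetic
route — which is the route anchored to the published numbers — enforces
the 1–6 MeV band for both agents.

## Dose and strand-break metrics

Both metrics are plain fluence-weighted sums over the energy bins,
evaluated at bin centers (with 1 MeV bins the center-vs-average
difference is small; the evaluation grid is the spectrum's, so the
choice is mechanical):

$$\mathrm{Dose}_{tot} = \sum_i \Phi(E_i)\,\mathrm{LET}(E_i)\times 1.6\times10^{-13},
\qquad \mathrm{SSB}_{tot} = \sum_i \Phi(E_i)\,\mathrm{SSB}(E_i),$$

and likewise for DSB. LET(E) is linearly interpolated on the tabulated
1–12 MeV grid (exact at grid points, strictly decreasing from 200 to
53 keV/µm) and clamped to the end values outside it, with a warning;
RBE(LET) is exposed for reporting only — neither metric is RBE-weighted.

**Units.** The fluence convention is "alphas per incident proton per
bin" and the conversion constant $1.6\times10^{-13}$ is applied
verbatim, so the implied area/mass normalisation of a true
fluence-to-dose conversion is absorbed into the synthetic-spectrum
scale. A consequence worth stating plainly: the fitted per-alpha
"yields" in the default damage table (∼10²/alpha) carry that
normalisation and are not microscopic strand-break yields.

**Damage-yield table.** The default table's shapes are skewed peaks
$(E/E_{pk})^k e^{k(1-E/E_{pk})}$ with the SSB maximum pinned at 2 MeV
and the DSB maximum at 1 MeV (where alpha LET is highest), $k = 2$. The
two scale factors are solved — not tuned — so the calibrated no-target
spectrum reproduces the reference totals ($2.1\times10^4$ SSB,
$8.8\times10^3$ DSB per proton). The fitted table ships as
`inst/extdata/damage_yield_default.tsv`, regenerated by
`inst/scripts/fit_damage_yield.R`.

**Enhancement.** `enhancement_percent()` is
$100\,(x_{with}-x_{without})/x_{without}$ with a rounding policy:
nearest integer by default, two significant figures and nearest ten
available because reference tables mix conventions. Calibration always
targets raw values, never rounded percentages. The reference tables are
internally inconsistent in two cells (a printed 100% where the raw
values give 90%, a printed 110% where they give 114%); the package
reports the computed values and leaves the discrepancy visible.

## Spectrum calibration

Full-transport alpha spectra are not reproducible at desk scale, so the
synthetic generator reproduces their *statistical structure*: a broad
gamma-shaped baseline over 0–15 MeV (shape 2, scale 2 — a smooth hump
peaking near 2 MeV) plus an agent-specific excess confined to 1–6 MeV,
built from three narrow gamma basis shapes peaking at 1.5, 3 and 5 MeV.
All calibration is deterministic linear algebra, in order:

1. baseline scale from the no-agent dose (1 unknown, 1 target — exact);
2. SSB and DSB yield scales from the no-agent damage totals (exact);
3. per agent, the three basis coefficients from the 3×3 linear system
   matching the dose, SSB and DSB excesses (exact; the solution is
   checked non-negative bin-wise and >50% inside 1–6 MeV).

Because every solve is exactly determined, residuals are at numerical
precision and the 2% calibration tolerance is a guard against
inconsistent user-supplied targets, not a fitting allowance. Counting
noise is Poisson on raw bin counts at the emulated proton number
(default $10^8$, the full-transport event count; a normal approximation
is used above mean $10^7$). What the generator does *not* emulate:
bin-to-bin correlations of a transport calculation, angular
distributions, LET mixing within a bin, or any spectral detail beyond
the three-moment match — passing tests therefore show the *pipeline*
reproduces the reference aggregates, not that the spectral shape is
microscopically correct.

## Neutron slowing-down and capture

Eight energy groups span thermal to 10 MeV (thermal group
$10^{-5}$–0.5 eV; the report band integrates thermal to 1 keV). The
source is an evaporation Maxwellian $f(E)\propto E e^{-E/T}$ with
$T = 1$ MeV (sample mean $2T$), and a per-proton yield that is an
explicit calibration normalisation, not a prediction.

Within each region the group balance is the infinite-medium slowing-down
competition: the current entering a group splits between absorption
($\Sigma_a$, 1/v-scaled from the thermal-point values — 0.332 b for
hydrogen, 250 000 b for ¹⁵⁷Gd, 4000 b for the ¹⁰B comparison) and
lethargy-gain removal ($\Sigma_s \xi / \Delta u$, hydrogen-dominated);
the thermal group is a pure absorption sink. The tumor sees the full
source; the healthy region sees the source spatially transmitted through
half the tumor thickness via the closed-form 1-D multigroup removal
cascade (`layer_transmission()`, a matrix exponential that reduces to
$e^{-\Sigma x}$ in the single-group purely-absorbing limit — an early
partial-fraction implementation was numerically unstable for
near-degenerate removal constants and was replaced). A literal 1-D
removal chain over the whole slab was rejected on physical grounds: it
compounds Gd absorption over every slowing-down stage along the path,
which is wrong for neutrons that moderate mostly outside the small
tumor, and over-suppresses by many orders of magnitude.

The 70:1 tumor-to-healthy concentration partition is applied as
`gd_ppm/70` in the healthy layers. Baseline (without-Gd) band fluences
are anchored to the reference values ($2.0\times10^{-6}$ per proton in
tumor, $4\times10^{-7}$ in healthy tissue) by region scale factors; the
with-Gd fluxes are the model's own output under the same scales, so the
reductions are computed, not imposed. At 3000 ppm the model yields a
tumor-band reduction factor ≈12 and a healthy-tissue reduction ≈60%
(`run_pipeline()$neutron_table`); the source literature itself is split
between "more than an order of magnitude" and printed fluences implying
a factor ≈6.7, and this package simply reports its computed value.
Adding Gd displaces a mass-equal sliver of the host composition, so
*fast*-group fluxes can rise by ∼$10^{-5}$ relative; the monotone
quantity is the thermal-to-1 keV band (and the thermal group itself),
which is what the property tests assert over 0–6000 ppm.

Not modelled: capture-gamma transport and dose (the capture is used
solely to remove neutrons), angular transport, and back-diffusion from
healthy tissue into the tumor.

## Numerical and degenerate-input choices

- Interpolations are linear and exact at grid points; out-of-range
  energies/LETs clamp to end values with a one-per-call warning.
- `n_peaks = 1` SOBP degenerates to a single unit-weight peak whose
  flat "window" is its own peak position.
- Sub-threshold channels return probability 0; sampling below threshold
  is an error.
- The thin-target assertion trips if $P > 10^{-3}$, guarding the
  forced-interaction weighting.
- Zero spectra give zero dose/damage; empty spectra and non-positive
  denominators (enhancement, reduction) are errors, not NaNs.
- All stochastic stages draw through an isolated seeded RNG scope that
  restores the caller's RNG state; equal seeds give bit-identical
  output.

## Problem sizes

The shipped defaults emulate $10^8$ protons in the synthetic generator
(where cost is independent of the count) while sampled stages default to
$10^5$ protons for beam spectra and $2\times10^4$ forced-interaction
events for alpha pairs — sizes chosen so the whole test suite runs in
seconds on one core while keeping Monte Carlo checks at ≥3σ
sensitivity. All counts are arguments and scale up freely.

## Summary of tunable parameters

| Parameter | Default | Units | Where |
|---|---|---|---|
| Range-model $\alpha$, $p$ | calibrated, 1.77 | cm·MeV⁻ᵖ, – | `range_coefficients()` |
| Energy straggling $\sigma_E$ | 0.02 | fraction | `build_sobp()` |
| SOBP peaks / flatness tol. | 11 / 0.05 | – | `build_sobp()` |
| Target thickness / tissue side | 50 / 0.5 | nm / µm | `nano_geometry()` |
| Plateau cross-sections | 0.4, 0.5, 250000, 4000 | b | `inst/extdata/reaction_channels.yml` |
| Q-values (C, F channels) | −7.275, +8.114 | MeV | same file |
| Yield-shape skewness $k$ | 2 | – | `spectrum_recipe()` |
| Emulated protons | 1e8 | – | `spectrum_recipe()` |
| Gd concentration / partition | 3000 / 70:1 | ppm (mass) | `validate_config()` |
| Evaporation temperature | 1 | MeV | `neutron_source()` |
| Group edges | 8 groups, 1e-5 eV–10 MeV | eV | `neutron_groups()` |
| Conversion constant | 1.6e-13 | – | `total_dose()` |

The ppm convention is mass-based, the standard in the Gd neutron-capture
literature. The fluorine target nuclide is ¹⁹F — the only stable
fluorine isotope — even where source material abbreviates it otherwise.
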