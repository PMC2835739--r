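---
title: "A mutant-accumulation selection assay in a seasonal plankton ecosystem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mutant-accumulation selection assay in a seasonal plankton ecosystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picosel)
```

## The assay

`picosel` treats natural selection on a nutrient-use trait the way a
microbiologist treats a competition experiment. Every picophytoplankton
parent in the model continuously produces three mutant lineages at the same
per-division rate Λ: a null mutant (identical to the parent), a nitrate-loss
mutant, and a nitrate-plus-nitrite-loss mutant. Because production rates are
identical and mutants carry no other differences, the ratio of any two
mutant pools is a pure record of selection integrated over the environment
the lineage experienced. The two indices are log10 ratios of annual-mean
abundances,

$$D_{\mathrm{NO_3}} = \log_{10}\frac{B_{\mathrm{null}}}{B_{\mathrm{NO_3\,loss}}},
\qquad
D_{\mathrm{NO_2}} = \log_{10}\frac{B_{\mathrm{NO_3\,loss}}}{B_{\mathrm{NO_3NO_2\,loss}}},$$

reported only where the parent exceeds $10^{-3}$ of its own maximum
(rare-parent mutant ratios are numerically meaningless). Averaging happens
before the ratio by default; `compute_assay(average = "ratio")` provides the
alternative. In a constant environment with gross growth rate $\mu$ and no
differential loss, the null:parent ratio obeys
$r(t) = (e^{3\Lambda\mu t}-1)/3 \approx \Lambda\mu t$, which the test suite
verifies to 2% against the simulated two-pool system — the calibration
anchor for everything else.

Mutants carry **no** compensating benefit: the model measures the cost of
loss in isolation, so $D \ge 0$ up to integrator noise, and any environment
that makes $D \approx 0$ is one where the loss can drift to fixation.

## Model structure and assumptions

The ecosystem is a zero-dimensional mixed layer: state variables are five
dissolved pools (NH4, NO2, NO3 in µM N; PO4 in µM P; Fe in nM), one biomass
pool per phytoplankton type and mutant lineage (µM P), one grazer per size
class, and three detritus pools. Phosphorus is the currency; biomass N is
Redfield (N:P = 16) and biomass iron follows a fixed quota `R_FeP`.

Growth is multiplicative, $\mu = \mu_{max}\,\gamma_T\,\gamma_I\,\gamma_{nut}$:

* $\gamma_T = e^{-((T-T_{opt})/w)^2}$ — a Gaussian thermal niche.
* $\gamma_I \propto (1-e^{-I/I_{opt}})e^{-k_{inh}I}$, normalized so its
  maximum is 1; $I$ is the mean irradiance over the layer,
  $I_0(1-e^{-kh})/(kh)$.
* $\gamma_{nut}$ is a Liebig minimum over nitrogen, phosphate and iron.
  Nitrogen sums Monod affinities per source, capped at 1, with the oxidized
  sources repressed by ammonium through $e^{-\psi\,\mathrm{NH_4}}$
  (ψ = 1.5 µM⁻¹, the convention of the classic nitrogen-preference models).
  Uptake is split across sources in proportion to the affinities, so the
  nutrient budget closes exactly.

Loss terms: linear mortality; grazing by a size-class grazer with a
saturating response on palatability-weighted total prey,
$g_{max}\,B^n/(K^n+B^n)\,Z$; mixed-layer dilution. Mortality and the
unassimilated fraction of grazing feed detritus, which remineralizes (N
returning as ammonium — the engine of the "recycled ammonium" regime) and
exports at a small rate. Nitrification oxidizes NH4 → NO2 → NO3 at first
order. Mutation debits the parent by $3\Lambda\mu B$ so that total
phosphorus is conserved exactly; at Λ = 1e-8 the debit is dynamically
invisible.

Mixed-layer physics follow the standard entrainment convention: when the
layer deepens, dissolved pools relax toward sub-layer values at rate
$(\mathrm{d}h/\mathrm{d}t)/h$ and particulate pools (assumed absent below
the layer) are diluted; shoaling changes nothing; a weak background
exchange (0.003 d⁻¹) operates year-round. Forcing is a single annual cosine
per variable. Two deliberate departures from the simplest design proved
necessary and are worth recording:

1. **Irradiance is phased to the solstice, not to temperature.** Locking
   PAR to SST puts the light minimum at the end of winter, exactly when the
   spring bloom must start; no parameterization of a cold-adapted ecotype
   survives that world. SST still lags the solstice by ~70 days and deepest
   mixing sits at the end of winter.
2. **A nitracline.** The sub-layer NO3/NO2/PO4 seen by entrainment is the
   reservoir value scaled by $1/(1+e^{-(h-d_0)/w})$. With a uniform
   reservoir, nitrate arrives at the very first autumn deepening, while the
   warm-adapted ecotype is still active and ammonium-starved — a regime in
   which the *summer* ecotype becomes the main nitrate user, inverting the
   observed seasonality in which surface nitrate rises only once mixing
   reaches depth in early winter. $d_0$ is 170 m at the seasonal site, 60 m
   in the gyre scenarios, 0 (disabled) in the diagnostic box.

## Scenario library

Six regimes stand in for the range of environments a global circulation
model would expose (`build_scenario`, serialized in
`inst/extdata/scenarios.json`): a permanently stratified oligotrophic gyre
(deep NO3 2 µM, MLD 40–60 m); a seasonally mixing subtropical site
(MLD 20–300 m over an 8 µM nitrate reservoir — the succession experiment);
a cold high-latitude column; an HNLC variant identical to the gyre except
deep Fe 0.06 nM and deep NO3 8 µM (the iron-interaction control, different
from the gyre *only* in those two fields, which the tests enforce
field-by-field); a closed box (conservation diagnostic); and an
ammonium-only world (deep NO3 = NO2 = 0, run with nitrification off), where
all three mutant classes are bit-identical by construction — the assay's
zero point.

Deep phosphate is chosen Redfield-consistent (deep N:P ≤ 14.5 across the
prescribed nitrate sweep up to 16 µM) so that nitrogen remains the limiting
element along the whole sweep; otherwise the top of the sweep silently
switches the community into phosphorus limitation, which by Liebig erases
nitrogen selection for reasons unrelated to nitrate supply. Even so, the
marginal benefit of nitrate saturates at the eutrophic end — bigger blooms
recycle more ammonium, which both saturates and represses the nitrogen
term — so $D_{\mathrm{NO_3}}$ flattens, and for some community draws can dip
slightly, at the highest supply.

## Communities and the ecotype pair

`generate_community()` draws 15 picophytoplankton and 18 large types
uniformly within versioned intervals (`inst/extdata/trait_ranges.json`).
The intervals for `mu_max` and the N/P half-saturations are disjoint
between size classes, so every draw satisfies the gleaner/opportunist
contract (small types grow slower but at lower nutrient levels); the
sampling-range table in the original design sketch allowed overlapping
`mu_max` intervals, which would violate that contract for individual draws.
Ranges are calibration choices, not literature values.

`make_ecotype_pair()` returns the controlled contrast used in the
succession experiments: E2 (warm, `T_opt` 22 °C, slightly lower K's)
versus E3 (cool, 16 °C), all other fields identical. Both are low-light
capable (`I_opt` 30 W m⁻²), which picocyanobacteria are, and without which
the cool type cannot use the dim nitrate-rich late winter. Succession runs
embed the pair in a seeded random large-phytoplankton background: the large
types consume the spring nitrate pulse, which is what pushes the summer
ecotype onto recycled ammonium — with no large phytoplankton the summer
bloom itself becomes nitrate-fueled and the mechanism under study
disappears.

## Numerical choices

The stiff-ish system (pools spanning 10 orders of magnitude) is integrated
with an embedded Dormand–Prince 5(4) pair written in C++ (no suitable ODE
package is available in the deployment environment), rtol 1e-8 and
atol 1e-12 µM, a 2-day step cap so seasonal forcing is always resolved, an
exact stop at the mutation onset (the only discontinuity), and a positivity
floor that clips negative undershoots to zero (observed clips are below
1e-9 µM; the conservation tests bound their cumulative effect). Linear
invariants (total P, N, Fe in a closed box) are preserved by any
Runge–Kutta method, so conservation holds to rounding error (~1e-15
relative over five years, versus the 1e-6 requirement). Because mutant
dynamics are linear in Λ, their relative accuracy tracks the parents'
rather than the absolute tolerance; the Λ-sweep test confirms the indices
move by < 3e-6 relative across Λ ∈ {1e-9, 1e-8, 1e-7}.

Grazing uses saturation exponent n = 2 (a type-III response) by default.
With n = 1 the specific grazing rate at low prey approaches
$g_{max}Z/K \sim 1.6\,\mathrm{d^{-1}}$, which drives seasonally disfavored
types to ~1e-40 µM P and below — absorbing extinctions that destroy both
the ecology and the mutant-ratio readout. The half-saturation property
(ingestion = $g_{max}Z/2$ at $B=K$) and the palatability apportionment are
exponent-independent; n = 1 remains available via the grazer parameter
list.

## The schedule and what a green test establishes

Runs follow the reporting convention: years 1–3 community spin-up, mutation
onset at day 1095, year 4 mutant accumulation, year 5 analysis
(`run_config` enforces `t_end ≥ onset + 730 d`). Mutant relative abundances
are not at steady state in year 5 — the indices keep growing slowly with
accumulated exposure — but their *ordering* across ecotypes and scenarios,
which is what the acceptance criteria assert, is stable from year 4 onward
and across a 5-member ensemble of community draws.

The synthetic forcing emulates the seasonal alternation of stratification
and deep mixing, recycled-ammonium summers, nitrate-rich winters, and an
iron-limited gyre; it does not emulate lateral transport, vertical
structure within the euphotic zone (no primary nitrite maximum, no
low-light floor populations), storms or interannual variability, diurnal
cycles, or self-shading. A green suite therefore establishes that the
selection-assay machinery is correct and that the paper-style qualitative
contrasts emerge in this 0-D world — not that the magnitudes of $D$ match
any particular ocean.

## Known limitations

* One grazer per size class and linear closure keep the food web minimal;
  apparent competition through the shared grazer is strong, and rare-type
  persistence depends on the type-III refuge.
* The mask and the analysis window replace the original spatial masking
  (abundance along a transect) with masking over time; parents that bloom
  briefly can pass the mask on few days.
* No gain-of-function mutation, no back-mutation, no frequency dependence,
  no fitness benefit of genome reduction — the indices measure cost of loss
  only.
* Scenario magnitudes are calibrated to qualitative contracts; absolute
  biomasses and index values should be read comparatively, not as field
  predictions.
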