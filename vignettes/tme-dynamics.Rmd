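---
title: "Modelling the breast tumour microenvironment with angiogenesis and hypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the breast tumour microenvironment with angiogenesis and hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeode)
```

## The model and its assumptions

The package models the breast tumour microenvironment (TME) of MMTV-PyMT
mice as a system of 18 coupled, non-dimensional ordinary differential
equations built by the law of mass action. Twelve variables are cell
populations — endothelial cells (EN), naive/helper/cytotoxic/regulatory T
cells (TN, Th, Tc, Tr), naive/activated dendritic cells (DN, D),
naive/activated macrophages (MN, M), cancer (C), necrotic cells (N) and
adipocytes (A) — and six are molecular: VEGF (V), oxygen (Ox), HMGB1 (H),
IL-12, IL-10 and IL-6.

Key structural assumptions:

- **Activation conserves flux.** Naive pools (TN, DN, MN) are produced at
  constant innate rates (`A_TN`, `A_DN`, `A_MN`) and lose exactly the flux
  their activated counterparts gain; the activation rates are shared
  symbols, not duplicated parameters.
- **Logistic growth with capacities.** Cancer, adipocytes and endothelial
  cells carry capacities `C0`, `A0`, `EN0`; EC growth is catalysed by VEGF
  (`lambda_VEN * V`). The capacities are estimated parameters like the
  rates.
- **Oxygen has no outgoing arrows; its absence does.** ECs are the oxygen
  source (`lambda_OxEN`); every cell group consumes oxygen
  (`delta_1..delta_6`). Hypoxia acts through two decreasing Hill switches
  of the oxygen level,
  `f_i(x) = ox_crit_i^m / (ox_crit_i^m + x^m)`:
  `f1` (mild hypoxia, HIF-pathway activation at 0.1–1% O2) promotes VEGF,
  IL-6 and IL-10 production, dendritic-cell maturation, Treg
  differentiation and T-cell cytotoxicity; `f2` (severe hypoxia, < 0.1%
  O2) adds hypoxic death terms to most cell types. Macrophages have no
  hypoxic death (they adapt to hypoxic niches); necrotic cells are already
  dead.
- **Necrosis.** A fraction `alpha_NC` of all cancer-cell death flux
  becomes necrotic cells, which decay at `delta_N`.
- **One time scale.** Time is in days throughout and is never
  non-dimensionalized; week 6 of tumour progression is the initial state,
  t = 0, and observations fall at t = 0, 14, 28, 42 (weeks 6/8/10/12).

The estimated-parameter registry enumerates every distinct symbol of the
printed equations exactly once: 85 rates plus the 3 capacities, 88 entries
(`tme_parameter_names()`), extended by `ox_crit1`, `ox_crit2`, `m_hill` to
the 91-entry axis used for sensitivity analysis. The summary count often
quoted for this model is 86 parameters (89 including the hypoxia shapes),
which disagrees with this enumeration by two; the package follows the
equations, since collapsing two symbols
would change the model.

### Hypoxia defaults

The main-text thresholds are percentages; their non-dimensional values
follow from the week-6 oxygen scale. 50 000 ppm (≈ 5% O2, normoxia) is the
week-6 maximum: with the table convention of ppm = mg/l and a 16 g/mol
molar mass, 50 000 ppm → 3.125 mol/l → 1.0 after scaling. 1% O2
(10 000 ppm) is then `ox_crit1 = 0.2` and 0.1% O2 (1 000 ppm)
`ox_crit2 = 0.02`. The Hill exponent defaults to `m = 5`, a moderately
sharp switch; all three are configurable (`hypoxia_params()`) and the
sensitivity tools treat them as first-class parameters. The
non-dimensional threshold values and the exponent are not fixed by the
experimental data, so these defaults are this package's own choice.

## Data preparation

`stage_cell_estimates()` reproduces the reference count arithmetic
exactly, and
the conventions matter:

- **Caliper geometry.** Tumour volume is `L * W^2 / 2`; assuming `L ≈ W`,
  the stage volumes 200/400/700/1400 mm³ invert to diameters `(2V)^(1/3)`
  **truncated** (not rounded) to 2 decimals: 7.36, 9.28, 11.18, 14.09 mm.
  Rounding would give 7.37 and 11.19 and break the downstream counts.
- **Per-gram yields.** 4.5±0.9×10⁷ cancer cells and 2.2±0.6×10⁶ TAMs per
  gram, obtained from two ~10 mm tumours, give
  `(yield/2) * (d/10)` cells per stage. Means are truncated to 3
  significant figures, standard deviations to 2 — the unique combination
  reproducing all eight reference stage estimates (e.g.
  2.25×10⁷ × 0.928 = 2.088×10⁷ → 2.08×10⁷ and
  0.45×10⁷ × 0.928 = 0.4176×10⁷ → 0.41×10⁷).
- **Per-mouse anchors.** Mice 1/2/3 sit at mean −1/0/+1 standard
  deviations (`mouse_anchor()`). This reproduces the reference cancer
  counts exactly at weeks 6, 8 and 12; at week 10 the reference table
  swaps mice 2 and 3, and the TAM columns follow yet another assignment,
  so the rule is applied as stated and the discrepancy documented rather
  than special-cased.
- **Fractions to counts.** The TAM total anchors the immune panel
  (`immune_counts_from_fractions()`); necrotic cells are exactly half the
  cancer cells and are excluded from the volume budget (reported volumes
  are devoid of necrotic tissue); non-immune counts fill the residual
  caliper volume in proportion to their fractions with single-cell
  caliper volumes `L³/2` from the reference size table (midpoints of
  ranges). Reference adipocyte/EC counts are far too small to absorb a
  200 mm³ residual on their own, so the non-immune panel accepts
  additional absorber types (epithelial cells at 30 µm dominate the
  volume); the model keeps only A and EN.
- **Oxygen units.** ppm is read as mg/l and divided by a 16 g/mol molar
  mass — the convention that reproduces the reference mol/l values
  (3.125 at week 6 down to 0.000625 at week 12). Molecular O₂ is
  32 g/mol; `o2_ppm_to_molar(ppm, molar_mass = 32)` gives the physically
  conventional value, but the default follows the tables.
- **Non-dimensionalization.** Every variable is divided by its maximum
  across all mice and stages, so data lie in [0, 1] with each variable
  attaining 1 somewhere; the scale registry is kept for back-conversion.

## Parameter estimation

The loss (`tme_loss()`) is the unweighted sum of squared differences
between simulated and observed non-dimensional values over mice, variables
and time points — defensible because the scaling puts every variable on
[0, 1]; a weight matrix is exposed for robustness studies. Initial
conditions are each mouse's observed week-6 state (a flag estimates them
instead). Integration failures return a large finite penalty (1e6) so the
global search continues.

The hybrid genetic algorithm (`ga_minimize()` + `local_refine()` inside
`fit_tme()`) follows the classic design: rank-based fitness scaling
(expectation ∝ 1/√rank), stochastic-universal selection along a line of
scaled segments, elite carry-over, scattered crossover, Gaussian mutation
whose scale shrinks tenfold over the run, and box bounds [0, 2] on every
parameter (searches with larger upper bounds do not produce values above
2). Defaults — population 200, 500 generations, 5% elite, crossover 0.8,
stall limit 50, tolerance 1e-8 — are this package's choices, since no
standard values exist for this problem; fitted parameter values are
therefore not reproduction targets. Refinement screens the best
few GA candidates with a short L-BFGS-B descent and then refines the
winner deeply; the refined loss never exceeds the GA loss. Carrying
capacities get a small positive lower bound (1e-3) because the logistic
terms divide by them.

`recovery_experiment()` closes the loop: a ground truth drawn uniformly
from [0, 2], noiseless observations at the four stage times, and ten free
rates re-estimated while the rest stay at truth. With biweekly sampling
some directions are genuinely weakly identified (rates faster than about
1/day equilibrate before the first sample, leaving near-ratio
information), so a few-percent median error is the realistic noiseless
performance — the package tests assert a pooled median relative error
below 10% over five seeds.

## Practical identifiability

`perturbed_synthetic()` perturbs fitted trajectories at the observation
times by independent multiplicative noise uniform in [1−level, 1+level]
(default 5%; lognormal noise is available in the generator).
`profile_likelihood()` scans one parameter over [0, 2·estimate]
(21 points by default), re-optimizing all other free parameters at each
grid point with warm starts sweeping outward from the estimate.
`classify_profile()` applies the threshold `loss + qchisq(alpha, 1)` with
`alpha = 0.95` (Δ = 3.84):
crossing on both sides → identifiable; failing at least one side →
practically non-identifiable; total variation under `flat_tol = 0.1` of
the chi-square increment → flat (suggesting local structural
non-identifiability). The chi-square calibration reads the loss as
−2 log-likelihood, i.e. it presumes residuals scaled by their noise level;
the coverage property test in the suite does exactly that on an
exponential-decay toy. Structural identifiability of the full model (all
variables observed) was established externally with a Lie-derivative
observability analysis and is recorded here as context only — the package
does not implement symbolic structural analysis. Reference analyses of
this model report per-mouse counts around 41/35/35 practically
non-identifiable and 31/12/13 flat parameters; such counts depend on the
optimizer, grids and noise draw and are treated as qualitative
expectations, not test targets.

## Principal-component global sensitivity analysis

`sensitivity_matrix()` stacks central finite differences
`∂X_k(t_i)/∂θ_j` into an (n·K) × N matrix — rows blocked by output
variable then time, N = 91 parameters by default on a daily grid over
[0, 150]. The relative step is 1e-4 with an absolute floor of 1e-6, and a
failed integration at a perturbed point retries with halved steps. The
`scaled` mode multiplies column j by θ_j, measuring response to relative
parameter change (the natural scale when parameters span orders of
magnitude); a forward-sensitivity-ODE cross-check on a toy block is part
of the test suite. `pc_decompose()` takes the thin SVD M = UΣVᵀ and
reports S_ij = σ_i·V_ji. The first-order response is
δX = Σ_ij S_ij δk_j U_i = U S δk — note S already contains σ_i, so no
further σ factor appears (this expansion is sometimes written with an
extra σ_i factor, which is redundant for the same reason).
`singular_spectrum()` counts PCs whose singular value reaches 20% of the
leading one; `variable_heatmap()` reports σ-scaled loadings above 20% of
the global maximum; `scalar_sensitivity()` analyses one output (cancer,
total immune cells = TN+Th+Tc+Tr+DN+D+MN+M, or all cells), where a single
dominant singular value makes PC sensitivity coincide with classical
global sensitivity; its sign is oriented so that positive means the
output rises overall when the parameter increases, verified against
direct ±10% perturbations. `perturbation_experiment()` re-simulates a
parameter family and returns cancer / total-immune envelopes.

## The synthetic-data generator

The generator defines the study conditions: three mice, observations at
t = 0/14/28/42 days, 5% multiplicative uniform noise, parameter prior
uniform on [0, 2] (per-name bounds and a sparsity mask available), the
reference stage volumes and yields, and the observed week-6 state of
mouse 2 (the mean-anchored mouse) as the default initial state.
`sample_ground_truth()` guarantees integrability on [0, 150] by
resampling up to a retry cap. `make_observations()` returns the noisy
dataset plus its noiseless reference; rescaling by per-variable maxima is
off by default so that a noiseless dataset closes the estimation loop
exactly (`loss(truth) = 0`) — switching it on mimics the real-data
scaling at the cost of that exact closure. `make_fraction_tables()`
inverts anchor-consistent counts into exactly the tables the
data-preparation step consumes; fractions are emitted from continuous
counts so the assemble → counts round trip is exact to integer precision.

What the generator emulates: the shapes, scales and noise structure of
the deconvolved fraction tables, TAM totals, caliper volumes and cytokine
levels. What it does not: transcriptome-level variation, deconvolution
error structure (correlated, non-multiplicative), inter-mouse biological
heterogeneity beyond the ±1 SD anchor rule, and measurement sparsity
patterns. Passing tests therefore demonstrate the correctness and
stability of the arithmetic and estimation machinery under the stated
conditions, not the biological adequacy of the model for new data.

## Numerical choices

- Stiff-capable integration (`lsoda`) with rtol 1e-8 / atol 1e-10;
  right-hand side compiled in C (a plain-R implementation is kept and
  tested to agree, and an independent term-table expansion agrees to
  1e-12).
- Negative excursions smaller than the absolute tolerance are clipped to
  zero after integration; the oxygen argument of the Hill switches is
  floored at zero during integration to keep `pow` defined.
- Truncation conventions in the data arithmetic are as described above;
  a 1e-9 pre-round guards truncation against binary representation noise.
- L-BFGS-B refinement uses finite-difference steps of 1e-7 and a tight
  factr (1e4); a failed line search returns the starting point with a
  warning rather than failing the fit.
- Profile scans warm-start outward from the estimate; a failed
  re-optimization flags the grid point (NA) and the curve continues.
- Test problem sizes: recovery uses 1 synthetic mouse, 10 free
  parameters, population 200 and 250 generations; sensitivity tests use
  coarse grids (6-day steps over [0, 60]); the full-model PCGSA in the
  acceptance script uses a 5-day grid over [0, 150] and all 91
  parameters.

## Known limitations

- No spatial transport, chemotaxis, macrophage M1/M2 split, or glycolytic
  (Warburg) metabolic switch — all deliberate scope exclusions of the
  underlying model.
- Real-data reconstruction of the immune count columns requires the
  numeric fraction tables, which are available only as figures; the
  synthetic round trip stands in for them.
- The GA is single-objective and the fit per mouse; no identifiability-
  aware reparameterization is attempted, so flat directions surface in
  the profile analysis rather than being removed.
- Full 88-parameter profile sweeps are compute-heavy and not part of the
  default test run; `tme_pipeline()` exposes them as an explicit batch
  stage.
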