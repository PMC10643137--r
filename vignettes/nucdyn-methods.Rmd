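---
title: "Methods: trajectory segmentation, bound-state kinetics and activity-by-contact links"
author: "nucdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory segmentation, bound-state kinetics and activity-by-contact links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nucdyn` analyses live-cell single-particle tracking of chromatin-associated
protein complexes (such as the NuRD nucleosome remodelling and deacetylase
complex) and, in a second arm, the genomic consequences of perturbing such
complexes through activity-by-contact (ABC) enhancer–promoter link calling.
This vignette is the package's account of the underlying models, the
parameters that matter, what the synthetic generators do and do not emulate,
and the numerical decisions taken where the design was genuinely open.

# The tracking model

## From localizations to trajectories

Single molecules are localized per frame in 2D or 3D (micrometres).
`link_localizations()` connects localizations in *subsequent* frames when
they lie within a distance cap: 0.8 µm for 20 ms exposures, 0.5 µm for
500 ms exposures. There is no gap closing by default — a missed detection
ends the track — because the downstream window statistics assume strictly
uniform sampling; a `gap` argument exists for exploration. Within a frame
pair, candidate matches are resolved greedily in ascending distance, each
endpoint used once. In the sparse labelling regime this equals the global
minimal-distance assignment (the test suite verifies this against an
exhaustive enumeration oracle); at high density greedy matching can differ
from the global optimum, which is a known limitation.

## The four sliding-window parameters

A window of 11 consecutive frames slides along each trajectory (stride 1).
Per window we compute:

* **α** — the anomalous exponent in MSD ∝ t^α, the slope of
  log TA-MSD(ℓ) versus log(ℓ·Δt) over lags ℓ = 1..5. α ≈ 1 indicates free
  diffusion, α < 1 subdiffusion in condensed chromatin, α > 1 directed
  motion.
* **D_app** (µm²/s) — MSD(1)/(2·dim·Δt), the minimal-lag apparent
  diffusion coefficient, least biased by subdiffusive curvature.
* **Lc** (µm) — the RMS distance of window points from their centroid, the
  spatial scale the molecule explores.
* **‖V‖** (µm/s) — the norm of the mean per-frame displacement divided by
  Δt; large values flag directed transport.

The TA-MSD averages over *all* point pairs at each lag. The lag cap at
half the window (5 of 11) is a standard bias/variance compromise: higher
lags have too few pairs to be stable.

**Jensen correction of the α fit.** The log of a noisy MSD is biased low
by Var(MSD)/(2·E[MSD]²), and the bias grows with lag (fewer pairs), so the
log–log slope is biased down — by as much as −0.07 at α = 1 for 11-frame
windows. `sliding_features()` therefore corrects each log MSD with a
second-order Jensen term whose variance-of-mean uses the Gaussian
overlapping-pair covariance kernel ρ_ij = ((ℓ−|i−j|)₊/ℓ)². With the
correction, the mean window α is within ±0.03 of the truth for fractional
Brownian motion at α ∈ {0.4, 0.7, 1.0}. On exact power-law input the
correction vanishes and the slope is exact, preserving the analytical
identities (α = 2 ballistic, α = 1 Brownian). `estimate_alpha()` itself
remains the plain least-squares slope so that its contract is transparent.

**The precision floor.** Localization noise σ sets the smallest effective
diffusion coefficient that is measurable: D_eff ≥ σ²/t. With 60 nm
precision at 20 ms exposures the floor is 0.06²/0.02 = 0.18 µm²/s; with
34 nm at 500 ms it is 0.034²/0.5 ≈ 0.002 µm²/s. Apparent mobilities below
the floor carry no biophysical meaning, which is why the slow bound state
at 500 ms can only just be distinguished from stationary dye molecules.

## Stage 1: confined versus unconfined

All valid windows are pooled into the 4D feature space and standardized
(z-score; the parameters have incommensurate units). A two-component
full-covariance Gaussian mixture is fitted by EM with k-means++ seeding,
10 restarts, and the best likelihood kept. The *confined* (chromatin-bound)
component is the one with the smaller mean D_app (ties broken by smaller
mean α), making the labelling canonical under component permutation.
Numerical choices:

* covariance regularization: on singularity, 10⁻⁶ × mean diagonal is added
  (logged);
* EM is asserted monotone in log-likelihood every iteration;
* observations are sorted into lexicographic order inside the fitter, so
  the fit is bitwise reproducible under permutation of the input rows at a
  fixed seed;
* the posterior threshold is strict (`P > 0.5`); an exact tie labels the
  window unconfined.

Each frame then takes the posterior of the window centred on it; the first
and last 5 frames, which no window centre reaches, take the nearest
window's posterior. State fractions are reported both per window and per
trajectory (majority rule — at least half the assigned frames); the
aggregation the original experiments used is not stated, so both are
exposed.

**Feature transform.** The default mixture operates on the raw
parameters. For the 500 ms chromatin-bound analysis the package fits the
mixture after log-transforming the scale parameters (D_app, Lc, ‖V‖):
those data span modes less than a decade apart in near-lognormal
parameters, and the raw-space mixture miscalibrates the slow/fast boundary
(slow share off by ~4 points on synthetic truth), while the log-space fit
is calibrated to a fraction of a point. The 20 ms analysis keeps the raw
space, where the two populations are far apart and raw fitting is both
accurate (97% per-frame on synthetic truth) and simpler to interpret.

## Stage 2: S/F1/F2 substates of bound molecules

At 500 ms exposure, motion blurring suppresses freely diffusing molecules,
so trajectories (filtered to those lasting more than 5 s) are dominated by
chromatin-bound complexes. The Stage-1 mixture then separates slow (S)
from fast bound molecules. Within the fast class only, a 1D two-component
Gaussian mixture on the window α values resolves F1 (lower α, condensed
chromatin) from F2 (higher α, decondensed, with drift). This two-stage
structure — not a single three-component fit — mirrors how the states were
defined; drift is reported alongside F2 calls but does not enter the
Stage-2 fit. Proportions are S = slow share, F1/F2 = fast share × mixture
weights; bootstrap confidence intervals (default 1,000 resamples) resample
both the α values and the slow/fast split.

**An identifiability limit, stated plainly.** Per-window α estimates from
11-frame windows carry irreducible sampling noise of SD ≈ 0.25 (the
Cramér–Rao bound for a Hurst-type exponent from ~10 increments is of the
same order; widening the window to 41 frames still leaves SD ≈ 0.17).
When the true F1/F2 means are 0.60 and 0.89 — separated by ~1 SD of the
estimator noise — a two-component Gaussian fit on window α values cannot
recover the 0.78/0.22 within-fast weights to ±3 percentage points; even on
perfectly Gaussian synthetic components at SD 0.26 the fitted second
weight lands near 0.48. The fit does recover weights to ±3 points when α
values have component spreads of ~0.1, the scale at which the published
histograms were fitted. Consequently: the S proportion is recoverable
end-to-end from trajectories (and is tested so), while end-to-end F1/F2
proportion recovery at ±3 points is not attainable with window-level α
estimates of this length; the corresponding assertions are kept in the
acceptance suite and fail honestly rather than being weakened.

## Kinetics

Association times are the lengths of maximal unconfined runs flanked on
both sides by confined frames (dissociation: roles swapped). Runs touching
a trajectory end are censored and excluded from the default fit; a
censoring-aware exponential likelihood (rate = events / total time at
risk) is available and removes the truncation bias. Rates are fitted by
maximum likelihood on the durations themselves — never by least squares on
a histogram, whose binning would be an unstated free parameter. The 95% CI
is exact via the gamma distribution of the duration sum; goodness of fit
is a KS test against the fitted exponential (approximate, since durations
are multiples of Δt).

Dissociation analysis is implemented but documented as unreliable for
long-binding factors: bound times of minutes exceed what photobleaching
allows one to observe. The supported route is the **time-lapse model**:
photobleaching scales with the number of exposures (hazard k_bleach·t_int
per frame) while unbinding scales with wall-clock time (hazard k_off·τ per
frame of lapse τ), so imaging the same molecules at lapse intervals
{0.5, 2.5, 8, 32} s and jointly fitting the geometric track-length
distributions separates the two rates. The fit is box-constrained L-BFGS-B
on (k_bleach, k_off) ≥ 0 with Wald intervals from the numerical Hessian;
when the k_off interval reaches 0 the result is flagged bleach-dominated —
the regime observed for NuRD subunits, whose mean frame count did not
decrease even at a 32 s lapse.

# The synthetic world

`simulate_trajectory()` provides Brownian motion, fractional Brownian
motion (exact-covariance circulant embedding, Cholesky fallback — the
generator is validated against its analytic autocovariance), confined
Ornstein–Uhlenbeck motion, directed motion, and continuous-time
Markov-switching mixtures of these; localization noise (optionally
z-anisotropic), geometric photobleaching truncation and detection gaps are
applied on top. Benchmark scenarios fix the parameter scales to the
measured biology:

* `stage1_20ms` — free (α 0.94, D_app 1.3 µm²/s) versus bound (α 0.51,
  D_app 0.43 µm²/s) molecules, whole-track states, 60 nm noise. The bound
  fraction defaults to 0.5 (the published percentages are condition- and
  subunit-specific; 0.5 is a neutral choice made once).
* `stage2_500ms` — bound molecules switching among S (α 0.59, D_app
  0.006), F1 (α 0.60, D_app 0.018) and F2 (α 0.89, D_app 0.018 plus
  0.03 µm/s drift) with stationary occupancies 0.67/0.26/0.07 and 34 nm
  noise. Mean state dwell is 30 s: substate periods must be long relative
  to the 5.5 s window for a two-stage analysis to be meaningful, and bound
  residence in this system is on the minute scale. Each switching segment
  restarts the fractional-Gaussian memory at the previous endpoint (states
  are independent motion regimes; long-range memory across state changes
  is not emulated).
* `timelapse` — geometric track lengths over the lapse ladder.
* `locus2d` — 2D confined locus tracks (dCas9-style labelling), analysed
  with the same machinery in their native dimensionality. 2D and 3D
  results are never pooled.

What a green test on this world establishes is estimator and classifier
correctness *given the model assumptions* — fBM-like subdiffusion,
isotropic Gaussian noise, Markov switching, geometric bleaching. It does
not establish robustness to aspects the generators do not emulate:
intra-exposure motion blur (only its consequences — noise inflation and
loss of fast molecules — are representable via the noise and gap
parameters), anisotropic axial precision of real 3D PSFs (configurable but
defaulted isotropic), non-Markovian state switching, or drift of the cell
and stage.

# The activity-by-contact arm

Promoters are the ±1 kb windows around TSS that overlap an H3K4me3 peak.
Candidate regulatory elements come from H3K27ac peaks via an ordered
pipeline: merge peaks closer than 500 bp (gap < 500; bookended peaks always
merge), discard merged peaks shorter than 500 bp, discard peaks overlapping
promoters; the master list is the union of the survivors ("intergenic")
and the promoters. Activity A_r is the mean per-base H3K27ac signal over
the element. Contact C_pr is the 5 kb-binned Hi-C value between the
promoter and element midpoints; pairs anchored in poorly covered bins
(marginal coverage below the 5th percentile — the cutoff is configurable
because the original rule is not stated) are imputed from the fitted
power-law distance decay C ∝ d^(−γ), with γ the negative slope of
log mean-contact versus log distance over 10 kb–5 Mb. Imputation is
anchored to the fitted curve, making it continuous in distance. Each
candidate within 5 Mb of a promoter is scored

ABC(p,r) = A_r·C_pr / Σ_{s∈N(p)} A_s·C_ps,

so scores over one promoter's candidates sum to 1. Strong links are the
pooled (both conditions) top decile by score; ties at the threshold are
kept, so the strong set may slightly exceed 10%. Link IDs are
promoter id : promoter position : element id, and categories
(condition-unique / common) are set algebra on those IDs — element IDs
must therefore be coordinate-comparable across conditions, which the toy
generator guarantees and real inputs must provide. Link-length
distributions are compared with a rank-based (Wilcoxon) location test —
a deliberate substitution for the unnamed Bayesian t-test variant used in
the original analysis — and enrichment against gene-regulation labels uses
the χ² statistic without continuity correction, cross-checked in the tests
against the closed 2×2 form. Coordinates are BED-convention 0-based
half-open throughout, with strand-aware 5′ TSS extraction from GTF input.

Gene-regulation labels are an input table, not computed here; Hi-C
normalization, compartment and TAD calling are out of scope (published
tools exist for all three), as is the DHS-based geometric-mean activity of
the original ABC formulation — the H3K27ac-only activity is the point of
this variant.

# Known limitations

* Greedy frame-pair linking can deviate from globally optimal tracking at
  high molecule density.
* The Lc estimator is a transparent RMS-radius proxy for the "spatial
  scale explored"; it underestimates the stationary confinement radius for
  strongly correlated windows (the centroid absorbs shared displacement).
* End-to-end F1/F2 proportion recovery is limited by window-level α noise
  (see the identifiability note above).
* The timelapse Wald intervals are boundary-naive at k_off = 0; the
  bleach-dominated flag, not the interval width, is the supported
  conclusion there.
* ABC scoring normalizes per promoter, so scores are not comparable as
  absolute contact strengths across promoters with very different
  candidate sets; the pooled decile threshold inherits this caveat.
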