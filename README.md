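# nucdyn

Single-molecule chromatin dynamics and enhancer–promoter link analysis.

Chromatin-modifying machines such as the NuRD (nucleosome remodelling and
deacetylase) complex bind enhancers, switch between diffusive and bound
states on sub-second timescales, and reshape enhancer–promoter contacts on
the megabase scale. `nucdyn` covers both ends of that problem:

**Tracking arm.** From per-frame 3D localizations of fluorescently tagged
molecules it builds trajectories (linking localizations in subsequent
frames within 0.8 µm for 20 ms exposures, 0.5 µm for 500 ms), slides an
11-frame window along each trajectory and computes four biophysical
parameters — the anomalous exponent α (MSD ∝ t^α), the apparent diffusion
coefficient D\_app = MSD(1)/(2·dim·Δt), the localization length Lc (RMS
radius about the window centroid) and the drift magnitude ‖V‖. A
full-covariance Gaussian mixture on the standardized 4D feature space
classifies every timepoint as confined (chromatin-bound) or unconfined
(freely diffusing) by posterior P > 0.5. For 500 ms "motion-blurred" data
a second stage resolves slow (S) and fast bound molecules, then splits the
fast class into F1/F2 substates by Gaussian fitting of the α distribution.
Dwell-time kinetics (exponential ML with exact gamma CIs, censoring-aware
variant) and a time-lapse model that separates the unbinding rate k\_off
from the photobleaching rate k\_bleach complete the arm. Every estimator
is validated against exact simulators (Brownian, fractional Brownian via
circulant embedding, confined Ornstein–Uhlenbeck, directed,
Markov-switching).

**Genomics arm.** A modified activity-by-contact (ABC) model scores
enhancer–promoter pairs: promoters are ±1 kb of a TSS overlapping an
H3K4me3 peak; regulatory elements are H3K27ac peaks merged at < 500 bp
gaps, length-filtered at 500 bp and cleared of promoter overlaps; activity
is the mean H3K27ac signal; contact comes from a 5 kb binned Hi-C matrix
with power-law (C ∝ d^−γ) imputation of poorly covered pairs; and

    ABC(p,r) = A_r · C_pr / Σ_{s ∈ N(p)} A_s · C_ps,   N(p) = elements within 5 Mb.

Strong links are the pooled top decile across two conditions, categorized
common/condition-unique by link ID, compared by a rank-based length test
and a χ² enrichment against gene-regulation labels.

## Worked example

```r
library(nucdyn)

# measurability floors for the two imaging regimes (um^2/s)
precision_floor(c(0.06, 0.034), c(0.02, 0.5))
#> [1] 0.180000 0.002312

# simulate a 20 ms two-state world and segment it
bench <- make_benchmark_suite("stage1_20ms", seed = 7, n_tracks = 120)
seg <- segment_trajectories(bench$trajectories, seed = 8)
seg$model
#> <nd_state_model> 2 components fitted on 3700 windows
#> component means (original scale):
#>       alpha  d_app     lc drift_norm
#> [1,] 0.4222 0.5928 0.2270     1.9395
#> [2,] 0.8736 1.4633 0.5045     5.4957
#> confined component: 1; separation 2.38 SD
round(state_fractions(seg$frames, "windows"), 3)
#>   confined unconfined
#>      0.482      0.518
```

The confined component has low α (subdiffusive, chromatin-bound) and low
D\_app; the recovered window fractions match the generator's 50/50 state
mix, and per-frame agreement with the simulation's ground truth is 97%.

```r
# ABC links on a synthetic genome with power-law contacts
g <- simulate_toy_genome(seed = 2, noise = "none")
prom <- define_promoters(g$tss, g$h3k4me3)
res  <- define_res(g$WT$h3k27ac, prom)
act  <- score_activity(res, g$WT$signal)
fit_gamma(g$WT$contacts)
#> <nd_gamma_fit> gamma = 1.0000 over 10000-5e+06 bp (398 distance bins)
links <- abc_scores(prom, res, act, g$WT$contacts, fit_gamma(g$WT$contacts))
head(links[order(-links$abc_score), c("link_id", "distance", "abc_score")], 3)
#>                                       link_id distance abc_score
#> 118    gene05_t1:752299:re_chrT_763207_763849    10000 0.4918374
#> 40     gene02_t1:263147:re_chrT_244276_246100    15000 0.4759434
#> 355 gene11_t1:1735403:re_chrT_1707181_1708893    30000 0.3473202
```

The recovered decay exponent equals the γ = 1 the genome was built with,
and the top-scoring links are short-range pairs combining high activity
with high contact, as the normalized score intends.

A thin command-line wrapper over the same functions is installed as
`exec/nucdyn` (subcommands `simulate`, `link`, `features`, `segment`,
`substates`, `kinetics`, `abc-call`, `abc-compare`; every run writes a
manifest with config hash, seed and input checksums).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch — the printed precision floors, a seeded stage-1 simulation with
end-to-end segmentation, the time-lapse rate separation on the
{0.5, 2.5, 8, 32} s lapse ladder, and a two-condition ABC call on the
synthetic genome — and writes its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/nucdyn-methods.Rmd` documents the models and their assumptions,
every tunable parameter with units and defaults, what the synthetic world
does and does not emulate, the numerical choices (EM initialization and
regularization, Jensen correction of the α fit, tie rules), and known
limitations — including an identifiability limit on window-level F1/F2
proportion recovery that the test suite reports honestly.
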