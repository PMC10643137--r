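# Named benchmark scenarios: labelled trajectory collections whose
# parameter scales follow the published measurements (20 ms free/bound
# mixtures, 500 ms S/F1/F2 substates, the time-lapse ladder, 2D locus
# tracks). These are the inputs of the end-to-end validation tests.

# D parameter giving a target apparent diffusion coefficient at lag 1:
# for fBM, MSD_1axis(t) = 2 D t^alpha, so D_app(lag 1) = D dt^(alpha - 1).
.d_for_dapp <- function(d_app, alpha, dt) d_app * dt^(1 - alpha)

#' Generate a labelled benchmark trajectory collection
#'
#' Scenarios:
#' \describe{
#'   \item{`stage1_20ms`}{3D tracks at 20 ms: a mixture of freely
#'     diffusing molecules (fBM, alpha 0.94, `D_app` 1.3 um^2/s) and
#'     chromatin-bound molecules (fBM, alpha 0.51, `D_app` 0.43 um^2/s),
#'     each track entirely one state; 60 nm localization noise.}
#'   \item{`stage2_500ms`}{3D tracks at 500 ms emulating chromatin-bound
#'     molecules switching among three substates: S (alpha 0.59, `D_app`
#'     0.006), F1 (alpha 0.60, `D_app` 0.018) and F2 (alpha 0.89, `D_app`
#'     0.018 plus directed drift); stationary occupancies 0.67/0.26/0.07;
#'     34 nm noise.}
#'   \item{`timelapse`}{geometric track-length table over the lapse ladder
#'     `{0.5, 2.5, 8, 32}` s (see [simulate_timelapse()]).}
#'   \item{`locus2d`}{2D confined (Ornstein-Uhlenbeck) locus tracks at
#'     500 ms, emulating dCas9-labelled enhancer loci.}
#' }
#'
#' @param scenario scenario name (see above).
#' @param seed integer seed; output is fully reproducible.
#' @param n_tracks number of tracks (default depends on the scenario).
#' @return For trajectory scenarios, a list with `trajectories` (list of
#'   [trajectory()]), `states` (list of per-frame true state labels,
#'   aligned with the trajectories) and `meta` (generator parameters).
#'   For `timelapse`, a list with `series` (data frame for
#'   [timelapse_model()]) and `meta`.
#' @export
make_benchmark_suite <- function(scenario = c("stage1_20ms", "stage2_500ms",
                                              "timelapse", "locus2d"),
                                 seed = 1L, n_tracks = NULL) {
  scenario <- tryCatch(match.arg(scenario), error = function(e)
    stop("unknown scenario; options: stage1_20ms, stage2_500ms, timelapse, locus2d"))
  switch(scenario,
    stage1_20ms = {
      n_tracks <- n_tracks %||% 500L
      dt <- 0.02
      meta <- list(dt = dt, noise_sd = 0.06, frac_bound = 0.5,
                   free = list(alpha = 0.94, d_app = 1.3),
                   bound = list(alpha = 0.51, d_app = 0.43))
      free_spec <- function(n) motion_spec("fbm", dim = 3L, dt = dt, n_frames = n,
                                           D = .d_for_dapp(1.3, 0.94, dt), alpha = 0.94)
      bound_spec <- function(n) motion_spec("fbm", dim = 3L, dt = dt, n_frames = n,
                                            D = .d_for_dapp(0.43, 0.51, dt), alpha = 0.51)
      with_seed(derive_seed(seed, "stage1"), {
        trajs <- vector("list", n_tracks)
        states <- vector("list", n_tracks)
        for (i in seq_len(n_tracks)) {
          n <- 15L + rgeom(1L, 1 / 25)
          n <- min(max(n, 15L), 100L)
          bound <- runif(1) < meta$frac_bound
          sim <- simulate_trajectory(
            if (bound) bound_spec(n) else free_spec(n),
            noise_spec(sd_xy = meta$noise_sd),
            id = sprintf("s1_%04d", i))
          trajs[[i]] <- sim$traj
          states[[i]] <- rep(if (bound) "bound" else "free", n_frames(sim$traj))
        }
        list(trajectories = trajs, states = states, meta = meta)
      })
    },
    stage2_500ms = {
      n_tracks <- n_tracks %||% 100L
      dt <- 0.5
      probs <- c(S = 0.67, F1 = 0.26, F2 = 0.07)
      # mean state dwell 30 s: substate periods must be long relative to
      # the 5.5 s window for the two-stage analysis to be meaningful, and
      # bound residence times in this system are on the minute scale
      meta <- list(dt = dt, noise_sd = 0.034, state_probs = probs,
                   switch_rate = 1 / 30, n_frames = 120L,
                   S = list(alpha = 0.59, d_app = 0.006),
                   F1 = list(alpha = 0.60, d_app = 0.018),
                   F2 = list(alpha = 0.89, d_app = 0.018, drift = 0.03))
      with_seed(derive_seed(seed, "stage2"), {
        trajs <- vector("list", n_tracks)
        states <- vector("list", n_tracks)
        for (i in seq_len(n_tracks)) {
          theta <- runif(1, 0, 2 * pi); phi <- acos(runif(1, -1, 1))
          v2 <- meta$F2$drift * c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
          spec <- motion_spec(
            "switching", dim = 3L, dt = dt, n_frames = meta$n_frames,
            rates = meta$switch_rate, state_probs = probs,
            states = list(
              S = motion_spec("fbm", dim = 3L, dt = dt,
                              D = .d_for_dapp(0.006, 0.59, dt), alpha = 0.59),
              F1 = motion_spec("fbm", dim = 3L, dt = dt,
                               D = .d_for_dapp(0.018, 0.60, dt), alpha = 0.60),
              F2 = motion_spec("fbm", dim = 3L, dt = dt,
                               D = .d_for_dapp(0.018, 0.89, dt), alpha = 0.89,
                               velocity = v2)))
          sim <- simulate_trajectory(spec, noise_spec(sd_xy = meta$noise_sd),
                                     id = sprintf("s2_%04d", i))
          trajs[[i]] <- sim$traj
          states[[i]] <- sim$states
        }
        list(trajectories = trajs, states = states, meta = meta)
      })
    },
    timelapse = {
      n_tracks <- n_tracks %||% 5000L
      meta <- list(k_bleach = 0.5, k_off = 0.01, taus = c(0.5, 2.5, 8, 32),
                   t_int = 0.5)
      list(series = simulate_timelapse(meta$k_bleach, meta$k_off, meta$taus,
                                       meta$t_int, n_tracks,
                                       seed = derive_seed(seed, "timelapse")),
           meta = meta)
    },
    locus2d = {
      n_tracks <- n_tracks %||% 60L
      dt <- 0.5
      meta <- list(dt = dt, noise_sd = 0.03, sd = 0.15, t_rel = 10,
                   n_frames = 100L)
      with_seed(derive_seed(seed, "locus2d"), {
        trajs <- vector("list", n_tracks)
        for (i in seq_len(n_tracks)) {
          sim <- simulate_trajectory(
            motion_spec("confined_ou", dim = 2L, dt = dt,
                        n_frames = meta$n_frames, sd = meta$sd,
                        t_rel = meta$t_rel),
            noise_spec(sd_xy = meta$noise_sd), id = sprintf("loc_%04d", i))
          trajs[[i]] <- sim$traj
        }
        list(trajectories = trajs,
             states = lapply(trajs, function(t) rep("confined_ou", n_frames(t))),
             meta = meta)
      })
    })
}
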