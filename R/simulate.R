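# Ground-truth trajectory generators. These are the package's stand-in for
# raw imaging data: every estimator and classifier is validated against
# them. Fractional Gaussian noise uses exact-covariance circulant
# embedding (Davies-Harte), falling back to Cholesky for short paths or
# when the embedding is not non-negative definite.

#' Motion specification for the trajectory simulator
#'
#' @param kind one of `"brownian"`, `"fbm"`, `"confined_ou"`, `"directed"`,
#'   `"switching"`.
#' @param dim spatial dimensionality (2 or 3).
#' @param dt frame interval (s).
#' @param n_frames number of frames to simulate.
#' @param D diffusion coefficient in um^2/s. For `fbm`, `D` is the
#'   generalized coefficient in `MSD_1axis(t) = 2 D t^alpha`.
#' @param alpha anomalous exponent target for `fbm`, in (0, 2].
#' @param sd stationary positional SD per axis (um) for `confined_ou`.
#' @param t_rel relaxation time (s) for `confined_ou`.
#' @param velocity drift velocity vector (um/s) for `directed` (recycled to
#'   `dim`).
#' @param states named list of sub-`motion_spec`s for `"switching"`
#'   (without `n_frames`; dims must agree).
#' @param rates for `"switching"`: either a single switching rate (s^-1,
#'   exponential holding times; the next state is drawn from
#'   `state_probs`) or `NULL`.
#' @param state_probs stationary probabilities of the states for
#'   `"switching"` (drawn independently at each switch, so these are also
#'   the time-stationary occupancies).
#' @return A list of class `nd_motion_spec`.
#' @export
motion_spec <- function(kind = c("brownian", "fbm", "confined_ou", "directed",
                                 "switching"),
                        dim = 3L, dt = 0.02, n_frames = 100L,
                        D = 1, alpha = 1, sd = 0.05, t_rel = 1,
                        velocity = NULL, states = NULL, rates = NULL,
                        state_probs = NULL) {
  kind <- match.arg(kind)
  stopifnot(dt > 0, dim %in% c(2L, 3L), n_frames >= 2L)
  if (kind == "fbm" && (alpha <= 0 || alpha > 2)) stop("alpha must be in (0, 2]")
  if (kind == "switching") {
    if (is.null(states) || length(states) < 2L) stop("switching needs >= 2 states")
    dims <- vapply(states, function(s) s$dim, 0L)
    if (length(unique(dims)) != 1L || dims[1] != dim)
      stop("inconsistent dims among switching sub-specs")
    if (is.null(rates) || any(rates < 0)) stop("switching needs a rate >= 0")
    if (is.null(state_probs)) state_probs <- rep(1 / length(states), length(states))
    state_probs <- state_probs / sum(state_probs)
  }
  structure(list(kind = kind, dim = as.integer(dim), dt = dt,
                 n_frames = as.integer(n_frames), D = D, alpha = alpha,
                 sd = sd, t_rel = t_rel,
                 velocity = if (!is.null(velocity)) rep_len(velocity, dim),
                 states = states, rates = rates, state_probs = state_probs),
            class = "nd_motion_spec")
}

#' Measurement-noise specification
#'
#' @param sd_xy lateral localization SD (um) added per frame and axis.
#' @param sd_z axial localization SD (um); defaults to isotropic.
#' @param bleach_rate photobleaching rate per exposure (per-frame survival
#'   `exp(-bleach_rate)`); 0 disables truncation.
#' @param gap_prob probability a frame goes undetected (detection gap);
#'   gaps split trajectories downstream, so the default is 0.
#' @return A list of class `nd_noise_spec`.
#' @export
noise_spec <- function(sd_xy = 0, sd_z = sd_xy, bleach_rate = 0, gap_prob = 0) {
  stopifnot(sd_xy >= 0, sd_z >= 0, bleach_rate >= 0,
            gap_prob >= 0, gap_prob <= 1)
  structure(list(sd_xy = sd_xy, sd_z = sd_z, bleach_rate = bleach_rate,
                 gap_prob = gap_prob), class = "nd_noise_spec")
}

# Exact fractional Gaussian noise, unit-time-step, Var = 1 per increment.
# Returns n increments of standard fBM with Hurst exponent H.
fgn <- function(n, H) {
  if (abs(H - 0.5) < 1e-12) return(rnorm(n))
  g <- function(k) 0.5 * (abs(k - 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k + 1)^(2 * H))
  r <- g(0:(n - 1))
  if (n >= 2L) {
    row <- c(r, g(n), rev(r[-1]))
    ev <- Re(fft(row))
    if (min(ev) > -1e-8) {
      ev <- pmax(ev, 0)
      m <- length(row)
      half <- m %/% 2L
      W <- complex(length.out = m)
      W[1] <- rnorm(1) * sqrt(m)
      W[half + 1] <- rnorm(1) * sqrt(m)
      a <- rnorm(half - 1); b <- rnorm(half - 1)
      W[2:half] <- (a + 1i * b) * sqrt(m / 2)
      W[(half + 2):m] <- Conj(W[half:2])
      x <- Re(fft(sqrt(ev) * W, inverse = TRUE)) / m
      return(x[seq_len(n)])
    }
  }
  # Cholesky fallback (exact, O(n^3); fine for short paths)
  G <- toeplitz(r)
  L <- chol(G)
  drop(crossprod(L, rnorm(n)))
}

# n fBM positions (after the origin) with per-axis MSD(t) = 2 D t^alpha
fbm_path <- function(n, alpha, D, dt) {
  H <- alpha / 2
  inc <- fgn(n, H) * sqrt(2 * D) * dt^H
  cumsum(inc)
}

# exact OU update around centre 0 with stationary sd s, relaxation t_rel
ou_path <- function(n, s, t_rel, dt, x0 = NULL) {
  a <- exp(-dt / t_rel)
  q <- s * sqrt(1 - a^2)
  x <- numeric(n)
  prev <- if (is.null(x0)) rnorm(1, 0, s) else x0
  for (i in seq_len(n)) {
    prev <- a * prev + rnorm(1, 0, q)
    x[i] <- prev
  }
  x
}

# raw (noise-free) displacement path for one axis-set; returns n x dim
.simulate_positions <- function(spec, n, origin = rep(0, spec$dim)) {
  d <- spec$dim
  pos <- switch(spec$kind,
    brownian = ,
    directed = {
      inc <- matrix(rnorm(n * d, 0, sqrt(2 * spec$D * spec$dt)), n, d)
      apply(inc, 2L, cumsum)
    },
    fbm = vapply(seq_len(d), function(j) fbm_path(n, spec$alpha, spec$D, spec$dt),
                 numeric(n)),
    confined_ou = {
      # confinement centred on the origin point
      vapply(seq_len(d), function(j) ou_path(n, spec$sd, spec$t_rel, spec$dt),
             numeric(n))
    },
    stop("unsupported kind in .simulate_positions: ", spec$kind))
  if (n == 1L) pos <- matrix(pos, 1L, d)
  # an optional constant drift can ride on any motion kind
  if (!is.null(spec$velocity))
    pos <- pos + outer(seq_len(n) * spec$dt, spec$velocity)
  sweep(pos, 2L, origin, `+`)
}

#' Simulate a single trajectory with ground-truth state labels
#'
#' Generates the true motion path per the motion spec, then applies
#' measurement noise, photobleaching truncation (geometric by per-frame
#' survival `exp(-bleach_rate)`) and detection gaps. For `"switching"`
#' motion a continuous-time Markov chain with exponential holding times
#' selects among the sub-specs; each segment is generated independently
#' starting from the previous endpoint (the fractional-Gaussian memory is
#' reset at switches).
#'
#' @param motion an [motion_spec()].
#' @param noise an [noise_spec()].
#' @param id trajectory identifier.
#' @param seed integer seed (reproducible; `NULL` uses the current RNG
#'   stream).
#' @return List with `traj` (an [trajectory()], or `NULL` if truncation
#'   left fewer than 2 frames) and `states` (character vector of true
#'   per-frame state names; the motion kind, or the sub-spec name for
#'   switching).
#' @export
simulate_trajectory <- function(motion, noise = noise_spec(), id = "sim",
                                seed = NULL) {
  run <- function() {
    n <- motion$n_frames
    if (motion$kind == "switching") {
      nm <- names(motion$states) %||% paste0("state", seq_along(motion$states))
      # CTMC: exponential holding at `rates`, next state drawn from
      # state_probs (may repeat), sampled on the frame grid
      state_idx <- integer(n)
      t_end <- 0
      cur <- sample.int(length(motion$states), 1L, prob = motion$state_probs)
      i <- 1L
      while (i <= n) {
        hold <- rexp(1, motion$rates)
        n_hold <- max(1L, round(hold / motion$dt))
        j <- min(n, i + n_hold - 1L)
        state_idx[i:j] <- cur
        i <- j + 1L
        cur <- sample.int(length(motion$states), 1L, prob = motion$state_probs)
      }
      pos <- matrix(0, n, motion$dim)
      origin <- rep(0, motion$dim)
      r <- rle(state_idx)
      at <- 1L
      for (seg in seq_along(r$values)) {
        len <- r$lengths[seg]
        sub <- motion$states[[r$values[seg]]]
        sub$dt <- motion$dt
        seg_pos <- .simulate_positions(sub, len, origin)
        if (sub$kind == "confined_ou") {
          # confine around the entry point rather than the global origin
          seg_pos <- sweep(seg_pos, 2L, origin, `-`)
          seg_pos <- sweep(seg_pos - matrix(seg_pos[1, ], len, motion$dim, byrow = TRUE),
                           2L, origin, `+`)
        }
        pos[at:(at + len - 1L), ] <- seg_pos
        origin <- pos[at + len - 1L, ]
        at <- at + len
      }
      states <- nm[state_idx]
    } else {
      pos <- .simulate_positions(motion, n)
      states <- rep(motion$kind, n)
    }
    # photobleaching truncation
    if (noise$bleach_rate > 0) {
      surv <- exp(-noise$bleach_rate)
      n_obs <- min(n, 1L + rgeom(1L, 1 - surv))
      pos <- pos[seq_len(n_obs), , drop = FALSE]
      states <- states[seq_len(n_obs)]
      n <- n_obs
    }
    if (n < 2L) return(list(traj = NULL, states = states))
    # localization noise
    sds <- c(noise$sd_xy, noise$sd_xy, noise$sd_z)[seq_len(motion$dim)]
    obs <- pos + matrix(rnorm(n * motion$dim), n, motion$dim) %*% diag(sds, motion$dim)
    keep <- if (noise$gap_prob > 0) runif(n) >= noise$gap_prob else rep(TRUE, n)
    if (sum(keep) < 2L) return(list(traj = NULL, states = states[keep]))
    # gaps split the track; keep the longest consecutive run
    if (!all(keep)) {
      runs <- rle(keep)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      kept_runs <- which(runs$values)
      best <- kept_runs[which.max(runs$lengths[kept_runs])]
      sel <- starts[best]:ends[best]
    } else sel <- seq_len(n)
    if (length(sel) < 2L) return(list(traj = NULL, states = states[sel]))
    list(traj = trajectory(id, motion$dt, seq_along(sel) - 1L,
                           obs[sel, , drop = FALSE]),
         states = states[sel])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate time-lapse imaging track lengths
#'
#' Draws geometric track lengths under per-frame survival
#' `exp(-(k_bleach * t_int + k_off * tau))` for each lapse condition:
#' the generator matched by [timelapse_model()].
#'
#' @param k_bleach bleach rate per second of exposure.
#' @param k_off chromatin unbinding rate (s^-1).
#' @param taus lapse intervals (s); the published ladder is
#'   `c(0.5, 2.5, 8, 32)`.
#' @param t_int integration (exposure) time (s).
#' @param n_tracks tracks per condition.
#' @param seed integer seed.
#' @return Data frame with columns `tau`, `t_int`, `n_frames`.
#' @export
simulate_timelapse <- function(k_bleach, k_off, taus = c(0.5, 2.5, 8, 32),
                               t_int = 0.5, n_tracks = 5000L, seed = 1L) {
  with_seed(seed, {
    do.call(rbind, lapply(taus, function(tau) {
      p <- exp(-(k_bleach * t_int + k_off * tau))
      data.frame(tau = tau, t_int = t_int,
                 n_frames = 1L + rgeom(n_tracks, 1 - p))
    }))
  })
}
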