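test_that("TA-MSD matches closed forms", {
  # stationary points: zero MSD at every lag
  pos <- matrix(0.3, nrow = 11, ncol = 3)
  expect_equal(ta_msd(pos, 0.02, 5), rep(0, 5))

  # 1D ballistic x = v k dt: MSD(l) = (v l dt)^2 exactly
  v <- 2.4; dt <- 0.02
  pos <- cbind(x = v * (0:10) * dt)
  expect_equal(ta_msd(pos, dt, 5), (v * (1:5) * dt)^2, tolerance = 1e-12)

  expect_error(ta_msd(pos[1:4, , drop = FALSE], dt, 5), "too short")
})

test_that("alpha estimator is exact on power-law MSD", {
  dt <- 0.02
  # ballistic MSD ~ t^2 and Brownian MSD = 6 D t
  msd_ball <- (3.1 * (1:5) * dt)^2
  expect_equal(estimate_alpha(msd_ball, dt), 2, tolerance = 1e-10)
  msd_bro <- 6 * 0.7 * (1:5) * dt
  expect_equal(estimate_alpha(msd_bro, dt), 1, tolerance = 1e-10)
  # exact general power law
  for (a in c(0.4, 0.7, 1.3)) {
    expect_equal(estimate_alpha(0.05 * ((1:5) * dt)^a, dt), a, tolerance = 1e-10)
  }
  # degenerate window flagged
  expect_true(is.na(estimate_alpha(c(0, msd_bro[-1]), dt)))
})

test_that("alpha estimates on exact fBM are centred on the target", {
  for (a in c(0.4, 0.7, 1.0)) {
    sim <- simulate_trajectory(
      motion_spec("fbm", dim = 3, dt = 0.02, n_frames = 6000, D = 0.5, alpha = a),
      id = "fbm", seed = 100 + round(100 * a))
    f <- sliding_features(sim$traj, window_config())
    expect_lt(abs(mean(f$alpha, na.rm = TRUE) - a), 0.05)
  }
})

test_that("D_app, Lc and drift follow their definitions and invariances", {
  dt <- 0.02
  # stationary emitter
  pos0 <- matrix(1, 11, 3)
  expect_equal(estimate_dapp(ta_msd(pos0, dt, 5), dt, 3), 0)
  expect_equal(estimate_lc(pos0), 0)
  expect_equal(estimate_drift(pos0, dt)$norm, 0)

  # two points at +/- r on one axis: Lc = r
  r <- 0.37
  expect_equal(estimate_lc(rbind(c(-r, 0, 0), c(r, 0, 0))), r)

  # constant velocity: drift_norm = |v| exactly
  v <- c(0.3, -0.4, 1.2)
  pos <- outer(0:10 * dt, v)
  expect_equal(estimate_drift(pos, dt)$norm, sqrt(sum(v^2)), tolerance = 1e-12)

  # rotation/translation invariance of d_app and lc; rotation invariance
  # of drift_norm (random windows, random rigid motions)
  set.seed(42)
  for (i in 1:10) {
    w <- matrix(rnorm(33, sd = 0.3), 11, 3)
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    shift <- rnorm(3, sd = 5)
    w2 <- sweep(w %*% R, 2, shift, `+`)
    expect_equal(estimate_lc(w2), estimate_lc(w), tolerance = 1e-10)
    expect_equal(estimate_dapp(ta_msd(w2, dt, 5), dt, 3),
                 estimate_dapp(ta_msd(w, dt, 5), dt, 3), tolerance = 1e-10)
    expect_equal(estimate_drift(w2, dt)$norm, estimate_drift(w, dt)$norm,
                 tolerance = 1e-10)
  }
})

test_that("ensemble means match diffusion closed forms", {
  # 3D Brownian: E[MSD(1)] = 6 D dt and E[d_app] = D
  D <- 1; dt <- 0.02
  sim <- simulate_trajectory(
    motion_spec("brownian", dim = 3, dt = dt, n_frames = 20000, D = D),
    id = "b", seed = 77)
  f <- sliding_features(sim$traj, window_config())
  expect_lt(abs(mean(f$d_app) - D), 3 * sd(f$d_app) / sqrt(nrow(f) / 11))

  # localization noise inflates MSD(1): sigma = 0.06 um on a stationary
  # emitter gives E[MSD(1)] = 2 * dim * sigma^2
  set.seed(5)
  sims <- replicate(300, {
    obs <- matrix(rnorm(33, 0, 0.06), 11, 3)
    ta_msd(obs, dt, 1)[1]
  })
  expect_equal(mean(sims), 2 * 3 * 0.06^2, tolerance = 0.05)
})

test_that("confined motion Lc approaches sd * sqrt(dim)", {
  # fast relaxation (t_rel = dt) makes window points near-independent, so
  # the OU stationary closed form applies with the exact iid centroid
  # correction: E|x - xbar|^2 = dim * s^2 * (1 - 1/n)
  s <- 0.05
  sim <- simulate_trajectory(
    motion_spec("confined_ou", dim = 3, dt = 0.02, n_frames = 30000,
                sd = s, t_rel = 0.02),
    id = "ou", seed = 9)
  f <- sliding_features(sim$traj, window_config())
  want <- s * sqrt(3 * (1 - 1 / 11))
  expect_lt(abs(mean(f$lc) - want), 0.005)
  # and the long-run spread matches the stationary SD itself
  expect_lt(abs(sd(sim$traj$pos[, 1]) - s), 0.005)
})

test_that("sliding window counts and transitions behave", {
  tr <- mk_traj(matrix(rnorm(33), 11, 3))
  expect_equal(nrow(sliding_features(tr, window_config())), 1)
  tr20 <- mk_traj(matrix(rnorm(60), 20, 3))
  expect_equal(nrow(sliding_features(tr20, window_config())), 10)
  expect_message(
    out <- sliding_features(mk_traj(matrix(rnorm(15), 5, 3)), window_config()),
    "skipping")
  expect_equal(nrow(out), 0)

  # piecewise trajectory: confined half then ballistic half moves the
  # alpha series from < 1 to ~2 across the junction
  set.seed(3)
  n <- 60
  conf <- vapply(1:3, function(j) 0.03 * rnorm(n), numeric(n))
  ball <- outer(1:n * 0.02, c(1.5, 0, 0)) +
    matrix(rnorm(3 * n, 0, 1e-4), n, 3)
  tr2 <- mk_traj(rbind(conf, sweep(ball, 2, conf[n, ], `+`)))
  f <- sliding_features(tr2, window_config())
  expect_lt(mean(f$alpha[1:20], na.rm = TRUE), 1)
  expect_gt(mean(f$alpha[81:100], na.rm = TRUE), 1.8)
})

test_that("precision floor reproduces the printed measurability bounds", {
  expect_equal(precision_floor(0.06, 0.02), 0.18, tolerance = 1e-12)
  expect_equal(round(precision_floor(0.034, 0.5), 3), 0.002)
  expect_equal(precision_floor(0, 1), 0)
  expect_error(precision_floor(0.06, 0), "exposure")
  expect_error(precision_floor(-0.01, 1), "sigma")
})

test_that("adding isotropic noise never decreases mean MSD(1)", {
  set.seed(21)
  for (i in 1:5) {
    path <- matrix(cumsum(rnorm(900, 0, 0.05)), 300, 3)
    clean <- mean(ta_msd(path, 0.02, 1))
    noisy <- mean(replicate(20, {
      obs <- path + matrix(rnorm(900, 0, 0.05), 300, 3)
      ta_msd(obs, 0.02, 1)
    }))
    expect_gte(noisy, clean)
  }
})
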