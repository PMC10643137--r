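# helpers to fabricate window-feature tables around known 4D Gaussians
fake_features <- function(n, mu, sd = rep(0.05, 4), traj_id = "t") {
  data.frame(traj_id = traj_id, window = seq_len(n), start_frame = seq_len(n),
             center_frame = seq_len(n),
             alpha = rnorm(n, mu[1], sd[1]), d_app = rnorm(n, mu[2], sd[2]),
             lc = rnorm(n, mu[3], sd[3]), drift_norm = rnorm(n, mu[4], sd[4]),
             dim = 3L, valid = TRUE)
}

test_that("the mixture recovers well-separated populations", {
  set.seed(1)
  mu_c <- c(0.5, 0.4, 0.2, 1)    # confined: low alpha, low d_app
  mu_u <- c(1.0, 1.4, 0.7, 4)
  feats <- rbind(fake_features(1000, mu_c, traj_id = "a"),
                 fake_features(1000, mu_u, traj_id = "b"))
  model <- fit_state_model(feats, seed = 3)
  conf <- model$confined_component
  unconf <- 3 - conf
  se <- 0.05 / sqrt(1000)
  expect_true(all(abs(model$means_original[conf, ] - mu_c) < 3 * se + 0.01))
  expect_true(all(abs(model$means_original[unconf, ] - mu_u) < 3 * se + 0.01))
  expect_false(model$overlap)

  cls <- classify_windows(model, feats)
  truth <- rep(c("confined", "unconfined"), each = 1000)
  expect_gte(mean(cls$label == truth), 0.99)
})

test_that("the fit is deterministic and order-invariant given the seed", {
  set.seed(2)
  feats <- rbind(fake_features(200, c(0.5, 0.4, 0.2, 1)),
                 fake_features(200, c(1.0, 1.4, 0.7, 4)))
  m1 <- fit_state_model(feats, seed = 7)
  m2 <- fit_state_model(feats[sample(nrow(feats)), ], seed = 7)
  expect_identical(m1$mixture$means, m2$mixture$means)
  expect_identical(m1$mixture$covariances, m2$mixture$covariances)
  expect_identical(m1$mixture$weights, m2$mixture$weights)
})

test_that("single-population input triggers the overlap diagnostic", {
  set.seed(3)
  feats <- fake_features(600, c(0.8, 0.8, 0.4, 2), sd = rep(0.1, 4))
  model <- fit_state_model(feats, seed = 1)
  expect_true(model$overlap)
  # degenerate split: means within ~1 SD of each other per coordinate
  expect_lt(model$separation, 1)
})

test_that("posteriors are proper probabilities with the strict tie rule", {
  set.seed(4)
  feats <- rbind(fake_features(500, c(0.5, 0.4, 0.2, 1)),
                 fake_features(500, c(1.0, 1.4, 0.7, 4)))
  model <- fit_state_model(feats, seed = 5)
  cls <- classify_windows(model, feats)
  # responsibilities sum to 1 across components
  Z <- sweep(sweep(as.matrix(feats[model$feat_cols]), 2, model$center),
             2, model$scale, `/`)
  R <- nucdyn:::gmm_posterior(model$mixture, Z)
  expect_true(all(abs(rowSums(R) - 1) <= 1e-12))

  # a vector at the confined component mean classifies with P > 0.99
  at_mean <- feats[1, ]
  at_mean[model$feat_cols] <- as.list(model$means_original[model$confined_component, ])
  expect_gt(classify_windows(model, at_mean)$posterior, 0.99)

  # invalid alpha -> unassigned
  bad <- feats[1, ]; bad$valid <- FALSE; bad$alpha <- NA
  expect_equal(classify_windows(model, bad)$label, "unassigned")

  # batch equals one-by-one
  one_by_one <- vapply(seq_len(20), function(i)
    classify_windows(model, feats[i, ])$posterior, numeric(1))
  expect_equal(cls$posterior[1:20], one_by_one, tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(6)
  X <- rbind(matrix(rnorm(400, 0), 100, 4), matrix(rnorm(400, 3), 100, 4))
  fit <- nucdyn:::gmm_fit(X, 2, seed = 1, n_init = 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * (1 + abs(fit$loglik))))
})

test_that("window labels map onto timepoints by the centre/nearest rule", {
  cfg <- window_config(11)
  tr <- mk_traj(matrix(rnorm(25 * 3, sd = 0.1), 25, 3))
  n_win <- 25 - 11 + 1
  windows <- data.frame(window = 1:n_win, posterior = runif(n_win))
  frames <- windows_to_timepoints(windows, tr, cfg)
  expect_equal(nrow(frames), 25)
  # direct index-arithmetic oracle: frame j takes window clamp(j - 5)
  want <- windows$posterior[pmin(pmax(1:25 - 5, 1), n_win)]
  expect_equal(frames$posterior, want)
  expect_equal(frames$label, ifelse(want > 0.5, "confined", "unconfined"))

  # uniform labels stay uniform; a single window switch gives exactly one
  # frame-label boundary
  wu <- transform(windows, posterior = 0.9)
  expect_true(all(windows_to_timepoints(wu, tr, cfg)$label == "confined"))
  ws <- transform(windows, posterior = rep(c(0.9, 0.1), c(7, n_win - 7)))
  lab <- windows_to_timepoints(ws, tr, cfg)$label
  expect_equal(sum(lab[-1] != lab[-25]), 1)
})

test_that("state fractions count windows and trajectories correctly", {
  lab <- function(id, labels) data.frame(traj_id = id, label = labels)
  all_conf <- lab("a", rep("confined", 10))
  expect_equal(unname(state_fractions(all_conf, "windows")), c(1, 0))

  # 3 confined-majority + 1 unconfined-majority trajectories
  coll <- rbind(lab("a", rep("confined", 5)),
                lab("b", c(rep("confined", 3), "unconfined")),
                lab("c", rep("confined", 2)),
                lab("d", c("confined", rep("unconfined", 4))))
  expect_equal(unname(state_fractions(coll, "trajectories")), c(0.75, 0.25))

  expect_error(state_fractions(lab("a", rep("unassigned", 4))), "undefined")
})

test_that("two-state switching occupancy is recovered at the window level", {
  # directly fabricated windows at known occupancy 0.7/0.3
  set.seed(8)
  n <- 10000
  is_conf <- runif(n) < 0.7
  feats <- rbind(fake_features(sum(is_conf), c(0.5, 0.4, 0.2, 1)),
                 fake_features(n - sum(is_conf), c(1.0, 1.4, 0.7, 4)))
  model <- fit_state_model(feats, seed = 2, n_init = 4)
  cls <- classify_windows(model, feats)
  fr <- state_fractions(cls, "windows")
  expect_lt(abs(fr["confined"] - 0.7), 0.03)
})
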