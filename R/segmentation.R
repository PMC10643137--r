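# optional log transform of the scale-type features before standardizing
.apply_feat_transform <- function(X, transform) {
  if (transform == "log") {
    sc <- c("d_app", "lc", "drift_norm")
    X[, sc] <- log(pmax(X[, sc], 1e-12))
  }
  X
}

#' Fit the confined/unconfined state model on pooled window features
#'
#' Fits a full-covariance Gaussian mixture (expectation-maximization,
#' k-means++ seeding, `n_init` restarts) to the standardized 4D feature
#' vectors `(alpha, d_app, lc, drift_norm)` pooled over all trajectories.
#' The confined (chromatin-bound) component is the one with the smaller
#' mean `d_app` on the original scale (ties broken by smaller mean
#' `alpha`), which makes the labelling canonical regardless of component
#' order. Features are z-scored before EM because the four parameters have
#' incommensurate units; the transform is stored in the model.
#'
#' @param features pooled feature data frame from [pooled_features()] /
#'   [sliding_features()]; rows with `valid = FALSE` are excluded.
#' @param n_components number of mixture components (2 for Stage 1).
#' @param seed integer seed; the fit is deterministic given the seed and
#'   invariant to the ordering of the input rows.
#' @param n_init number of EM restarts (best likelihood kept).
#' @param transform `"identity"` (default) fits the mixture on the raw
#'   parameters; `"log"` log-transforms the scale parameters (`d_app`,
#'   `lc`, `drift_norm`) first, which calibrates the split better for
#'   low-mobility (500 ms) data whose parameters are near-lognormal with
#'   modes less than a decade apart. `alpha` is never transformed.
#' @return An object of class `nd_state_model`: mixture parameters (on the
#'   standardized scale), the standardization transform, the index of the
#'   confined component, component means on the original scale, and an
#'   overlap diagnostic (`TRUE` when component means lie within 1 pooled
#'   SD of each other, indicating a degenerate split).
#' @export
fit_state_model <- function(features, n_components = 2L, seed = 1L, n_init = 10L,
                            transform = c("identity", "log")) {
  transform <- match.arg(transform)
  feat_cols <- c("alpha", "d_app", "lc", "drift_norm")
  ok <- features$valid & stats::complete.cases(features[feat_cols])
  X <- as.matrix(features[ok, feat_cols])
  if (nrow(X) < 10L * n_components)
    stop("insufficient data: ", nrow(X), " valid windows < ", 10L * n_components)
  X <- .apply_feat_transform(X, transform)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  fit <- gmm_fit(Z, k = n_components, seed = seed, n_init = n_init)
  means_orig <- sweep(sweep(fit$means, 2L, scl, `*`), 2L, ctr, `+`)
  colnames(means_orig) <- feat_cols
  if (transform == "log")
    means_orig[, c("d_app", "lc", "drift_norm")] <-
      exp(means_orig[, c("d_app", "lc", "drift_norm")])
  d_app_means <- means_orig[, "d_app"]
  conf <- which(d_app_means == min(d_app_means))
  if (length(conf) > 1L) conf <- conf[which.min(means_orig[conf, "alpha"])]
  # separation of component means in units of their average per-axis SD
  sep <- Inf
  if (n_components >= 2L) {
    pairs <- utils::combn(n_components, 2L)
    sep <- min(apply(pairs, 2L, function(p) {
      v1 <- diag(fit$covariances[, , p[1]]); v2 <- diag(fit$covariances[, , p[2]])
      sqrt(mean((fit$means[p[1], ] - fit$means[p[2], ])^2 / (0.5 * (v1 + v2))))
    }))
  }
  structure(list(mixture = fit, center = ctr, scale = scl,
                 transform = transform,
                 feat_cols = feat_cols,
                 means_original = means_orig,
                 confined_component = unname(conf),
                 n_components = n_components,
                 separation = sep, overlap = sep < 1,
                 n_windows = nrow(X), seed = seed),
            class = "nd_state_model")
}

#' @export
print.nd_state_model <- function(x, ...) {
  cat(sprintf("<nd_state_model> %d components fitted on %d windows\n",
              x$n_components, x$n_windows))
  cat("component means (original scale):\n")
  print(round(x$means_original, 4))
  cat(sprintf("confined component: %d; separation %.2f SD%s\n",
              x$confined_component, x$separation,
              if (x$overlap) " [overlap diagnostic: degenerate split]" else ""))
  invisible(x)
}

#' Classify sliding windows as confined or unconfined
#'
#' Evaluates the mixture's posterior responsibility of the confined
#' component for each window; a window is confined when `P > 0.5` (a tie at
#' exactly 0.5 goes to unconfined, the strict reading of `P > 1 - P`).
#' Windows flagged invalid (degenerate alpha) are labelled `unassigned`.
#'
#' @param model an [fit_state_model()] result.
#' @param features feature data frame.
#' @return The feature data frame with added columns `posterior` (confined
#'   membership probability) and `label` in
#'   `c("confined", "unconfined", "unassigned")`.
#' @export
classify_windows <- function(model, features) {
  out <- features
  out$posterior <- NA_real_
  out$label <- "unassigned"
  ok <- features$valid & stats::complete.cases(features[model$feat_cols])
  if (any(ok)) {
    X <- as.matrix(features[ok, model$feat_cols])
    X <- .apply_feat_transform(X, model$transform %||% "identity")
    Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
    R <- gmm_posterior(model$mixture, Z)
    p <- R[, model$confined_component]
    out$posterior[ok] <- p
    out$label[ok] <- ifelse(p > 0.5, "confined", "unconfined")
  }
  out
}

#' Propagate window labels to per-timepoint labels
#'
#' Each frame takes the posterior of the window centred on it; the first
#' and last `(window_len - 1)/2` frames, which no window centre reaches,
#' take the nearest window's posterior. Labels follow `P > 0.5`.
#'
#' @param windows classified window data frame for one trajectory
#'   (from [classify_windows()]; must carry `window` and `posterior`).
#' @param traj the trajectory the windows came from.
#' @param config the [window_config()] used to build the windows.
#' @return Data frame with one row per frame: `traj_id`, `frame`,
#'   `posterior`, `label`, plus the source window's `alpha` and index.
#' @export
windows_to_timepoints <- function(windows, traj, config = window_config()) {
  w <- config$window_len
  half <- (w - 1L) %/% 2L
  n <- n_frames(traj)
  n_win <- nrow(windows)
  if (n_win == 0L) {
    return(data.frame(traj_id = traj$id, frame = traj$frames,
                      posterior = NA_real_, label = "unassigned",
                      alpha = NA_real_, window = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  if (n_win != n - w + 1L) stop("windows do not match trajectory length")
  widx <- pmin(pmax(seq_len(n) - half, 1L), n_win)
  p <- windows$posterior[widx]
  lab <- ifelse(is.na(p), "unassigned", ifelse(p > 0.5, "confined", "unconfined"))
  a <- if (is.null(windows$alpha)) rep(NA_real_, n_win) else windows$alpha
  data.frame(traj_id = traj$id, frame = traj$frames,
             posterior = p, label = lab,
             alpha = a[widx], window = widx,
             stringsAsFactors = FALSE)
}

#' State fractions over a collection of labelled material
#'
#' `by = "windows"` reports the share of assigned windows (or frames) per
#' state. `by = "trajectories"` counts a trajectory toward a state when at
#' least half of its assigned frames carry that label (majority rule).
#' Fractions are over assigned material only and sum to 1.
#'
#' @param labels either a data frame with columns `traj_id` and `label`, or
#'   a list of such data frames (row-bound internally).
#' @param by `"windows"` or `"trajectories"`.
#' @return Named numeric vector of fractions for `confined` and
#'   `unconfined`.
#' @export
state_fractions <- function(labels, by = c("windows", "trajectories")) {
  by <- match.arg(by)
  if (is.list(labels) && !is.data.frame(labels)) labels <- do.call(rbind, labels)
  lab <- labels$label
  assigned <- lab %in% c("confined", "unconfined")
  if (!any(assigned)) stop("no assigned labels: fractions undefined")
  if (by == "windows") {
    tab <- table(factor(lab[assigned], levels = c("confined", "unconfined")))
    return(setNames(as.numeric(tab) / sum(tab), c("confined", "unconfined")))
  }
  per <- tapply(lab[assigned], labels$traj_id[assigned], function(l) {
    mean(l == "confined") >= 0.5
  })
  frac_conf <- mean(per)
  c(confined = frac_conf, unconfined = 1 - frac_conf)
}

#' End-to-end segmentation of a trajectory collection
#'
#' Convenience wrapper: pooled features, Stage-1 mixture fit, window
#' classification, and per-frame label series for every trajectory.
#'
#' @param trajs list of trajectories.
#' @param config an [window_config()].
#' @param seed seed for the mixture fit.
#' @param n_components mixture components (default 2).
#' @param transform feature transform passed to [fit_state_model()].
#' @return List with `model`, `windows` (classified feature rows), and
#'   `frames` (row-bound per-frame label series).
#' @export
segment_trajectories <- function(trajs, config = window_config(), seed = 1L,
                                 n_components = 2L,
                                 transform = c("identity", "log")) {
  feats <- pooled_features(trajs, config)
  model <- fit_state_model(feats, n_components = n_components, seed = seed,
                           transform = match.arg(transform))
  cls <- classify_windows(model, feats)
  frames <- do.call(rbind, lapply(trajs, function(tr) {
    wtr <- cls[cls$traj_id == tr$id, , drop = FALSE]
    windows_to_timepoints(wtr, tr, config)
  }))
  list(model = model, windows = cls, frames = frames)
}
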