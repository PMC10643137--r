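#' Split chromatin-bound windows into slow and fast classes (Stage 1)
#'
#' For 500 ms exposure data, motion blurring removes freely diffusing
#' molecules, so the two Stage-1 mixture components separate slow-moving /
#' immobile from fast-moving chromatin-bound molecules. The confined
#' component of the fitted model (smaller mean `d_app`) is the slow class.
#' Only trajectories passing the duration filter (strictly longer than
#' `min_duration` seconds) contribute.
#'
#' @param classified classified window data frame from [classify_windows()]
#'   on 500 ms features.
#' @param traj_durations named numeric vector mapping `traj_id` to
#'   trajectory duration in seconds (see [traj_duration()]); if `NULL`, no
#'   duration filter is applied.
#' @param min_duration duration threshold in seconds (default 5: keep
#'   trajectories that lasted more than 5 s).
#' @param model the Stage-1 model, used only for its overlap diagnostic.
#' @return List with data frames `slow` and `fast` (partition of the
#'   assigned windows; counts conserved), `n_filtered_out` trajectories,
#'   and `overlap` diagnostic flag.
#' @export
split_slow_fast <- function(classified, traj_durations = NULL,
                            min_duration = 5, model = NULL) {
  keep <- rep(TRUE, nrow(classified))
  n_filtered <- 0L
  if (!is.null(traj_durations)) {
    ok_ids <- names(traj_durations)[traj_durations > min_duration]
    n_filtered <- length(setdiff(unique(classified$traj_id), ok_ids))
    keep <- classified$traj_id %in% ok_ids
  }
  sub <- classified[keep & classified$label != "unassigned", , drop = FALSE]
  if (nrow(sub) == 0L) stop("insufficient data: duration filter removed all windows")
  slow <- sub[sub$label == "confined", , drop = FALSE]
  fast <- sub[sub$label == "unconfined", , drop = FALSE]
  list(slow = slow, fast = fast, n_filtered_out = n_filtered,
       overlap = if (!is.null(model)) model$overlap else NA)
}

#' Fit the two-component Gaussian mixture to fast-window alpha values
#' (Stage 2)
#'
#' Resolves the two fast chromatin-bound substates F1 and F2 from the
#' distribution of anomalous exponents of fast windows. Components are
#' ordered by mean: the lower-alpha component is F1, the higher is F2.
#' Proportions over the three bound states are `S = slow share` and
#' `F1/F2 = fast share x component weights`. Confidence intervals come
#' from a seeded bootstrap that resamples both the alpha values and the
#' slow/fast split (binomial on the slow count).
#'
#' @param fast_alphas numeric vector of alpha values from fast windows
#'   (>= 50 required).
#' @param n_slow number of slow windows (sets the S share).
#' @param n_boot bootstrap resamples for the confidence intervals
#'   (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Object of class `nd_alpha_fit` with `means`, `sds`, `weights`
#'   (F1, F2), `proportions` (named S, F1, F2; sums to 1), `ci` (percentile
#'   bootstrap bounds per parameter) and an `overlap` diagnostic (component
#'   means within 1 pooled SD).
#' @export
fit_alpha_mixture <- function(fast_alphas, n_slow, n_boot = 1000L, seed = 1L,
                              conf = 0.95) {
  fast_alphas <- fast_alphas[is.finite(fast_alphas)]
  if (length(fast_alphas) < 50L)
    stop("insufficient data: need >= 50 alpha values, got ", length(fast_alphas))
  n_fast <- length(fast_alphas)
  n_tot <- n_fast + n_slow
  fit <- gmm_fit_1d(fast_alphas, k = 2L)
  p_slow <- n_slow / n_tot
  props <- c(S = p_slow, F1 = (1 - p_slow) * fit$weights[1],
             F2 = (1 - p_slow) * fit$weights[2])
  stat_names <- c("mean_F1", "mean_F2", "sd_F1", "sd_F2",
                  "prop_S", "prop_F1", "prop_F2")
  boot <- with_seed(derive_seed(seed, "alpha-boot"), {
    t(vapply(seq_len(n_boot), function(b) {
      ns <- rbinom(1L, n_tot, p_slow)
      nf <- n_tot - ns
      if (nf < 10L) return(rep(NA_real_, 7L))
      xb <- sample(fast_alphas, nf, replace = TRUE)
      fb <- gmm_fit_1d(xb, k = 2L, mu0 = fit$means, sd0 = fit$sds, w0 = fit$weights)
      psb <- ns / n_tot
      c(fb$means, fb$sds, psb, (1 - psb) * fb$weights)
    }, numeric(7L)))
  })
  colnames(boot) <- stat_names
  a <- (1 - conf) / 2
  ci <- t(apply(boot, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  sep <- abs(diff(fit$means)) / sqrt(mean(fit$sds^2))
  structure(list(means = fit$means, sds = fit$sds, weights = fit$weights,
                 proportions = props, ci = ci, n_fast = n_fast,
                 n_slow = n_slow, separation = sep, overlap = sep < 1,
                 conf = conf, seed = seed),
            class = "nd_alpha_fit")
}

#' @export
print.nd_alpha_fit <- function(x, ...) {
  cat(sprintf("<nd_alpha_fit> F1: alpha = %.3f (sd %.3f), F2: alpha = %.3f (sd %.3f)\n",
              x$means[1], x$sds[1], x$means[2], x$sds[2]))
  cat(sprintf("proportions: S %.1f%%, F1 %.1f%%, F2 %.1f%%%s\n",
              100 * x$proportions["S"], 100 * x$proportions["F1"],
              100 * x$proportions["F2"],
              if (isTRUE(x$overlap)) " [overlap diagnostic]" else ""))
  invisible(x)
}

#' Assign S/F1/F2 substate labels to frames
#'
#' Slow frames keep label `S`. Fast frames are assigned F1 or F2 by the
#' posterior of the alpha mixture at the frame's alpha value; `F2` requires
#' posterior > 0.5 (ties go to F1, the lower-alpha component). A single
#' trajectory may carry all three labels: state switching is representable.
#'
#' @param frames per-frame label series (from [windows_to_timepoints()]),
#'   with Stage-1 labels `confined` (slow) / `unconfined` (fast) and the
#'   per-frame `alpha`.
#' @param alpha_fit an [fit_alpha_mixture()] result.
#' @return The input with columns `substate` in
#'   `c("S", "F1", "F2", "unassigned")` and `posterior_f2`.
#' @export
assign_substates <- function(frames, alpha_fit) {
  out <- frames
  out$substate <- "unassigned"
  out$posterior_f2 <- NA_real_
  out$substate[out$label == "confined"] <- "S"
  fast <- which(out$label == "unconfined" & is.finite(out$alpha))
  if (length(fast)) {
    a <- out$alpha[fast]
    d1 <- alpha_fit$weights[1] * dnorm(a, alpha_fit$means[1], alpha_fit$sds[1])
    d2 <- alpha_fit$weights[2] * dnorm(a, alpha_fit$means[2], alpha_fit$sds[2])
    p2 <- d2 / (d1 + d2)
    out$posterior_f2[fast] <- p2
    out$substate[fast] <- ifelse(p2 > 0.5, "F2", "F1")
  }
  out
}
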