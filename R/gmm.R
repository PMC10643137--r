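# Full-covariance Gaussian mixture fitting by expectation-maximization.
# Written in-package because no mixture-model package is available in the
# target environment and the classifier is central to the method. The
# fitter sorts observations into canonical (lexicographic) order before
# doing anything stochastic, so the fitted model is bitwise identical
# under permutation of the input rows at a fixed seed.

# log density of rows of X under N(mu, Sigma); Sigma via Cholesky
.gmm_logdens <- function(X, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z * z) - sum(log(diag(ch))) - 0.5 * ncol(X) * log(2 * pi)
}

.gmm_regularize <- function(sigma, reg) {
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok || min(diag(sigma)) <= 0) {
    nd_log("singular mixture covariance: regularizing diagonal")
    sigma <- sigma + diag(reg * mean(diag(sigma)) + 1e-12, nrow(sigma))
  }
  sigma
}

# k-means++ center seeding (deterministic given the RNG state)
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# One EM run from a hard k-means initialization. Asserts the monotone
# log-likelihood property of EM at every iteration.
.gmm_em_run <- function(X, k, centers, max_iter, tol, reg) {
  n <- nrow(X); d <- ncol(X)
  km <- suppressWarnings(kmeans(X, centers = centers, iter.max = 50L))
  lab <- km$cluster
  w <- tabulate(lab, k) / n
  w[w == 0] <- 1e-6; w <- w / sum(w)
  mu <- matrix(0, k, d); sig <- array(0, c(d, d, k))
  gcov <- cov(X) + diag(1e-8, d)
  for (j in seq_len(k)) {
    rows <- X[lab == j, , drop = FALSE]
    mu[j, ] <- if (nrow(rows)) colMeans(rows) else colMeans(X)
    sig[, , j] <- if (nrow(rows) > d) .gmm_regularize(cov(rows), reg) else gcov
  }
  ll_old <- -Inf
  ll_trace <- numeric(0)
  R <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) .gmm_logdens(X, mu[j, ], sig[, , j]),
                   numeric(n))
    logw <- sweep(logd, 2L, log(w), `+`)
    m <- apply(logw, 1L, max)
    lse <- m + log(rowSums(exp(logw - m)))
    ll <- sum(lse)
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old)))
      stop("EM log-likelihood decreased; numerical failure")
    ll_trace <- c(ll_trace, ll)
    R <- exp(logw - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll))) { ll_old <- ll; break }
    ll_old <- ll
    nk <- colSums(R)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(R[, j] * X) / nk[j]
      Xc <- sweep(X, 2L, mu[j, ])
      s <- crossprod(Xc * sqrt(R[, j])) / nk[j]
      sig[, , j] <- .gmm_regularize(s, reg)
    }
  }
  list(weights = w, means = mu, covariances = sig,
       loglik = ll_old, loglik_trace = ll_trace, resp = R)
}

# Fit a k-component full-covariance GMM; n_init restarts, best likelihood
# kept. Deterministic given `seed` and invariant to row permutation.
gmm_fit <- function(X, k, seed = 1L, n_init = 10L, max_iter = 500L,
                    tol = 1e-8, reg = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 10L * k) stop("insufficient data: need at least ", 10L * k, " observations")
  ord <- do.call(order, as.data.frame(X))
  Xo <- X[ord, , drop = FALSE]
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, paste0("gmm-init-", i)), {
      centers <- .kmeanspp_centers(Xo, k)
      tryCatch(.gmm_em_run(Xo, k, centers, max_iter, tol, reg),
               error = function(e) NULL)
    })
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("all EM initializations failed")
  best$resp <- NULL
  best$k <- k
  best
}

# Posterior responsibilities of rows of X under a fitted model
gmm_posterior <- function(model, X) {
  X <- as.matrix(X)
  k <- model$k
  logd <- vapply(seq_len(k),
                 function(j) .gmm_logdens(X, model$means[j, ],
                                          model$covariances[, , j]),
                 numeric(nrow(X)))
  if (nrow(X) == 1L) logd <- matrix(logd, nrow = 1L)
  logw <- sweep(logd, 2L, log(model$weights), `+`)
  m <- apply(logw, 1L, max)
  exp(logw - (m + log(rowSums(exp(logw - m)))))
}

# Fast deterministic 1D two-component EM (quantile-based init), used for
# the alpha-substate fit and its bootstrap.
gmm_fit_1d <- function(x, k = 2L, mu0 = NULL, sd0 = NULL, w0 = NULL,
                       max_iter = 500L, tol = 1e-7) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (is.null(mu0)) mu0 <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (is.null(sd0)) sd0 <- rep(max(sd(x) / k, 1e-6), k)
  if (is.null(w0)) w0 <- rep(1 / k, k)
  mu <- mu0; s <- pmax(sd0, 1e-8); w <- w0 / sum(w0)
  ll_old <- -Inf
  ll <- NA_real_
  logd <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k))
      logd[, j] <- -0.5 * ((x - mu[j]) / s[j])^2 - log(s[j]) + log(w[j])
    m <- do.call(pmax, as.data.frame(logd))
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    R <- exp(logd - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll))) break
    ll_old <- ll
    nk <- pmax(colSums(R), 1e-12)
    w <- nk / n
    mu <- colSums(R * x) / nk
    for (j in seq_len(k))
      s[j] <- sqrt(max(sum(R[, j] * (x - mu[j])^2) / nk[j], 1e-12))
  }
  ordc <- order(mu)
  # loglik reported up to the dropped -0.5*log(2*pi) per observation
  list(means = mu[ordc], sds = s[ordc], weights = w[ordc],
       loglik = ll - 0.5 * n * log(2 * pi), k = k)
}
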