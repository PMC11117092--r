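#' L2-regularized spectral precision
#'
#' Minimizes `-log det(Phi) + tr(Theta Phi) + eta * sum_{j!=k} |Phi_jk|^2`
#' over Hermitian positive-definite `Phi` (diagonal unpenalized).  The ridge
#' acts only on off-diagonal entries, so no eigenvalue closed form exists;
#' the smooth convex objective is minimized by gradient descent with
#' Barzilai-Borwein steps and Armijo backtracking restricted to the positive
#' -definite cone, stopping when the stationarity residual
#' `max |-Phi^{-1} + Theta + 2 eta offdiag(Phi)|` drops below `tol`.  Unlike
#' the L1 path, no entry is forced to exact zero.
#'
#' @param theta `csd` object or Hermitian PD complex matrix.
#' @param eta nonnegative ridge penalty.
#' @param tol tolerance on the stationarity residual, relative to the CSD
#'   diagonal scale.
#' @param max_iter maximum gradient iterations.
#' @return list of class `l2_precision_fit` with `Phi`, `eta`, `residual`,
#'   `niter`, `converged`.
#' @export
l2_precision <- function(theta, eta, tol = 1e-6, max_iter = 1000) {
  if (eta < 0) stopf("eta must be nonnegative")
  th <- as_csd_matrix(theta)
  n <- nrow(th)
  ev <- eigen(th, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    # rank-deficient CSD: ridge-load as in the support refit
    th <- th + 0.001 * max(max_offdiag_mod(th), 1e-12) * diag(n)
  }
  tol <- tol * max(Re(diag(th)))   # residual has the units of theta
  offdiag <- function(m) { diag(m) <- 0i; m }
  objective <- function(Phi, logdet) {
    -logdet + Re(sum(th * t(Phi))) + eta * sum(Mod(offdiag(Phi))^2)
  }
  logdet_h <- function(m) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(NULL)
    sum(log(ev))
  }
  Phi <- diag(1 / Re(diag(th))) + 0i   # diagonal start: PD, well scaled
  ld <- logdet_h(Phi)
  J <- objective(Phi, ld)
  G <- hermitianize(-solve(Phi) + th + 2 * eta * offdiag(Phi))
  step <- 0.1 / (max(Mod(G)) + 1)
  resid <- max(Mod(G))
  it <- 0L
  G_prev <- NULL; Phi_prev <- NULL
  while (it < max_iter && resid >= tol) {
    it <- it + 1L
    if (!is.null(G_prev)) {   # Barzilai-Borwein step
      S <- Phi - Phi_prev; Y <- G - G_prev
      num <- Re(sum(Conj(S) * S)); den <- Re(sum(Conj(S) * Y))
      if (is.finite(den) && den > 1e-300) step <- num / den
    }
    accepted <- FALSE
    gnorm2 <- Re(sum(Conj(G) * G))
    for (bt in 1:60) {
      cand <- hermitianize(Phi - step * G)
      ld_c <- logdet_h(cand)
      if (!is.null(ld_c)) {
        J_c <- objective(cand, ld_c)
        if (J_c <= J - 1e-4 * step * gnorm2) { accepted <- TRUE; break }
      }
      step <- step / 2
    }
    if (!accepted) break
    Phi_prev <- Phi; G_prev <- G
    Phi <- cand; J <- J_c
    G <- hermitianize(-solve(Phi) + th + 2 * eta * offdiag(Phi))
    resid <- max(Mod(G))
  }
  converged <- is.finite(resid) && resid < tol
  if (!is.finite(resid) || resid > 100 * tol)
    warning(sprintf("L2 solver stalled (residual %.3g after %d iterations)",
                    resid, it))
  structure(list(Phi = Phi, eta = eta, residual = resid, niter = it,
                 converged = converged), class = "l2_precision_fit")
}

threshold_support <- function(phi, percentile) {
  n <- nrow(phi)
  mo <- Mod(phi); diag(mo) <- NA
  vals <- mo[upper.tri(mo)]
  thr <- as.numeric(quantile(vals, percentile / 100, names = FALSE))
  A <- matrix(0L, n, n)
  A[!is.na(mo) & mo > thr] <- 1L
  binary_network(A)
}

#' Cross-validated L2 precision with percentile thresholding
#'
#' Baseline competitor to [agl()]: for each candidate ridge penalty `eta`
#' and percentile threshold, each ensemble's L2-regularized precision is
#' thresholded at that percentile of its off-diagonal moduli, refit by
#' maximum likelihood on the surviving support, and scored by the same
#' held-out deviance as the adaptive graphical lasso.  The minimizing pair
#' is refit on the pooled CSD.
#'
#' @param x samples, matrix, list of CSDs, or `ensemble_set` (as in [agl()]).
#' @param eta_grid candidate ridge penalties; default log-spaced from the
#'   pooled-CSD scale.
#' @param percentile_grid candidate thresholds within `[5, 95]`.
#' @param k_ensembles ensembles when `x` is raw samples.
#' @param delta_factor ridge factor for the refit.
#' @param tol,max_iter controls for [l2_precision()].
#' @return object of class `l2fit` with `Phi` (thresholded + refit, pooled),
#'   `Phi_l2` (unthresholded pooled L2 fit), `support`, `eta`, `percentile`,
#'   `cv_table`, `partial_coherence`.
#' @export
cv_l2 <- function(x, eta_grid = NULL, percentile_grid = seq(5, 95, by = 10),
                  k_ensembles = 4L, delta_factor = 0.001,
                  tol = 1e-6, max_iter = 1000) {
  if (any(percentile_grid < 5 | percentile_grid > 95))
    stopf("percentile_grid must lie within [5, 95]")
  ens <- ensemble_csds(x, k_ensembles)
  csds <- ens$csds
  K <- length(csds)
  if (K < 2L) stopf("cross-validation needs at least 2 ensembles")
  counts <- vapply(csds, function(e) as.double(e$n_samples %||% 1), 0)
  theta_pooled <- hermitianize(
    Reduce(`+`, Map(function(e, w) w * e$theta, csds, counts)) / sum(counts))
  if (is.null(eta_grid)) {
    sc <- max_offdiag_mod(theta_pooled)
    # eta multiplies |Phi|^2 and Phi scales like 1/Theta, so scale by sc^2
    eta_grid <- sc^2 * 10^seq(-3, 1, length.out = 5)
  }
  fits <- lapply(csds, function(e)
    lapply(eta_grid, function(eta)
      l2_precision(e$theta, eta, tol = tol, max_iter = max_iter)$Phi))

  tab <- expand.grid(eta = eta_grid, percentile = percentile_grid,
                     KEEP.OUT.ATTRS = FALSE)
  tab$deviance <- 0
  for (r in seq_len(nrow(tab))) {
    gi <- match(tab$eta[r], eta_grid)
    for (i in seq_len(K)) {
      supp <- threshold_support(fits[[i]][[gi]], tab$percentile[r])
      ref <- refit_support(csds[[i]]$theta, supp, delta_factor = delta_factor)
      for (j in seq_len(K)) if (j != i)
        tab$deviance[r] <- tab$deviance[r] +
          spectral_deviance(ref$Phi, csds[[j]]$theta)
    }
  }
  best <- which(tab$deviance <= min(tab$deviance) + 1e-12)
  if (length(best) > 1L) {  # prefer the sparser model
    best <- best[tab$percentile[best] == max(tab$percentile[best])]
    best <- best[which.max(tab$eta[best])]
  }
  best <- best[1L]
  eta_star <- tab$eta[best]; pct_star <- tab$percentile[best]
  Phi_l2 <- l2_precision(theta_pooled, eta_star, tol = tol,
                         max_iter = max_iter)$Phi
  supp <- threshold_support(Phi_l2, pct_star)
  refit <- refit_support(theta_pooled, supp, delta_factor = delta_factor)
  structure(list(Phi = refit$Phi, Phi_l2 = Phi_l2, support = supp,
                 eta = eta_star, percentile = pct_star, cv_table = tab,
                 partial_coherence = partial_coherence(refit$Phi),
                 theta_pooled = theta_pooled, call = match.call()),
            class = "l2fit")
}

#' @export
print.l2fit <- function(x, ...) {
  cat("L2-regularized precision (percentile-thresholded)\n")
  cat(sprintf("  eta = %.4g, percentile = %g, edges = %d\n",
              x$eta, x$percentile, x$support$n_edges))
  invisible(x)
}

#' @export
coef.l2fit <- function(object, type = c("precision", "partial_coherence"), ...) {
  switch(match.arg(type),
         precision = object$Phi,
         partial_coherence = object$partial_coherence)
}

#' Bootstrap-thresholded coherence or imaginary-coherence network
#'
#' Resamples the spectral samples (rows, with replacement) `n_boot` times,
#' recomputes the pairwise measure per resample, and retains an edge when
#' the bootstrap distribution excludes zero.  For the real-valued imaginary
#' coherence this is the two-sided `alpha`-level percentile interval; for
#' complex coherence, zero must be outside the two-sided interval of the
#' real part or of the imaginary part, each tested at `alpha / 2`
#' (Bonferroni across the two components), since a magnitude interval can
#' never cover zero.
#'
#' With `n_boot = 1` the intervals are degenerate points and every nonzero
#' edge is retained.
#'
#' @param samples [spectral_samples()] object or complex matrix (>= 2 rows).
#' @param measure `"coherence"` or `"imaginary_coherence"`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; resample indices are shared across edges.
#' @return object of class `bootstrap_network` with `support`
#'   ([binary_network()]), `lower`/`upper` interval matrices (complex
#'   measures: per component, returned as a list), `measure`, `n_boot`,
#'   `alpha`, and the point estimate `estimate`.
#' @export
bootstrap_threshold <- function(samples,
                                measure = c("coherence", "imaginary_coherence"),
                                n_boot = 1000L, alpha = 0.05, seed = 1L) {
  measure <- match.arg(measure)
  z <- as_samples_matrix(samples)
  if (nrow(z) < 2L) stopf("bootstrap needs at least 2 samples")
  if (n_boot < 1L) stopf("n_boot must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  n <- ncol(z)
  measure_fun <- if (measure == "coherence") coherence else imaginary_coherence
  estimate <- measure_fun(estimate_csd(z))

  up <- which(upper.tri(matrix(0, n, n)))
  nb <- as.integer(n_boot)
  re_draws <- matrix(0, nb, length(up))
  im_draws <- if (measure == "coherence") matrix(0, nb, length(up)) else NULL
  set.seed(seed)
  for (b in seq_len(nb)) {
    idx <- sample.int(nrow(z), nrow(z), replace = TRUE)
    m <- measure_fun(estimate_csd(z[idx, , drop = FALSE]))
    re_draws[b, ] <- Re(m[up])
    if (measure == "coherence") im_draws[b, ] <- Im(m[up])
  }

  interval <- function(draws, a) {
    t(apply(draws, 2L, quantile, probs = c(a / 2, 1 - a / 2), names = FALSE))
  }
  excludes0 <- function(ci) ci[, 1L] > 0 | ci[, 2L] < 0

  if (measure == "imaginary_coherence") {
    ci <- interval(re_draws, alpha)
    keep <- excludes0(ci)
    lower <- upper <- matrix(NA_real_, n, n)  # upper triangle only
    lower[up] <- ci[, 1L]; upper[up] <- ci[, 2L]
    bounds <- list(lower = lower, upper = upper)
  } else {
    ci_re <- interval(re_draws, alpha / 2)
    ci_im <- interval(im_draws, alpha / 2)
    keep <- excludes0(ci_re) | excludes0(ci_im)
    bounds <- list(re = ci_re, im = ci_im, pairs = up)
  }
  A <- matrix(0L, n, n)
  A[up[keep]] <- 1L
  structure(list(support = binary_network(A + t(A),
                                          labels = colnames(z)),
                 estimate = estimate, intervals = bounds,
                 measure = measure, n_boot = nb, alpha = alpha),
            class = "bootstrap_network")
}

#' @export
print.bootstrap_network <- function(x, ...) {
  cat(sprintf("Bootstrap-thresholded %s network: %d edges (%d resamples, alpha = %g)\n",
              x$measure, x$support$n_edges, x$n_boot, x$alpha))
  invisible(x)
}
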