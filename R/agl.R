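# Default penalty grid: log-spaced from min_ratio * lambda_max to
# lambda_max, where lambda_max is the largest off-diagonal CSD modulus over
# the ensembles the cross-validation fits on -- the smallest flat penalty
# that zeroes every edge in every CV fit.
default_lambda_grid <- function(thetas, nlambda = 8, min_ratio = 0.01) {
  lmax <- max(vapply(thetas, max_offdiag_mod, 0))
  if (lmax <= 0) lmax <- 1
  exp(seq(log(min_ratio * lmax), log(lmax), length.out = nlambda))
}

ensemble_csds <- function(x, k_ensembles) {
  if (inherits(x, "ensemble_set")) return(x)
  if (is.list(x) && !inherits(x, "spectral_samples") &&
      all(vapply(x, function(e) inherits(e, "csd") || is.matrix(e), TRUE))) {
    csds <- lapply(x, function(e) if (inherits(e, "csd")) e else new_csd(e, NA_integer_))
    return(structure(list(csds = csds), class = "ensemble_set"))
  }
  samples <- if (inherits(x, "spectral_samples")) x else spectral_samples(x)
  split_ensembles(samples, k = k_ensembles)
}

#' Fit the adaptive graphical lasso with cross-validated penalties
#'
#' The main modelling function.  Given complex spectral samples (or a set of
#' per-ensemble cross-spectral densities) and a binary constraint network, it
#' selects the on-constraint penalty `lambda1` and off-constraint penalty
#' `lambda2` over a grid by K-fold cross-validated deviance: for each
#' candidate pair and each ensemble, the penalized precision is fit, its
#' support extracted, a maximum-likelihood refit computed on that support,
#' and the refit scored by `-log det(Phi) + tr(Theta_j Phi)` against every
#' held-out ensemble.  The returned point estimate is the refit on the
#' pooled (sample-weighted mean) CSD at the selected pair.
#'
#' A selected `lambda1 < lambda2` means the cross-validation chose to
#' penalize constraint edges less than non-edges, i.e. the constraint
#' network carries information about the conditional-dependence structure
#' (`constraint_used`).  With no constraint (or `lambda1 == lambda2`) the
#' model reduces to the vanilla graphical lasso.
#'
#' Deviance ties are broken toward the larger `lambda1 + lambda2`, then the
#' larger `lambda2` (sparser model preferred).
#'
#' @param x a [spectral_samples()] object, a complex matrix
#'   (samples x nodes), a list of `csd` objects, or an `ensemble_set`.
#' @param constraint a [binary_network()], 0/1 adjacency matrix, or `NULL`
#'   for the unconstrained (flat-penalty) graphical lasso.
#' @param lambda candidate penalty values shared by both levels; default is
#'   `nlambda` log-spaced values from 0.01 to 1 times the largest
#'   off-diagonal CSD modulus over the ensembles (the smallest flat penalty
#'   that zeroes every edge in every CV fit).
#' @param nlambda size of the default grid (default 8).
#' @param k_ensembles number of contiguous ensembles when `x` is raw samples.
#' @param zero_tol relative support threshold, see [support_of()].
#' @param delta_factor ridge factor for the support refit, see
#'   [refit_support()].
#' @param tol,max_iter solver controls for [glasso_complex()].
#' @return object of class `agl` with elements `Phi` (support refit on the
#'   pooled CSD), `Phi_penalized`, `support` ([binary_network()]),
#'   `partial_coherence`, `lambda` (named selected pair), `lambda_grid`,
#'   `cv_table` (data.frame of lambda1, lambda2, deviance), `cv_min`,
#'   `constraint_used`, `constraint`, `ensemble_fits` (per-ensemble refits
#'   at the selected pair), `theta_pooled`, `n_samples`.
#' @examples
#' truth <- generate_precision(random_network(5, 5, seed = 1), seed = 2)
#' z <- sample_complex_mvn(truth$theta_true, 240, seed = 3)
#' fit <- agl(z, constraint = truth$network)
#' fit
#' coef(fit)[1:3, 1:3]
#' @export
agl <- function(x, constraint = NULL, lambda = NULL, nlambda = 8L,
                k_ensembles = 4L, zero_tol = 1e-6, delta_factor = 0.001,
                tol = 1e-4, max_iter = 100) {
  ens <- ensemble_csds(x, k_ensembles)
  csds <- ens$csds
  K <- length(csds)
  if (K < 2L) stopf("cross-validation needs at least 2 ensembles")
  n <- nrow(csds[[1L]]$theta)
  labels <- colnames(csds[[1L]]$theta) %||% paste0("node", seq_len(n))
  counts <- vapply(csds, function(e) as.double(e$n_samples %||% NA), 0)
  if (anyNA(counts)) counts <- rep(1, K)
  theta_pooled <- hermitianize(
    Reduce(`+`, Map(function(e, w) w * e$theta, csds, counts)) / sum(counts))
  dimnames(theta_pooled) <- list(labels, labels)

  flat <- is.null(constraint)
  if (flat) {
    mask <- matrix(0, n, n)
  } else {
    mask <- as_adjacency(constraint)
    if (nrow(mask) != n) stopf("constraint dimension does not match the data")
  }

  thetas <- lapply(csds, `[[`, "theta")
  grid <- sort(lambda %||% default_lambda_grid(thetas, nlambda = nlambda))
  if (flat) {
    # flat penalty: only the lambda1 == lambda2 diagonal is meaningful
    dev <- cv_grid_cpp(thetas, mask, grid[1], grid, tol, max_iter,
                       zero_tol, delta_factor)
    tab <- data.frame(lambda1 = grid, lambda2 = grid, deviance = as.vector(dev))
  } else {
    dev <- cv_grid_cpp(thetas, mask, grid, grid, tol, max_iter,
                       zero_tol, delta_factor)
    tab <- expand.grid(lambda1 = grid, lambda2 = grid, KEEP.OUT.ATTRS = FALSE)
    tab$deviance <- as.vector(dev)
  }

  best <- which(tab$deviance <= min(tab$deviance) + 1e-12)
  if (length(best) > 1L) {
    sums <- tab$lambda1[best] + tab$lambda2[best]
    best <- best[sums == max(sums)]
    if (length(best) > 1L) best <- best[which.max(tab$lambda2[best])]
  }
  best <- best[1L]
  l1 <- tab$lambda1[best]; l2 <- tab$lambda2[best]

  pen <- penalty_weights(lambda_on = l1, lambda_off = l2,
                         constraint = if (flat) NULL else mask, n = n)
  fit_pen <- glasso_complex(theta_pooled, pen, tol = tol, max_iter = max_iter,
                            delta_factor = delta_factor)
  supp <- support_of(fit_pen$Phi, zero_tol = zero_tol)
  supp$labels <- labels
  dimnames(supp$adjacency) <- list(labels, labels)
  refit <- refit_support(theta_pooled, supp, delta_factor = delta_factor)

  ensemble_fits <- lapply(thetas, function(th) {
    fp <- glasso_complex(th, pen, tol = tol, max_iter = max_iter,
                         delta_factor = delta_factor)
    s <- support_of(fp$Phi, zero_tol = zero_tol)
    refit_support(th, s, delta_factor = delta_factor)
  })

  Phi <- refit$Phi
  dimnames(Phi) <- list(labels, labels)
  structure(list(
    Phi = Phi,
    Phi_penalized = fit_pen$Phi,
    support = supp,
    partial_coherence = partial_coherence(Phi),
    lambda = c(lambda1 = l1, lambda2 = l2),
    lambda_grid = grid,
    cv_table = tab,
    cv_min = min(tab$deviance),
    constraint_used = !flat && (l1 < l2),
    constraint = if (flat) NULL else binary_network(mask, labels = labels),
    ensemble_fits = ensemble_fits,
    theta_pooled = theta_pooled,
    n_samples = sum(counts),
    n_nodes = n,
    labels = labels,
    call = match.call()), class = "agl")
}

#' @export
print.agl <- function(x, ...) {
  cat("Adaptive graphical lasso fit\n")
  cat(sprintf("  nodes: %d, samples: %s, ensembles: %d\n",
              x$n_nodes, format(x$n_samples), length(x$ensemble_fits)))
  cat(sprintf("  selected lambda1 (on-constraint) = %.4g, lambda2 (off) = %.4g\n",
              x$lambda["lambda1"], x$lambda["lambda2"]))
  if (is.null(x$constraint)) {
    cat("  no constraint network (flat penalty, vanilla graphical lasso)\n")
  } else {
    cat(sprintf("  constraint informative (lambda1 < lambda2): %s\n",
                x$constraint_used))
  }
  cat(sprintf("  recovered edges: %d\n", x$support$n_edges))
  invisible(x)
}

#' @export
summary.agl <- function(object, ...) {
  pc <- object$partial_coherence
  up <- upper.tri(pc)
  edge <- as_adjacency(object$support)[up] == 1L
  s <- list(fit = object,
            n_edges = object$support$n_edges,
            pc_range = if (any(edge)) range(Mod(pc[up][edge])) else c(NA, NA),
            cv_table = object$cv_table,
            deviance = object$cv_min)
  if (!is.null(object$constraint)) {
    A <- as_adjacency(object$constraint)[up]
    E <- as_adjacency(object$support)[up]
    s$edges_on_constraint <- sum(A == 1L & E == 1L)
    s$edges_off_constraint <- sum(A == 0L & E == 1L)
  }
  class(s) <- "summary.agl"
  s
}

#' @export
print.summary.agl <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$edges_on_constraint))
    cat(sprintf("  edges on / off the constraint: %d / %d\n",
                x$edges_on_constraint, x$edges_off_constraint))
  if (x$n_edges > 0)
    cat(sprintf("  |partial coherence| on recovered edges: [%.3f, %.3f]\n",
                x$pc_range[1], x$pc_range[2]))
  cat(sprintf("  cross-validated deviance at the optimum: %.4g\n", x$deviance))
  invisible(x)
}

#' Extract the fitted precision or partial coherence
#'
#' @param object an `agl` fit.
#' @param type `"precision"` (the support refit, default) or
#'   `"partial_coherence"`.
#' @param ... unused.
#' @return complex matrix.
#' @export
coef.agl <- function(object, type = c("precision", "partial_coherence"), ...) {
  switch(match.arg(type),
         precision = object$Phi,
         partial_coherence = object$partial_coherence)
}

#' Plot an adaptive graphical lasso fit
#'
#' Two base-graphics panels: the cross-validated deviance surface over the
#' penalty grid (log axes; the selected pair marked) and the magnitude of
#' the fitted partial coherence.
#'
#' @param x an `agl` fit.
#' @param which subset of panels, any of `1:2`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.agl <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    g <- x$lambda_grid
    d <- matrix(NA_real_, length(g), length(g))
    idx <- cbind(match(x$cv_table$lambda1, g), match(x$cv_table$lambda2, g))
    d[idx] <- x$cv_table$deviance
    graphics::image(log10(g), log10(g), d,
                    xlab = "log10 lambda1 (on-constraint)",
                    ylab = "log10 lambda2 (off-constraint)",
                    main = "CV deviance", ...)
    graphics::points(log10(x$lambda["lambda1"]), log10(x$lambda["lambda2"]),
                     pch = 4, cex = 2, lwd = 2)
  }
  if (2 %in% which) {
    pc <- Mod(x$partial_coherence)
    diag(pc) <- 0
    graphics::image(seq_len(nrow(pc)), seq_len(ncol(pc)), pc,
                    xlab = "node", ylab = "node",
                    main = "|partial coherence|",
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE))
  }
  invisible(x)
}
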