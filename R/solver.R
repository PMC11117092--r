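#' Penalty weights for the adaptive graphical lasso
#'
#' Builds the matrix penalty: `lambda_on` on edges of the constraint network,
#' `lambda_off` elsewhere off the diagonal; the diagonal is never penalized.
#' With `lambda_on == lambda_off` the penalty reduces to the scalar
#' graphical-lasso penalty.
#'
#' @param n number of nodes (ignored when `constraint` is given).
#' @param lambda_on nonnegative penalty on constraint edges.
#' @param lambda_off nonnegative penalty off the constraint.
#' @param constraint binary adjacency matrix (or `binary_network`), or `NULL`
#'   for a flat penalty at `lambda_off`.
#' @return list of class `penalty_weights` with the scalar levels and the
#'   full penalty `matrix`.
#' @export
penalty_weights <- function(n = NULL, lambda_on, lambda_off, constraint = NULL) {
  if (lambda_on < 0 || lambda_off < 0) stopf("penalty levels must be nonnegative")
  if (!is.null(constraint)) {
    A <- as_adjacency(constraint)
    n <- nrow(A)
  } else {
    if (is.null(n)) stopf("supply n or a constraint network")
    A <- matrix(0, n, n)
  }
  P <- lambda_on * A + lambda_off * (1 - A)
  diag(P) <- 0
  structure(list(lambda_on = lambda_on, lambda_off = lambda_off, matrix = P),
            class = "penalty_weights")
}

as_penalty_matrix <- function(penalty, n) {
  if (inherits(penalty, "penalty_weights")) penalty <- penalty$matrix
  if (length(penalty) == 1L) {
    P <- matrix(penalty, n, n)
  } else {
    P <- as.matrix(penalty)
  }
  if (nrow(P) != n || ncol(P) != n) stopf("penalty matrix has wrong dimension")
  if (any(P < 0)) stopf("penalty entries must be nonnegative")
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

#' Complex graphical lasso
#'
#' Minimizes `-log det(Phi) + tr(Theta Phi) + sum_{j<k} P_jk |Phi_jk|` over
#' Hermitian positive-definite `Phi`, where `|.|` is the complex modulus and
#' the diagonal is unpenalized.  Solved by block coordinate descent on the
#' covariance iterate with a modulus soft-threshold in the inner lasso; the
#' outer loop exits when the objective decrease drops below `tol`.
#'
#' A CSD that fails the positive-semidefinite check is ridge-loaded with
#' `delta_factor` times its largest upper-triangle modulus before solving
#' (and the fit is flagged `ridge_loaded`).
#'
#' @param theta a `csd` object or Hermitian PSD complex matrix.
#' @param penalty a [penalty_weights()] object, scalar, or penalty matrix.
#' @param tol outer-loop objective-decrease tolerance.
#' @param max_iter maximum outer sweeps.
#' @param delta_factor ridge-loading factor for non-PSD input.
#' @param init optional previous fit (list with `W`, `B`) used as warm start.
#' @return list of class `cglasso_fit`: `Phi` (Hermitian PD complex matrix),
#'   `objective`, `niter`, `converged`, `gap`, `ridge_loaded`, plus the
#'   internal `W`/`B` iterates usable as warm starts.
#' @export
glasso_complex <- function(theta, penalty, tol = 1e-6, max_iter = 100,
                           delta_factor = 0.001, init = NULL) {
  th <- as_csd_matrix(theta)
  n <- nrow(th)
  P <- as_penalty_matrix(penalty, n)
  ev <- eigen(th, symmetric = TRUE, only.values = TRUE)$values
  ridge_loaded <- FALSE
  if (min(ev) < -1e-10 * max(abs(ev), 1e-300) || min(Re(diag(th))) <= 0) {
    delta <- delta_factor * max(max_offdiag_mod(th), max(Re(diag(th))), 1e-12)
    th <- th + delta * diag(n)
    ridge_loaded <- TRUE
  }
  warm <- !is.null(init) && !is.null(init$W) && !is.null(init$B)
  W0 <- if (warm) init$W else matrix(0i, n, n)
  B0 <- if (warm) init$B else matrix(0i, n, n)
  fit <- cglasso_cpp(th, P, tol, as.integer(max_iter), W0, B0, warm)
  if (!fit$converged)
    warning(sprintf("graphical lasso did not reach tol in %d sweeps (gap %.3g)",
                    max_iter, fit$gap))
  fit$Phi <- hermitianize(fit$Phi)
  fit$ridge_loaded <- ridge_loaded
  class(fit) <- "cglasso_fit"
  fit
}

#' Support of an estimated precision
#'
#' An edge j-k is declared present when `|Phi_jk|` exceeds `zero_tol` times
#' the largest off-diagonal modulus.
#'
#' @param phi_hat precision matrix or fit object.
#' @param zero_tol relative threshold (default `1e-6`).
#' @return a [binary_network()].
#' @export
support_of <- function(phi_hat, zero_tol = 1e-6) {
  phi <- as_precision_matrix(phi_hat)
  n <- nrow(phi)
  mo <- Mod(phi)
  diag(mo) <- 0
  mx <- max(mo)
  A <- matrix(0L, n, n)
  if (mx > 0) A[mo > zero_tol * mx] <- 1L
  A <- 1L * ((A + t(A)) > 0)
  diag(A) <- 0L
  binary_network(A, labels = colnames(phi))
}

#' Maximum-likelihood refit on a fixed support
#'
#' Minimizes `-log det(Phi) + tr((Theta + delta I) Phi)` subject to exact
#' zeros off the given support.  The diagonal ridge `delta` is
#' `delta_factor` times the largest upper-triangle modulus of the CSD,
#' guarding against rank deficiency.  At the optimum the inverse of the
#' refit matches the loaded CSD on the support and the diagonal (the
#' covariance-selection stationarity conditions).
#'
#' @param theta a `csd` object or Hermitian complex matrix.
#' @param support a [binary_network()] or 0/1 adjacency matrix.
#' @param delta_factor ridge factor (default 0.001).
#' @param tol objective-decrease tolerance (as in [glasso_complex()]).
#' @param max_iter maximum sweeps.
#' @return list of class `cglasso_refit` with `Phi` (exact zeros off
#'   support), `niter`, `converged`.
#' @export
refit_support <- function(theta, support, delta_factor = 0.001,
                          tol = 1e-6, max_iter = 200) {
  th <- as_csd_matrix(theta)
  n <- nrow(th)
  S <- as_adjacency(support)
  if (nrow(S) != n) stopf("support dimension does not match CSD")
  delta <- delta_factor * max(max_offdiag_mod(th), 1e-12)
  thd <- th + delta * diag(n)
  n0 <- matrix(0i, n, n)
  fit <- refit_cpp(thd, matrix(as.integer(S), n, n), tol, as.integer(max_iter),
                   n0, n0, FALSE)
  if (!fit$converged)
    warning(sprintf("support refit did not converge in %d sweeps", max_iter))
  fit$Phi <- {
    Phi <- hermitianize(fit$Phi)
    Phi[S == 0 & row(Phi) != col(Phi)] <- 0i
    Phi
  }
  fit$delta <- delta
  class(fit) <- "cglasso_refit"
  fit
}

#' Gaussian spectral deviance
#'
#' Held-out negative log-likelihood term `-log det(Phi) + tr(Theta Phi)`
#' scoring a fitted precision against an independent CSD; minimized (for
#' fixed Theta) at `Phi = Theta^{-1}`.
#'
#' @param phi Hermitian positive-definite precision (matrix or fit object).
#' @param theta_heldout held-out `csd` object or Hermitian matrix.
#' @return scalar deviance.
#' @export
spectral_deviance <- function(phi, theta_heldout) {
  phi <- as_precision_matrix(phi)
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("precision must be positive definite")
  d <- deviance_cpp(phi, as_csd_matrix(theta_heldout))
  if (!is.finite(d)) stopf("deviance is not finite")
  d
}
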