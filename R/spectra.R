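#' Spectral samples
#'
#' Container for complex-valued per-window Fourier coefficients: rows are
#' samples (windows), columns are nodes (channels, sources or ROIs).  Under
#' the proper (circularly symmetric) complex Gaussian model these samples are
#' fully characterized by their cross-spectral density.
#'
#' @param values complex matrix, n_samples x n_nodes.
#' @param node_labels optional character vector of unique node labels.
#' @return an object of class `spectral_samples`.
#' @export
spectral_samples <- function(values, node_labels = NULL) {
  values <- as.matrix(values)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (nrow(values) < 1L) stopf("need at least one sample")
  bad <- which(!apply(values, 1L, function(r) all(is.finite(Re(r)) & is.finite(Im(r)))))
  if (length(bad))
    stopf("non-finite spectral sample in row(s) %s", paste(head(bad, 5L), collapse = ", "))
  labels <- check_labels(node_labels %||% colnames(values), ncol(values))
  colnames(values) <- labels
  structure(list(values = values, node_labels = labels), class = "spectral_samples")
}

#' @export
print.spectral_samples <- function(x, ...) {
  cat(sprintf("Spectral samples: %d samples x %d nodes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_samples_matrix <- function(x) {
  if (inherits(x, "spectral_samples")) x$values
  else if (is.matrix(x)) spectral_samples(x)$values
  else stopf("expected a spectral_samples object or a matrix")
}

#' Estimate the cross-spectral density
#'
#' Maximum-likelihood estimate of the cross-spectral density (CSD) from
#' complex spectral samples: `theta = (1/n) * sum_t z_t z_t^H`.  Hermitian
#' symmetry is enforced after accumulation to absorb floating-point
#' asymmetry.
#'
#' @param samples a [spectral_samples()] object or complex matrix
#'   (samples x nodes).
#' @return an object of class `csd` with elements `theta` (Hermitian PSD
#'   complex matrix) and `n_samples` (samples used).
#' @export
estimate_csd <- function(samples) {
  z <- as_samples_matrix(samples)
  n <- nrow(z)
  theta <- crossprod(z, Conj(z)) / n   # (j,k) = sum_t z_tj conj(z_tk) / n
  theta <- hermitianize(theta)
  new_csd(theta, n)
}

new_csd <- function(theta, n_samples) {
  theta <- hermitianize(as.matrix(theta))
  structure(list(theta = theta, n_samples = as.integer(n_samples)), class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("Cross-spectral density: %d x %d (from %d samples)\n",
              nrow(x$theta), ncol(x$theta), x$n_samples))
  invisible(x)
}

as_csd_matrix <- function(x) {
  if (inherits(x, "csd")) x$theta
  else if (is.matrix(x)) hermitianize(x)
  else stopf("expected a csd object or a matrix")
}

check_hermitian_psd <- function(theta, what = "matrix", tol = 1e-10) {
  if (!is_square(theta)) stopf("%s must be square", what)
  asym <- max(Mod(theta - Conj(t(theta))))
  scale <- max(Mod(theta), 1e-300)
  if (asym > 1e-8 * scale) stopf("%s is not Hermitian (asymmetry %.3g)", what, asym)
  ev <- eigen(hermitianize(theta), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1e-300))
    stopf("%s is not positive semi-definite (min eigenvalue %.3g)", what, min(ev))
  invisible(ev)
}

#' Partial coherence from a precision matrix
#'
#' Normalizes the spectral precision: `PC_jk = Phi_jk / sqrt(Phi_jj Phi_kk)`.
#' Off-diagonal moduli measure conditional linear dependence between two
#' nodes given all others; the support of the precision is the functional
#' graph.
#'
#' @param phi Hermitian positive-definite complex matrix (precision), or a
#'   fit object with a `$Phi` element.
#' @return complex matrix with unit diagonal.
#' @export
partial_coherence <- function(phi) {
  phi <- as_precision_matrix(phi)
  d <- Re(diag(phi))
  if (any(d <= 0)) stopf("precision has nonpositive diagonal entries")
  s <- 1 / sqrt(d)
  pc <- phi * (s %o% s)
  diag(pc) <- 1 + 0i
  pc
}

as_precision_matrix <- function(phi) {
  if (is.list(phi) && !is.null(phi$Phi)) phi <- phi$Phi
  if (inherits(phi, "csd")) stopf("got a CSD; partial coherence needs a precision matrix")
  phi <- as.matrix(phi)
  if (!is.complex(phi)) storage.mode(phi) <- "complex"
  hermitianize(phi)
}

#' Coherence from a cross-spectral density
#'
#' `C_jk = Theta_jk / sqrt(Theta_jj Theta_kk)`: marginal linear dependence
#' per frequency, susceptible to indirect connections and source leakage.
#'
#' @param theta a `csd` object or Hermitian complex matrix with positive
#'   diagonal.
#' @return complex matrix with unit diagonal.
#' @export
coherence <- function(theta) {
  th <- as_csd_matrix(theta)
  d <- Re(diag(th))
  if (any(d <= 0)) stopf("CSD has nonpositive diagonal entries")
  s <- 1 / sqrt(d)
  cc <- th * (s %o% s)
  diag(cc) <- 1 + 0i
  cc
}

#' Imaginary coherence from a cross-spectral density
#'
#' `IC_jk = Im(Theta_jk) / sqrt(Theta_jj Theta_kk)`; real-valued and
#' antisymmetric, insensitive to zero-lag mixing.
#'
#' @inheritParams coherence
#' @return real matrix with zero diagonal.
#' @export
imaginary_coherence <- function(theta) {
  th <- as_csd_matrix(theta)
  d <- Re(diag(th))
  if (any(d <= 0)) stopf("CSD has nonpositive diagonal entries")
  s <- 1 / sqrt(d)
  ic <- Im(th) * (s %o% s)
  diag(ic) <- 0
  ic
}

#' Real embedding of a Hermitian matrix
#'
#' Maps an n x n Hermitian matrix Theta to the real symmetric 2n x 2n matrix
#' `(1/2) [[Re, -Im], [Im, Re]]`.  The factor 1/2 makes the embedding the
#' covariance of the stacked (Re z, Im z) vector of a proper complex Gaussian
#' with E[z z^H] = Theta, so samples drawn from it reproduce the CSD exactly.
#'
#' @param theta a `csd` object or Hermitian complex matrix.
#' @return real symmetric matrix of dimension 2n.
#' @seealso [real_to_complex_embedding()]
#' @export
complex_to_real_embedding <- function(theta) {
  th <- as_csd_matrix(theta)
  0.5 * rbind(cbind(Re(th), -Im(th)), cbind(Im(th), Re(th)))
}

#' Invert the real embedding
#'
#' @param m real 2n x 2n matrix produced by [complex_to_real_embedding()].
#' @return the original complex Hermitian matrix.
#' @export
real_to_complex_embedding <- function(m) {
  n2 <- nrow(m)
  if (n2 %% 2L != 0L) stopf("embedding must have even dimension")
  n <- n2 / 2L
  a <- m[seq_len(n), seq_len(n), drop = FALSE]
  b <- m[(n + 1L):n2, seq_len(n), drop = FALSE]
  hermitianize(2 * (a + 1i * b))
}
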