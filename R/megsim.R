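#' Synthetic quasi-physical lead field
#'
#' Builds a leakage-inducing forward operator without any head-model
#' machinery: gradiometer-like sensors are placed on an upper hemisphere,
#' ROI sources on an interior sphere, and each ROI carries three orthogonal
#' unit dipoles.  The field of a tangential dipole decays with the inverse
#' square of sensor-source distance, so spatially close ROIs project to
#' overlapping sensor patterns and mix at the sensors (the leakage the
#' inverse step must then disentangle).
#'
#' @param n_sensors number of sensors (default 204).
#' @param n_rois number of ROIs (default 114).
#' @param seed integer seed for sensor/source placement.
#' @return object of class `leadfield`: `matrix`
#'   (n_sensors x 3 n_rois), `roi_grouping` (list mapping ROI to its three
#'   column indices), `sensor_pos`, `roi_pos`.
#' @export
synthetic_leadfield <- function(n_sensors = 204L, n_rois = 114L, seed = 1L) {
  if (n_sensors < 1 || n_rois < 1) stopf("need at least one sensor and one ROI")
  set.seed(seed)
  # sensors: upper hemisphere of radius 1.1 (Fibonacci-type spread + jitter)
  k <- seq_len(n_sensors)
  phi_g <- (1 + sqrt(5)) / 2
  zs <- (k - 0.5) / n_sensors                 # in (0, 1): upper hemisphere
  az <- 2 * pi * k / phi_g + runif(n_sensors, 0, 1e-3)
  r_xy <- sqrt(pmax(0, 1 - zs^2))
  sensor_pos <- 1.1 * cbind(r_xy * cos(az), r_xy * sin(az), zs)
  # ROI centers: interior sphere of radius 0.8, roughly uniform
  u <- matrix(rnorm(3L * n_rois), n_rois, 3L)
  u <- u / sqrt(rowSums(u^2))
  rad <- 0.8 * runif(n_rois, 0.6, 1)^(1 / 3)
  roi_pos <- u * rad
  M <- matrix(0, n_sensors, 3L * n_rois)
  ex <- diag(3)
  for (q in seq_len(n_rois)) {
    d <- sweep(sensor_pos, 2L, roi_pos[q, ])            # sensor - source
    dist2 <- rowSums(d^2)
    dhat <- d / sqrt(dist2)
    nrm <- sensor_pos / sqrt(rowSums(sensor_pos^2))      # outward normals
    for (a in 1:3) {
      # tangential-dipole kernel: ((e_a x dhat) . n) / |d|^2
      cr <- cbind(ex[a, 2] * dhat[, 3] - ex[a, 3] * dhat[, 2],
                  ex[a, 3] * dhat[, 1] - ex[a, 1] * dhat[, 3],
                  ex[a, 1] * dhat[, 2] - ex[a, 2] * dhat[, 1])
      M[, 3L * (q - 1L) + a] <- rowSums(cr * nrm) / dist2
    }
  }
  # guard: no all-zero column (possible only in contrived geometries)
  cn <- sqrt(colSums(M^2))
  zero <- cn < 1e-12
  if (any(zero)) M[, zero] <- 1e-6 * matrix(rnorm(n_sensors * sum(zero)),
                                            n_sensors)
  grouping <- lapply(seq_len(n_rois), function(q) 3L * (q - 1L) + 1:3)
  names(grouping) <- paste0("roi", seq_len(n_rois))
  structure(list(matrix = M, roi_grouping = grouping,
                 sensor_pos = sensor_pos, roi_pos = roi_pos),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Lead field: %d sensors x %d dipole columns (%d ROIs x 3)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$roi_grouping)))
  invisible(x)
}

#' Load a user-supplied lead field from CSV
#'
#' Reads a dense numeric matrix (sensors x 3 ROIs) from a delimited file and
#' validates it against the implied ROI grouping of three consecutive
#' columns per ROI.
#'
#' @param path CSV file, sensors in rows.
#' @param n_rois number of ROIs; the file must have exactly `3 * n_rois`
#'   columns.
#' @return a `leadfield` object.
#' @export
load_leadfield <- function(path, n_rois) {
  M <- as.matrix(read.table(path, sep = ",", header = FALSE))
  storage.mode(M) <- "double"
  if (ncol(M) != 3L * n_rois)
    stopf("lead field has %d columns; expected %d (= 3 x %d ROIs)",
          ncol(M), 3L * n_rois, n_rois)
  cn <- sqrt(colSums(M^2))
  if (any(cn < 1e-12))
    stopf("lead field has all-zero column(s): %s",
          paste(head(which(cn < 1e-12), 5L), collapse = ", "))
  grouping <- lapply(seq_len(n_rois), function(q) 3L * (q - 1L) + 1:3)
  names(grouping) <- paste0("roi", seq_len(n_rois))
  structure(list(matrix = M, roi_grouping = grouping),
            class = "leadfield")
}

#' Add circular complex Gaussian source noise at a target SNR
#'
#' Adds independent proper complex Gaussian noise with common per-source
#' variance `sigma2` chosen so that
#' `10 log10(tr(Theta_true) / (n_sources * sigma2))` equals `snr_db`.
#'
#' @param sources [spectral_samples()] of source activity.
#' @param theta_true the generating CSD (sets the signal power).
#' @param snr_db target signal-to-noise ratio in dB (default 25);
#'   `Inf` returns the input unchanged.
#' @param seed integer seed.
#' @return noisy [spectral_samples()].
#' @export
add_source_noise <- function(sources, theta_true, snr_db = 25, seed = 1L) {
  z <- as_samples_matrix(sources)
  if (is.infinite(snr_db) && snr_db > 0) return(spectral_samples(z))
  if (!is.finite(snr_db)) stopf("snr_db must be finite (or +Inf)")
  th <- as_csd_matrix(theta_true)
  n_src <- ncol(z)
  sigma2 <- sum(Re(diag(th))) / n_src * 10^(-snr_db / 10)
  set.seed(seed)
  noise <- sqrt(sigma2 / 2) *
    (matrix(rnorm(length(z)), nrow(z)) + 1i * matrix(rnorm(length(z)), nrow(z)))
  spectral_samples(z + noise, node_labels = colnames(z))
}

#' Forward-project source samples to sensors
#'
#' Applies the lead field sample-by-sample: `B = M S`.  Sources may be given
#' per dipole column (3 per ROI) or per ROI with an orientation matrix that
#' embeds each scalar ROI series along a fixed unit 3-vector.
#'
#' @param sources [spectral_samples()], `n_samples x 3 n_rois` or
#'   `n_samples x n_rois` (with `orientation`).
#' @param leadfield a `leadfield` object.
#' @param orientation optional `n_rois x 3` matrix of unit orientations used
#'   when `sources` is per-ROI.
#' @return sensor-level [spectral_samples()].
#' @export
forward_project <- function(sources, leadfield, orientation = NULL) {
  S <- as_samples_matrix(sources)
  M <- leadfield$matrix
  n_rois <- length(leadfield$roi_grouping)
  if (ncol(S) == n_rois) {
    if (is.null(orientation))
      stopf("per-ROI sources need an orientation matrix (n_rois x 3)")
    S <- embed_orientation(S, orientation)
  }
  if (ncol(S) != ncol(M))
    stopf("source dimension %d does not match lead field (%d columns)",
          ncol(S), ncol(M))
  spectral_samples(S %*% t(M))
}

embed_orientation <- function(S, orientation) {
  n_rois <- ncol(S)
  orientation <- as.matrix(orientation)
  if (nrow(orientation) != n_rois || ncol(orientation) != 3L)
    stopf("orientation must be n_rois x 3")
  E <- matrix(0, n_rois, 3L * n_rois)
  for (q in seq_len(n_rois))
    E[q, 3L * (q - 1L) + 1:3] <- orientation[q, ]
  S %*% E
}

#' Weighted minimum-norm inverse operator
#'
#' Depth-weighted, ridge-regularized linear inverse of the lead field.
#' Diagonal weights are the per-column norms of `M` raised to
#' `weight_exponent`; with `G = M W`, the operator is
#' `W G^T (G G^T + nu I)^{-1}` where `nu` is the `nu_percentile`-th
#' percentile of the singular values of `G`.
#'
#' @param leadfield a `leadfield` object.
#' @param weight_exponent depth-weighting exponent (default 2.5).
#' @param nu_percentile percentile of the singular values of `MW` used as
#'   the regularizer (default 10).
#' @param nu optional explicit regularizer overriding the percentile rule.
#' @return object of class `inverse_operator` with `matrix`
#'   (3 n_rois x n_sensors), `nu`, `weights`.
#' @export
wmne_inverse <- function(leadfield, weight_exponent = 2.5, nu_percentile = 10,
                         nu = NULL) {
  M <- leadfield$matrix
  cn <- sqrt(colSums(M^2))
  if (all(cn < 1e-12)) stopf("lead field has rank 0")
  w <- cn^weight_exponent
  G <- M * rep(w, each = nrow(M))   # M %*% diag(w)
  dec <- svd(G)
  sv <- dec$d
  if (is.null(nu)) nu <- as.numeric(quantile(sv, nu_percentile / 100, names = FALSE))
  if (nu <= 0) nu <- max(sv) * 1e-10
  # G^T (G G^T + nu I)^{-1} = V diag(d / (d^2 + nu)) U^T via the SVD.
  # Singular values at the numerical noise floor (e.g. the invisible radial
  # dipole directions of a tangential-field lead field) are truncated so the
  # operator does not amplify arbitrary null-space vectors.
  f <- ifelse(sv > 1e-10 * max(sv), sv / (sv^2 + nu), 0)
  Minv <- w * (dec$v %*% (f * t(dec$u)))
  structure(list(matrix = Minv, nu = nu, weights = w,
                 roi_grouping = leadfield$roi_grouping),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("wMNE inverse operator: %d sources x %d sensors (nu = %.4g)\n",
              nrow(x$matrix), ncol(x$matrix), x$nu))
  invisible(x)
}

#' Apply an inverse operator to sensor samples
#'
#' @param inverse an `inverse_operator`.
#' @param sensors sensor-level [spectral_samples()].
#' @return source-level [spectral_samples()] (3 columns per ROI).
#' @export
apply_inverse <- function(inverse, sensors) {
  B <- as_samples_matrix(sensors)
  if (ncol(B) != ncol(inverse$matrix))
    stopf("sensor dimension does not match the inverse operator")
  spectral_samples(B %*% t(inverse$matrix))
}

#' Collapse dipole triplets to one series per ROI
#'
#' For each ROI, the 3 x n_samples dipole block is projected onto its first
#' left singular vector (the dominant dipole orientation); the sign/phase
#' convention makes the first nonzero component of the singular vector real
#' and positive.  All-zero blocks collapse to a zero series and are flagged.
#'
#' @param source_samples [spectral_samples()] with 3 columns per ROI.
#' @param roi_grouping list mapping each ROI to its 3 column indices.
#' @return [spectral_samples()] with one column per ROI; attribute
#'   `degenerate` lists all-zero ROIs.
#' @export
collapse_orientation <- function(source_samples, roi_grouping) {
  S <- as_samples_matrix(source_samples)
  n_rois <- length(roi_grouping)
  out <- matrix(0i, nrow(S), n_rois)
  degenerate <- integer(0)
  for (q in seq_len(n_rois)) {
    blk <- t(S[, roi_grouping[[q]], drop = FALSE])  # 3 x n_samples
    if (max(Mod(blk)) == 0) { degenerate <- c(degenerate, q); next }
    v <- svd(blk, nu = 1, nv = 0)$u[, 1L]
    nz <- which(Mod(v) > 1e-12)[1L]
    v <- v * Conj(v[nz]) / Mod(v[nz])   # first nonzero component real > 0
    out[, q] <- as.vector(Conj(v) %*% blk)
  }
  res <- spectral_samples(out, node_labels = names(roi_grouping))
  attr(res, "degenerate") <- degenerate
  res
}

#' Source-leakage simulation: forward model, wMNE inverse, recovery
#'
#' Full pipeline per iteration: ground-truth precision on the planted
#' network, proper complex Gaussian source samples, additive source noise at
#' the target SNR, projection through the lead field, weighted minimum-norm
#' inversion, orientation collapse to one series per ROI, and then all four
#' estimators (adaptive graphical lasso, cross-validated L2, bootstrapped
#' coherence and imaginary coherence) scored against the ground truth.
#' Scalar ROI activity is embedded along a fixed random unit orientation per
#' ROI before forward projection.
#'
#' @param n_rois,n_edges planted network size.
#' @param n_samples samples per iteration.
#' @param n_iterations number of iterations.
#' @param leadfield a `leadfield`; default [synthetic_leadfield()] sized to
#'   `n_sensors` and `n_rois`.
#' @param n_sensors sensors for the default lead field.
#' @param snr_db source SNR in dB (default 25).
#' @param lambda_grid penalty grid for the AGL (default grid if `NULL`).
#' @param methods subset of `c("agl", "l2", "coherence",
#'   "imaginary_coherence")`.
#' @param n_boot bootstrap resamples for the coherence baselines.
#' @param seed master seed.
#' @param k_ensembles CV ensembles.
#' @param tol,max_iter AGL solver controls.
#' @return data.frame, one row per iteration x method: tp, fp, fn,
#'   weight_correlation (NA for the support-only bootstrap methods'
#'   correlation is computed from coherence magnitudes), method, iteration.
#' @export
run_sim3 <- function(n_rois, n_edges, n_samples, n_iterations,
                     leadfield = NULL, n_sensors = 2L * n_rois,
                     snr_db = 25, lambda_grid = NULL,
                     methods = c("agl", "l2", "coherence",
                                 "imaginary_coherence"),
                     n_boot = 200L, seed = 1L, k_ensembles = 4L,
                     tol = 1e-4, max_iter = 100) {
  methods <- match.arg(methods, several.ok = TRUE)
  lf <- leadfield %||% synthetic_leadfield(n_sensors, n_rois,
                                           seed = derive_seed(seed, 7L))
  net <- random_network(n_rois, n_edges, seed = derive_seed(seed, 0L))
  rows <- list()
  for (i in seq_len(n_iterations)) {
    s <- derive_seed(seed, 100L + i)
    truth <- generate_precision(net, seed = derive_seed(s, 1L))
    src <- sample_complex_mvn(truth$theta_true, n_samples,
                              seed = derive_seed(s, 2L))
    src <- add_source_noise(src, truth$theta_true, snr_db = snr_db,
                            seed = derive_seed(s, 3L))
    set.seed(derive_seed(s, 4L))
    ori <- matrix(rnorm(3L * n_rois), n_rois, 3L)
    ori <- ori / sqrt(rowSums(ori^2))
    sens <- forward_project(src, lf, orientation = ori)
    inv <- wmne_inverse(lf)
    rec <- apply_inverse(inv, sens)
    roi_series <- collapse_orientation(rec, lf$roi_grouping)

    if ("agl" %in% methods) {
      fit <- agl(roi_series, constraint = net, lambda = lambda_grid,
                 k_ensembles = k_ensembles, tol = tol, max_iter = max_iter)
      met <- recovery_metrics(truth, fit$Phi, fit$support)
      rows[[length(rows) + 1L]] <-
        data.frame(method = "agl", iteration = i, tp = met$tp, fp = met$fp,
                   fn = met$fn, weight_correlation = met$weight_correlation)
    }
    if ("l2" %in% methods) {
      fit <- cv_l2(roi_series, k_ensembles = k_ensembles)
      met <- recovery_metrics(truth, fit$Phi, fit$support)
      rows[[length(rows) + 1L]] <-
        data.frame(method = "l2", iteration = i, tp = met$tp, fp = met$fp,
                   fn = met$fn, weight_correlation = met$weight_correlation)
    }
    for (mm in intersect(methods, c("coherence", "imaginary_coherence"))) {
      bt <- bootstrap_threshold(roi_series, measure = mm, n_boot = n_boot,
                                seed = derive_seed(s, 5L))
      At <- as_adjacency(net); Ae <- as_adjacency(bt$support)
      up <- upper.tri(At)
      rows[[length(rows) + 1L]] <-
        data.frame(method = mm, iteration = i,
                   tp = sum(At[up] == 1L & Ae[up] == 1L),
                   fp = sum(At[up] == 0L & Ae[up] == 1L),
                   fn = sum(At[up] == 1L & Ae[up] == 0L),
                   weight_correlation = NA_real_)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
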