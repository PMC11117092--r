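# ---- zero-phase elliptic band-pass filtering -------------------------------
#
# High-order narrow-transition elliptic band-pass designs are numerically
# meaningless in transfer-function form (polynomial coefficients of order
# 20+ with roots packed against the unit circle), so the filter is designed
# entirely in zero-pole-gain form: a low-order analog elliptic low-pass
# prototype (whose roots are well separated, so factoring it is safe), an
# analog low-pass-to-band-pass transform applied root by root, and a
# bilinear transform applied root by root.  The response is then evaluated
# as a product of first-order factors, which is stable at any order, and
# applied in the frequency domain as |H|^2 (the forward-backward filter:
# exactly zero phase, double the stop-band attenuation).

ellip_K <- function(k) {
  a <- 1; b <- sqrt(1 - k^2)
  while (abs(a - b) > 1e-15) {
    t <- (a + b) / 2
    b <- sqrt(a * b)
    a <- t
  }
  pi / (2 * a)
}

ellip_order <- function(selectivity, rp, rs) {
  eps_p <- sqrt(10^(rp / 10) - 1)
  eps_s <- sqrt(10^(rs / 10) - 1)
  k1 <- eps_p / eps_s
  max(2L, ceiling(ellip_K(selectivity) * ellip_K(sqrt(1 - k1^2)) /
                  (ellip_K(sqrt(1 - selectivity^2)) * ellip_K(k1))))
}

# Digital elliptic band-pass in zero-pole-gain form.
ellip_zpk_bandpass <- function(lo, hi, fs, transition, rp, rs) {
  wrp <- function(f) 2 * fs * tan(pi * f / fs)   # bilinear prewarp, rad/s
  wl <- wrp(lo); wh <- wrp(hi)
  w0 <- sqrt(wl * wh); BW <- wh - wl
  # low-pass-equivalent stop-band frequency (tighter of the two edges)
  Om <- function(w) abs((w^2 - w0^2) / (BW * w))
  Os <- min(Om(wrp(lo - transition)), Om(wrp(hi + transition)))
  N <- ellip_order(1 / Os, rp, rs)
  proto <- signal::ellip(N, rp, rs, 1, "low", plane = "s")
  zs <- polyroot(rev(proto$b)); ps <- polyroot(rev(proto$a))
  klp <- proto$b[1] / proto$a[1]
  lp2bp_roots <- function(r) {
    unlist(lapply(r, function(ri) {
      d <- sqrt(as.complex((ri * BW / 2)^2 - w0^2))
      c(ri * BW / 2 + d, ri * BW / 2 - d)
    }))
  }
  zbp <- lp2bp_roots(zs); pbp <- lp2bp_roots(ps)
  deg <- length(ps) - length(zs)
  zbp <- c(zbp, rep(0 + 0i, deg))
  kbp <- klp * BW^deg
  bil <- function(r) (2 * fs + r) / (2 * fs - r)
  zd <- bil(zbp); pd <- bil(pbp)
  kd <- kbp * Re(prod(2 * fs - zbp) / prod(2 * fs - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(zero = zd, pole = pd, gain = kd, order = N)
}

# |H(e^{iw})| from the zpk factors, stable at any order.
zpk_response <- function(flt, w) {
  zz <- exp(1i * w)
  H <- rep(abs(flt$gain), length(zz))
  for (r in flt$zero) H <- H * Mod(zz - r)
  for (r in flt$pole) H <- H / Mod(zz - r)
  H
}

# Zero-phase application: odd-reflection padding, multiply the spectrum by
# |H|^2 (real and nonnegative, hence exactly zero phase), transform back.
zero_phase_apply <- function(flt, x, padlen) {
  n <- length(x)
  p <- min(padlen, n - 1L)
  ext <- c(2 * x[1] - x[(p + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - p)])
  ne <- length(ext)
  H2 <- zpk_response(flt, 2 * pi * (seq_len(ne) - 1L) / ne)^2
  y <- Re(stats::fft(stats::fft(ext) * H2, inverse = TRUE)) / ne
  y[(p + 1L):(p + n)]
}

#' Frequency band definition
#'
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz; must satisfy `0 < low < high`.
#' @return list of class `band_definition`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stopf("band edges must satisfy 0 < low < high")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Canonical neural frequency bands
#'
#' delta (1-3 Hz), theta (4-7), alpha (8-13), beta (14-29), gamma (30-80).
#'
#' @return named list of [band_definition()] objects.
#' @export
neural_bands <- function() {
  list(delta = band_definition("delta", 1, 3),
       theta = band_definition("theta", 4, 7),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 14, 29),
       gamma = band_definition("gamma", 30, 80))
}

#' Design a zero-phase elliptic band-pass filter
#'
#' Elliptic band-pass with stop-band edges 0.5 Hz beyond the pass band,
#' 100 dB stop-band attenuation and 0.02 dB pass-band ripple, designed in
#' zero-pole-gain form and applied forward-backward (zero phase) by
#' [filter_band()].
#'
#' @param band a [band_definition()] (or list with `low_hz`, `high_hz`).
#' @param fs sampling rate in Hz.
#' @param transition_hz stop-band offset from each pass-band edge (default 0.5).
#' @param rs stop-band attenuation in dB (default 100).
#' @param rp pass-band ripple in dB (default 0.02).
#' @return object of class `bandpass_filter`.
#' @export
design_bandpass <- function(band, fs, transition_hz = 0.5, rs = 100,
                            rp = 0.02) {
  low <- band$low_hz; high <- band$high_hz
  ny <- fs / 2
  if (!(low > transition_hz && high + transition_hz < ny))
    stopf("band [%g, %g] Hz infeasible at fs = %g (need %g < low and high < %g)",
          low, high, fs, transition_hz, ny - transition_hz)
  flt <- ellip_zpk_bandpass(low, high, fs, transition_hz, rp, rs)
  # pad with several transition-band time constants so edge ringing decays
  padlen <- ceiling(4 * fs / transition_hz / 2)
  structure(c(flt, list(band = band, fs = fs, padlen = padlen)),
            class = "bandpass_filter")
}

#' @export
print.bandpass_filter <- function(x, ...) {
  cat(sprintf("Elliptic band-pass %g-%g Hz at fs = %g (prototype order %d, zero phase)\n",
              x$band$low_hz, x$band$high_hz, x$fs, x$order))
  invisible(x)
}

#' Apply a zero-phase band-pass filter
#'
#' Applies the squared magnitude response of the elliptic design (the
#' forward-backward filter) to each channel; zero phase distortion by
#' construction.
#'
#' @param filter a `bandpass_filter`.
#' @param x numeric vector (one channel) or channels-x-time matrix.
#' @return filtered data, same shape as `x`.
#' @export
filter_band <- function(filter, x) {
  apply1 <- function(v) zero_phase_apply(filter, as.numeric(v), filter$padlen)
  if (is.matrix(x)) t(apply(x, 1L, apply1)) else apply1(as.numeric(x))
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric tridiagonal
# eigenproblem; polarity fixed so the largest-magnitude element is positive.
dpss_tapers <- function(n, nw = 2, k = 3) {
  w <- nw / n
  t <- seq_len(n) - 1
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  T <- diag(dg)
  T[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- od
  T[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- od
  ev <- eigen(T, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    hj <- h[, j]
    if (hj[which.max(abs(hj))] < 0) hj <- -hj
    h[, j] <- hj / sqrt(sum(hj^2))
  }
  h
}

#' Multitaper spectral samples from a time series
#'
#' Splits each channel into non-overlapping windows of `window_s` seconds,
#' tapers each window with `n_tapers` Slepian tapers (time-bandwidth `nw`),
#' Fourier transforms, and averages the complex eigencoefficients across
#' tapers.  With 1-second windows the frequency grid is the integers, and a
#' `T`-second recording yields `floor(T / window_s)` samples per frequency.
#'
#' @param timeseries channels-x-time numeric matrix (a vector is one channel).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 1).
#' @param freqs integer frequencies (Hz) to keep; default all positive
#'   frequencies below Nyquist on the window's grid.
#' @param nw taper time-bandwidth product (default 2).
#' @param n_tapers tapers per window (default 3).
#' @return named list, one [spectral_samples()] per frequency
#'   (windows x channels).
#' @export
multitaper_samples <- function(timeseries, fs, window_s = 1.0, freqs = NULL,
                               nw = 2, n_tapers = 3) {
  x <- if (is.matrix(timeseries)) timeseries else matrix(timeseries, nrow = 1L)
  nwin_len <- round(fs * window_s)
  if (ncol(x) < nwin_len)
    stopf("time series shorter than one %gs window (%d < %d samples)",
          window_s, ncol(x), nwin_len)
  n_win <- floor(ncol(x) / nwin_len)
  labels <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
  df <- 1 / window_s
  grid <- seq_len(floor((nwin_len - 1) / 2)) * df  # positive freqs below Nyquist
  freqs <- freqs %||% grid
  bins <- round(freqs * window_s) + 1L
  if (any(bins < 2L | bins > nwin_len))
    stopf("requested frequencies outside the window's grid")
  h <- dpss_tapers(nwin_len, nw = nw, k = n_tapers)
  out <- lapply(freqs, function(f) matrix(0i, n_win, nrow(x)))
  names(out) <- as.character(freqs)
  for (w in seq_len(n_win)) {
    seg <- x[, ((w - 1L) * nwin_len + 1L):(w * nwin_len), drop = FALSE]
    # eigencoefficients for all tapers, averaged: (freq x channel)
    acc <- matrix(0i, nwin_len, nrow(x))
    for (k in seq_len(n_tapers))
      acc <- acc + stats::mvfft(t(seg) * h[, k])
    acc <- acc / n_tapers
    for (fi in seq_along(freqs))
      out[[fi]][w, ] <- acc[bins[fi], ]
  }
  lapply(out, spectral_samples, node_labels = labels)
}

#' Split spectral samples into contiguous ensembles
#'
#' Contiguous equal blocks in sample order for K-fold cross-validation; a
#' trailing remainder not filling a block is dropped (recorded in the
#' `n_dropped` element).
#'
#' @param samples [spectral_samples()] object or complex matrix.
#' @param k number of ensembles (default 4).
#' @return object of class `ensemble_set`: `csds` (list of `csd`),
#'   `blocks` (list of [spectral_samples()]), `n_dropped`.
#' @export
split_ensembles <- function(samples, k = 4L) {
  z <- as_samples_matrix(samples)
  n <- nrow(z)
  if (k > n) stopf("cannot split %d samples into %d ensembles", n, k)
  size <- n %/% k
  dropped <- n - size * k
  if (dropped > 0)
    warning(sprintf("dropping %d trailing sample(s) not filling an ensemble", dropped))
  blocks <- lapply(seq_len(k), function(i)
    spectral_samples(z[((i - 1L) * size + 1L):(i * size), , drop = FALSE],
                     node_labels = colnames(z)))
  structure(list(csds = lapply(blocks, estimate_csd), blocks = blocks,
                 n_dropped = dropped), class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("Ensemble set: %d ensembles of %d samples\n",
              length(x$csds), x$csds[[1L]]$n_samples))
  invisible(x)
}

#' Fit the adaptive graphical lasso per band and frequency
#'
#' For each band: band-pass filter the time series, extract multitaper
#' spectral samples, and fit [agl()] independently at every integer
#' frequency in the band (no averaging over frequencies).  The per-band
#' readout counts frequencies whose cross-validation selected
#' `lambda1 < lambda2`, i.e. where the constraint network was informative.
#'
#' @param timeseries channels-x-time numeric matrix.
#' @param fs sampling rate in Hz.
#' @param bands list of [band_definition()]s (default [neural_bands()],
#'   restricted to feasible bands for `fs`).
#' @param constraint a [binary_network()] or `NULL`.
#' @param lambda penalty grid passed to [agl()].
#' @param k_ensembles CV ensembles.
#' @param window_s multitaper window (default 1 s).
#' @param ... further arguments to [agl()].
#' @return object of class `band_fit_set`: per band a list with `band`,
#'   `frequencies`, `fits` (per-frequency `agl` objects), `constraint_used`
#'   (logical per frequency), `pc` (mean |partial coherence| across the
#'   band's frequencies).
#' @export
fit_bands <- function(timeseries, fs, bands = neural_bands(),
                      constraint = NULL, lambda = NULL, k_ensembles = 4L,
                      window_s = 1.0, ...) {
  x <- if (is.matrix(timeseries)) timeseries else matrix(timeseries, nrow = 1L)
  out <- list()
  for (b in bands) {
    flt <- design_bandpass(b, fs)
    xb <- filter_band(flt, x)
    freqs <- seq(ceiling(b$low_hz), floor(b$high_hz))
    freqs <- freqs[freqs < fs / 2]
    if (!length(freqs)) next
    sams <- multitaper_samples(xb, fs, window_s = window_s, freqs = freqs)
    fits <- lapply(sams, agl, constraint = constraint, lambda = lambda,
                   k_ensembles = k_ensembles, ...)
    used <- vapply(fits, `[[`, TRUE, "constraint_used")
    pcs <- lapply(fits, function(f) Mod(f$partial_coherence))
    pc <- Reduce(`+`, pcs) / length(pcs)
    diag(pc) <- 0
    out[[b$name]] <- list(band = b, frequencies = freqs, fits = fits,
                          constraint_used = unname(used), pc = pc)
  }
  structure(out, class = "band_fit_set")
}

#' @export
print.band_fit_set <- function(x, ...) {
  cat("Per-band adaptive graphical lasso fits\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf("  %-6s (%g-%g Hz): constraint used at %d/%d frequencies\n",
                nm, e$band$low_hz, e$band$high_hz,
                sum(e$constraint_used), length(e$frequencies)))
  }
  invisible(x)
}

#' Assign each edge to the band where it is strongest
#'
#' Labels every edge (constraint edges, or all pairs when no constraint is
#' given) with the band of its maximum mean partial-coherence magnitude.
#' Edges that are zero in every band stay unlabeled (`NA`); ties break
#' toward the lower-frequency band.
#'
#' @param band_fits a `band_fit_set` from [fit_bands()].
#' @param constraint optional [binary_network()] restricting the labeled
#'   edges.
#' @return data.frame with columns `node_a`, `node_b`, `band`, `magnitude`.
#' @export
assign_max_band <- function(band_fits, constraint = NULL) {
  if (!length(band_fits)) stopf("need at least one fitted band")
  order_bands <- order(vapply(band_fits, function(e) e$band$low_hz, 0))
  band_fits <- band_fits[order_bands]
  pc1 <- band_fits[[1L]]$pc
  n <- nrow(pc1)
  labels <- colnames(band_fits[[1L]]$fits[[1L]]$Phi) %||% paste0("node", seq_len(n))
  A <- if (is.null(constraint)) 1 - diag(n) else as_adjacency(constraint)
  pairs <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  mags <- vapply(band_fits, function(e) e$pc[pairs], numeric(nrow(pairs)))
  mags <- matrix(mags, nrow = nrow(pairs))
  best <- apply(mags, 1L, function(m)
    if (all(m == 0)) NA_integer_ else which.max(m))  # which.max takes first tie
  data.frame(node_a = labels[pairs[, 1L]],
             node_b = labels[pairs[, 2L]],
             band = names(band_fits)[best],
             magnitude = mags[cbind(seq_len(nrow(pairs)),
                                    ifelse(is.na(best), 1L, best))] *
               ifelse(is.na(best), NA_real_, 1))
}
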