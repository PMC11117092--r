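test_that("the elliptic band-pass meets its pass/stop specification", {
  fs <- 64
  flt <- design_bandpass(band_definition("mid", 8, 12), fs)
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mid <- 700:1200
  # tone amplitude estimated by projection onto the tone (leakage-free)
  tone_amp <- function(y, f) {
    seg <- y[mid]
    2 * Mod(mean(seg * exp(-2i * pi * f * t[mid])))
  }
  y10 <- filter_band(flt, sin(2 * pi * 10 * t))
  expect_equal(tone_amp(y10, 10), 1, tolerance = 0.01)
  # stop-band tone attenuated by at least 100 dB (forward-backward doubles
  # the design attenuation)
  y20 <- filter_band(flt, sin(2 * pi * 20 * t))
  expect_lt(tone_amp(y20, 20), 1e-5)
  # zero phase: cross-correlation peak at lag 0
  cc <- ccf(y10[mid], sin(2 * pi * 10 * t)[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # designed response: stop-band edges at/below -100 dB
  H <- aglasso:::zpk_response(flt, 2 * pi * c(7.5, 12.5, 5, 20) / fs)
  expect_true(all(20 * log10(H) < -99.9))
  expect_error(design_bandpass(band_definition("bad", 0.3, 3), 64), "infeasible")
})

test_that("multitaper sampling concentrates tones and counts windows", {
  fs <- 64
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- rbind(sin(2 * pi * 10 * t), rnorm(length(t)))
  sams <- multitaper_samples(x, fs)
  expect_equal(nrow(sams[[1]]$values), 30L)  # floor(T / window)
  pw <- vapply(sams, function(s) mean(Mod(s$values[, 1])^2), 0)
  expect_equal(names(which.max(pw)), "10")
  # white noise: flat mean power within sampling error
  pw2 <- vapply(sams, function(s) mean(Mod(s$values[, 2])^2), 0)
  expect_lt(max(pw2) / min(pw2), 3)
  expect_error(multitaper_samples(x[, 1:10], fs), "shorter")
})

test_that("ensemble splitting is contiguous and flags dropped samples", {
  z <- sample_complex_mvn(diag(3) + 0i, 480, seed = 2)
  ens <- split_ensembles(z, 4)
  expect_equal(length(ens$csds), 4L)
  expect_equal(ens$csds[[1]]$n_samples, 120L)
  expect_equal(ens$n_dropped, 0L)
  # concatenation of blocks reproduces the input
  expect_equal(do.call(rbind, lapply(ens$blocks, `[[`, "values")), z$values)
  expect_warning(ens10 <- split_ensembles(z$values[1:10, ], 4), "dropping")
  expect_equal(ens10$n_dropped, 2L)
  expect_equal(nrow(ens10$blocks[[1]]$values), 2L)
  expect_error(split_ensembles(z$values[1:3, ], 4), "cannot split")
})

test_that("band fitting flags the constraint only in the planted band", {
  # 4-node network planted in one band; an adjacent band holds only noise
  fs <- 64
  net <- random_network(4, 4, seed = 3)
  truth <- generate_precision(net, seed = 4)
  n_sec <- 96
  zf <- sample_complex_mvn(truth$theta_true, n_sec * 3, seed = 5)$values
  t <- seq(0, n_sec - 1 / fs, by = 1 / fs)
  x <- matrix(0, 4, length(t))
  # synthesize band-limited signals carrying the planted covariance at
  # 9-11 Hz, plus broadband background noise
  set.seed(6)
  for (f0 in c(9, 10, 11)) {
    seg <- zf[((f0 - 9) * n_sec + 1):((f0 - 8) * n_sec), ]
    for (ch in 1:4) {
      amp <- approx(seq_len(n_sec), Re(seg[, ch]), xout = seq_along(t) / fs,
                    rule = 2)$y
      ph <- approx(seq_len(n_sec), Im(seg[, ch]), xout = seq_along(t) / fs,
                   rule = 2)$y
      x[ch, ] <- x[ch, ] + amp * cos(2 * pi * f0 * t) - ph * sin(2 * pi * f0 * t)
    }
  }
  x <- x + matrix(rnorm(length(x), sd = 0.05 * sd(x)), nrow(x))
  bands <- list(band_definition("planted", 9, 11),
                band_definition("empty", 18, 22))
  fits <- fit_bands(x, fs, bands = bands, constraint = net, nlambda = 5)
  expect_s3_class(fits, "band_fit_set")
  expect_gt(mean(fits$planted$constraint_used), 0.5)
  expect_output(print(fits), "planted")
  lab <- assign_max_band(fits, constraint = net)
  expect_equal(nrow(lab), 4L)
  expect_true(all(lab$band == "planted", na.rm = TRUE))
})

test_that("max-band assignment labels by the strongest band with low-frequency ties", {
  mk <- function(name, lo, hi, pc) list(band = band_definition(name, lo, hi),
                                        frequencies = lo:hi,
                                        fits = list(list(Phi = diag(3) + 0i)),
                                        constraint_used = TRUE, pc = pc)
  pc1 <- matrix(0, 3, 3); pc1[1, 2] <- pc1[2, 1] <- 0.5
  pc2 <- matrix(0, 3, 3); pc2[1, 2] <- pc2[2, 1] <- 0.5  # tie
  pc2[1, 3] <- pc2[3, 1] <- 0.4
  bf <- structure(list(alpha = mk("alpha", 8, 13, pc1),
                       beta = mk("beta", 14, 29, pc2)),
                  class = "band_fit_set")
  lab <- assign_max_band(bf)
  tie_row <- lab[lab$node_a == "node1" & lab$node_b == "node2", ]
  expect_equal(tie_row$band, "alpha")  # tie broken toward lower frequency
  e13 <- lab[lab$node_a == "node1" & lab$node_b == "node3", ]
  expect_equal(e13$band, "beta")
  zero_row <- lab[lab$node_a == "node2" & lab$node_b == "node3", ]
  expect_true(is.na(zero_row$band))  # zero in every band: unlabeled
})
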