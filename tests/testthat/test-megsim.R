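test_that("the synthetic lead field is deterministic and distance-sensitive", {
  lf <- synthetic_leadfield(24, 6, seed = 2)
  expect_equal(dim(lf$matrix), c(24L, 18L))
  expect_equal(lf$matrix, synthetic_leadfield(24, 6, seed = 2)$matrix)
  expect_true(all(sqrt(colSums(lf$matrix^2)) > 0))
  # column norms decay with sensor-source distance: nearer ROI -> larger norm
  d <- apply(lf$roi_pos, 1, function(p) min(sqrt(colSums((t(lf$sensor_pos) - p)^2))))
  cn <- vapply(seq_len(6), function(q)
    sqrt(sum(lf$matrix[, lf$roi_grouping[[q]]]^2)), 0)
  expect_lt(cor(d, cn, method = "spearman"), 0)
})

test_that("lead field loading validates shape and rejects zero columns", {
  lf <- synthetic_leadfield(12, 3, seed = 5)
  path <- tempfile(fileext = ".csv")
  write.table(lf$matrix, path, sep = ",", row.names = FALSE, col.names = FALSE)
  got <- load_leadfield(path, n_rois = 3)
  expect_equal(got$matrix, lf$matrix, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(load_leadfield(path, n_rois = 4), "columns")
  bad <- lf$matrix; bad[, 2] <- 0
  write.table(bad, path, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(load_leadfield(path, n_rois = 3), "zero")
})

test_that("source noise hits the requested SNR", {
  theta <- random_hermitian_pd(4, seed = 7)
  src <- sample_complex_mvn(theta, 2000, seed = 8)
  # closed form: identity CSD at 25 dB has sigma^2 = 10^-2.5
  noisy <- add_source_noise(sample_complex_mvn(diag(4) + 0i, 4000, seed = 9),
                            diag(4) + 0i, snr_db = 25, seed = 10)
  resid <- noisy$values - sample_complex_mvn(diag(4) + 0i, 4000, seed = 9)$values
  expect_equal(mean(Mod(resid)^2), 10^(-2.5), tolerance = 0.1)
  # infinite SNR: unchanged
  clean <- add_source_noise(src, theta, snr_db = Inf, seed = 1)
  expect_equal(clean$values, src$values)
})

test_that("forward projection is linear and maps unit sources to columns", {
  lf <- synthetic_leadfield(20, 4, seed = 3)
  zero <- forward_project(matrix(0i, 5, 12), lf)
  expect_true(all(zero$values == 0i))
  e <- matrix(0i, 1, 12); e[1, 7] <- 1 + 0i
  out <- forward_project(e, lf)
  expect_equal(as.vector(Re(out$values)), lf$matrix[, 7], tolerance = 1e-12)
  set.seed(11)
  s1 <- matrix(rnorm(24) + 1i * rnorm(24), 2)
  s2 <- matrix(rnorm(24) + 1i * rnorm(24), 2)
  lin <- forward_project(s1 + 2 * s2, lf)
  expect_equal(lin$values,
               forward_project(s1, lf)$values + 2 * forward_project(s2, lf)$values,
               tolerance = 1e-10)
})

test_that("the weighted minimum-norm inverse behaves in the well-posed limit", {
  # orthogonal lead field with unit columns, tiny regularizer: M^- M -> I
  set.seed(13)
  Q <- qr.Q(qr(matrix(rnorm(144), 12)))
  lf <- list(matrix = Q, roi_grouping = lapply(1:4, function(q) 3 * (q - 1) + 1:3))
  class(lf) <- "leadfield"
  inv <- wmne_inverse(lf, nu = 1e-12)
  expect_equal(inv$matrix %*% Q, diag(12), tolerance = 1e-6)
  # homogeneity: scaling M by c rescales the operator by 1/c with nu scaled
  lf2 <- synthetic_leadfield(16, 4, seed = 14)
  i1 <- wmne_inverse(lf2)
  lf2c <- lf2; lf2c$matrix <- 3 * lf2$matrix
  # weights scale by 3^2.5, singular values by 3^3.5, so with nu scaled by
  # 3^7 the operator scales by 1/3
  i2 <- wmne_inverse(lf2c, nu = i1$nu * 3^7)
  expect_equal(i2$matrix * 3, i1$matrix, tolerance = 1e-6)
  # resolution matrix has finite, diagonally concentrated rows
  R <- i1$matrix %*% lf2$matrix
  expect_true(all(is.finite(R)))
})

test_that("orientation collapse recovers confined activity up to sign", {
  grouping <- lapply(1:2, function(q) 3 * (q - 1) + 1:3)
  set.seed(17)
  x <- rnorm(30) + 1i * rnorm(30)
  S <- matrix(0i, 30, 6)
  S[, 1] <- x  # activity confined to the x-dipole of ROI 1
  out <- collapse_orientation(S, grouping)
  expect_equal(Mod(out$values[, 1]), Mod(x), tolerance = 1e-10)
  expect_true(2 %in% attr(out, "degenerate"))
  # rotation of the 3-axis frame leaves the collapsed series invariant
  ori <- c(1, 2, -1); ori <- ori / sqrt(sum(ori^2))
  S2 <- matrix(0i, 30, 6)
  S2[, 1:3] <- x %o% ori
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  S2r <- S2
  S2r[, 1:3] <- S2[, 1:3] %*% t(R)
  a <- collapse_orientation(S2, grouping)$values[, 1]
  b <- collapse_orientation(S2r, grouping)$values[, 1]
  expect_equal(Mod(a), Mod(b), tolerance = 1e-8)
  # projection never gains energy
  expect_lte(sum(Mod(a)^2), sum(Mod(S2[, 1:3])^2) + 1e-8)
})

test_that("the full leakage pipeline runs deterministically end to end", {
  r <- suppressWarnings(
    run_sim3(6, 8, 160, 1, n_sensors = 18, n_boot = 40, seed = 5))
  expect_equal(nrow(r), 4L)
  expect_setequal(r$method, c("agl", "l2", "coherence", "imaginary_coherence"))
  expect_true(all(r$tp + r$fn == 8))
  r2 <- suppressWarnings(
    run_sim3(6, 8, 160, 1, n_sensors = 18, n_boot = 40, seed = 5))
  expect_equal(r, r2)
})
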