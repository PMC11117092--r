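test_that("random networks have the requested size and are reproducible", {
  net <- random_network(5, 5, seed = 3)
  expect_equal(net$n_edges, 5L)
  expect_equal(nrow(net$adjacency), 5L)
  expect_equal(random_network(5, 5, seed = 3)$adjacency, net$adjacency)
  big <- random_network(114, 720, seed = 1)
  expect_equal(big$n_edges, 720L)
  tri <- random_network(3, 3, seed = 9)
  expect_equal(tri$adjacency, matrix(1L, 3, 3) - diag(3L),
               ignore_attr = TRUE)
  expect_error(random_network(4, 7, seed = 1), "n_edges")
})

test_that("node shuffling preserves the degree multiset and edge count", {
  empty <- binary_network(matrix(0L, 4, 4))
  expect_equal(shuffle_network(empty, 1)$n_edges, 0L)
  full <- binary_network(matrix(1L, 4, 4) - diag(4L))
  expect_equal(shuffle_network(full, 2)$adjacency, full$adjacency)
  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L; star <- star + t(star)
  sh <- shuffle_network(binary_network(star), seed = 7)
  expect_equal(unname(sort(rowSums(sh$adjacency))), sort(rowSums(star)))
  expect_equal(sh$n_edges, 5L)
})

test_that("the PD loading loop reproduces the stated row-sum updates", {
  expect_equal(make_pd(diag(2)), diag(2) + 0i)
  m <- matrix(c(1, 3, 3, 1), 2)
  expect_equal(make_pd(m), matrix(c(5, 3, 3, 5), 2) + 0i)
  # PD on a sweep of random Hermitian inputs
  set.seed(31)
  for (r in 1:200) {
    n <- sample(2:6, 1)
    A <- matrix(rnorm(n^2) + 1i * rnorm(n^2), n)
    out <- make_pd((A + Conj(t(A))) / 2)
    ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("generated precisions respect the network and the stated distributions", {
  net <- random_network(6, 8, seed = 4)
  t1 <- generate_precision(net, seed = 5)
  t2 <- generate_precision(net, seed = 5)
  expect_equal(t1$phi_true, t2$phi_true)  # determinism
  A <- net$adjacency
  off <- A == 0L & row(A) != col(A)
  expect_true(all(t1$phi_true[off] == 0i))
  expect_lt(max(Mod(t1$theta_true %*% t1$phi_true - diag(6))), 1e-8)
  # empty network: diagonal precision via the unit loading
  te <- generate_precision(binary_network(matrix(0L, 3, 3)), seed = 6)
  expect_equal(te$phi_true, diag(3) + 0i)
  # edge weight and phase moments over many edges
  bignet <- random_network(150, 5000, seed = 7)
  tb <- generate_precision(bignet, seed = 8)
  up <- which(upper.tri(A <- bignet$adjacency) & A == 1L)
  w <- Mod(tb$phi_true[up])
  p <- Arg(tb$phi_true[up])
  expect_lt(abs(mean(w) - 100), 3 * 30 / sqrt(5000))
  expect_lt(abs(sd(w) - 30), 2)
  expect_lt(abs(mean(p) - pi / 2), 3 * 0.25 / sqrt(5000))
})

test_that("complex Gaussian sampling reproduces the CSD and properness", {
  z <- sample_complex_mvn(diag(3) + 0i, 10000, seed = 2)
  est <- estimate_csd(z)$theta
  expect_lt(max(Mod(est - diag(3))), 5 / sqrt(10000))
  # complementary covariance E[z z^T] vanishes (circular symmetry)
  zc <- z$values
  comp <- crossprod(zc, zc) / nrow(zc)
  expect_lt(max(Mod(comp)), 5 / sqrt(10000))
  # bit determinism and single-sample edge case
  expect_equal(sample_complex_mvn(diag(3) + 0i, 5, seed = 9)$values,
               sample_complex_mvn(diag(3) + 0i, 5, seed = 9)$values)
  z1 <- sample_complex_mvn(diag(2) + 0i, 1, seed = 1)
  expect_equal(nrow(z1$values), 1L)
})

test_that("recovery metrics count edges and score weights as specified", {
  truth <- generate_precision(random_network(5, 5, seed = 1), seed = 2)
  m <- recovery_metrics(truth, truth$phi_true, truth$network)
  expect_equal(c(m$tp, m$fp, m$fn), c(5L, 0L, 0L))
  expect_equal(m$weight_correlation, 1, tolerance = 1e-10)
  # empty estimate: all false negatives, flagged degenerate correlation
  empty <- diag(Re(diag(truth$phi_true))) + 0i
  me <- recovery_metrics(truth, empty, binary_network(matrix(0L, 5, 5)))
  expect_equal(c(me$tp, me$fp, me$fn), c(0L, 0L, 5L))
  expect_true(me$degenerate)
  expect_equal(me$weight_correlation, 0)
  # common phase rotation of all edges leaves the correlation magnitude intact
  rot <- truth$phi_true
  up <- upper.tri(rot) & truth$network$adjacency == 1L
  rot[up] <- rot[up] * exp(0.9i)
  rot[t(up)] <- Conj(t(rot)[t(up)])
  mr <- recovery_metrics(truth, rot, truth$network)
  expect_equal(mr$weight_correlation, 1, tolerance = 1e-8)
})

test_that("ground-truth partial coherence has the network as its exact support", {
  truth <- generate_precision(random_network(7, 9, seed = 21), seed = 22)
  pc <- partial_coherence(truth$phi_true)
  A <- truth$network$adjacency
  off <- row(A) != col(A)
  expect_equal(unname(1L * (Mod(pc[off]) > 0)), unname(A[off]))
})

test_that("simulation drivers emit schema-valid per-iteration records", {
  r1 <- run_sim1(5, 5, 60, 1, seed = 31)
  expect_equal(nrow(r1), 1L)
  expect_true(all(c("tp", "fp", "fn", "weight_correlation", "lambda1",
                    "lambda2", "lambda_gap", "constraint_used",
                    "deviance", "iteration") %in% names(r1)))
  expect_equal(r1$tp + r1$fn, 5)
  r0 <- run_sim2(5, 5, 60, 0, seed = 31)
  expect_equal(length(r0), 0L)
  # determinism of the whole driver
  r1b <- run_sim1(5, 5, 60, 1, seed = 31)
  expect_equal(r1, r1b)
})

test_that("recovery improves with more samples on matched networks", {
  net <- random_network(5, 5, seed = 41)
  r_small <- run_sim1(5, 5, 24, 4, seed = 42, network = net)
  r_large <- run_sim1(5, 5, 480, 4, seed = 42, network = net)
  expect_gte(median(r_large$tp), median(r_small$tp))
  expect_gt(mean(r_large$weight_correlation), mean(r_small$weight_correlation))
})
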