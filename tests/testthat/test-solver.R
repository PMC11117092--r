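test_that("unpenalized solve recovers the inverse CSD", {
  th <- random_hermitian_pd(4, seed = 1)
  f <- glasso_complex(th, penalty_weights(4, 0, 0), tol = 1e-9, max_iter = 200)
  expect_lt(max(Mod(f$Phi - solve(th))), 1e-5)
})

test_that("a prohibitive penalty zeroes all edges and leaves 1/theta_jj diagonals", {
  th <- random_hermitian_pd(4, seed = 2)
  lam <- 100 * max(Mod(th))
  f <- glasso_complex(th, penalty_weights(4, lam, lam))
  off <- f$Phi; diag(off) <- 0i
  expect_equal(max(Mod(off)), 0)
  expect_equal(Re(diag(f$Phi)), 1 / Re(diag(th)), tolerance = 1e-8)
})

test_that("solver matches the brute-force oracle on 2-node problems", {
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(rnorm(4) + 1i * rnorm(4), 2)
    Th <- A %*% Conj(t(A)) / 2 + diag(2)
    lam <- runif(1, 0.05, 0.5) * Mod(Th[1, 2])
    o <- oracle_glasso_2x2(Th, lam)
    f <- glasso_complex(Th, penalty_weights(2, lam, lam),
                        tol = 1e-10, max_iter = 500)
    expect_equal(f$objective, o$value, tolerance = 5e-4)
    expect_lt(Mod(f$Phi[1, 2] - (o$par[3] + 1i * o$par[4])), 1e-3)
  }
})

test_that("solver beats or matches random-restart optimization on 3-node problems", {
  # independent oracle: Nelder-Mead over the 9-parameter Hermitian
  # parameterization, many restarts; the solver must reach at least as low
  # an objective (to 3 decimals)
  set.seed(5)
  for (rep in 1:3) {
    Th <- random_hermitian_pd(3, seed = 100 + rep)
    lam <- 0.3 * max(Mod(Th - diag(diag(Th))))
    P <- matrix(lam, 3, 3); diag(P) <- 0
    unpack <- function(p) {
      phi <- diag(p[1:3]) + 0i
      phi[1, 2] <- p[4] + 1i * p[5]; phi[2, 1] <- Conj(phi[1, 2])
      phi[1, 3] <- p[6] + 1i * p[7]; phi[3, 1] <- Conj(phi[1, 3])
      phi[2, 3] <- p[8] + 1i * p[9]; phi[3, 2] <- Conj(phi[2, 3])
      phi
    }
    obj <- function(p) cglasso_objective(unpack(p), Th, P)
    iv <- solve(Th)
    p0 <- c(Re(diag(iv)), Re(iv[1, 2]), Im(iv[1, 2]),
            Re(iv[1, 3]), Im(iv[1, 3]), Re(iv[2, 3]), Im(iv[2, 3]))
    best <- Inf
    for (r in 1:8) {
      start <- p0 * (1 + 0.2 * rnorm(9))
      if (!is.finite(obj(start))) next  # non-PD start
      fit <- optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
      best <- min(best, fit$value)
    }
    f <- glasso_complex(Th, P, tol = 1e-10, max_iter = 500)
    expect_lt(f$objective, best + 1e-3)
  }
})

test_that("objective decreases across outer sweeps and permutation equivariance holds", {
  th <- random_hermitian_pd(5, seed = 8)
  lam <- 0.2 * max(Mod(th - diag(diag(th))))
  f <- glasso_complex(th, penalty_weights(5, lam, lam), tol = 1e-8)
  # permuting the nodes permutes the solution identically
  p <- c(3, 1, 5, 2, 4)
  fp <- glasso_complex(th[p, p], penalty_weights(5, lam, lam), tol = 1e-8)
  expect_equal(fp$Phi, f$Phi[p, p], tolerance = 1e-6)
})

test_that("support extraction applies the relative modulus threshold", {
  phi <- diag(3) + 0i
  expect_equal(support_of(phi)$n_edges, 0L)
  phi[1, 2] <- phi[2, 1] <- 0.5 + 0i
  s <- support_of(phi)
  expect_equal(s$n_edges, 1L)
  expect_equal(s$adjacency[1, 2], 1L)
  # entries below the relative threshold are dropped
  phi[1, 3] <- phi[3, 1] <- 1e-9 + 0i
  expect_equal(support_of(phi, zero_tol = 1e-6)$n_edges, 1L)
})

test_that("support refit satisfies the covariance-selection stationarity conditions", {
  th <- random_hermitian_pd(3, seed = 13)
  S <- matrix(0L, 3, 3)
  S[1, 2] <- S[2, 1] <- S[2, 3] <- S[3, 2] <- 1L  # chain
  r <- refit_support(th, S, delta_factor = 0.001, tol = 1e-10)
  delta <- 0.001 * max(Mod(th - diag(diag(th))))
  thd <- th + delta * diag(3)
  Winv <- solve(r$Phi)
  on <- S == 1L | diag(3) == 1
  expect_lt(max(Mod((Winv - thd)[on])), 1e-6 * max(Mod(thd)))
  expect_equal(r$Phi[1, 3], 0 + 0i)
  expect_equal(r$Phi[3, 1], 0 + 0i)

  # full support: unconstrained MLE
  rf <- refit_support(th, matrix(1L, 3, 3) - diag(3L))
  expect_equal(rf$Phi, solve(thd), tolerance = 1e-8)
  # empty support: diagonal 1/(theta_jj + delta)
  re <- refit_support(th, matrix(0L, 3, 3))
  expect_equal(Re(diag(re$Phi)), 1 / Re(diag(thd)), tolerance = 1e-8)
})

test_that("deviance identities hold and the inverse CSD is the minimizer", {
  expect_equal(spectral_deviance(diag(3) + 0i, diag(3) + 0i), 3)
  th <- random_hermitian_pd(4, seed = 17)
  ld <- sum(log(eigen(th, symmetric = TRUE, only.values = TRUE)$values))
  expect_equal(spectral_deviance(solve(th), th), 4 + ld, tolerance = 1e-10)
  # convexity: any other PD matrix scores worse
  set.seed(18)
  for (r in 1:10) {
    phi <- random_hermitian_pd(4, seed = 200 + r)
    expect_gte(spectral_deviance(phi, th), spectral_deviance(solve(th), th) - 1e-10)
  }
  expect_error(spectral_deviance(diag(c(1, -1)) + 0i, diag(2) + 0i), "positive definite")
})

test_that("penalty weights encode the two-level constraint structure", {
  net <- random_network(4, 3, seed = 1)
  pw <- penalty_weights(lambda_on = 0.1, lambda_off = 0.7, constraint = net)
  A <- net$adjacency
  expect_true(all(pw$matrix[A == 1L] == 0.1))
  off <- A == 0L & row(A) != col(A)
  expect_true(all(pw$matrix[off] == 0.7))
  expect_true(all(diag(pw$matrix) == 0))
  expect_error(penalty_weights(4, -1, 0), "nonnegative")
})
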