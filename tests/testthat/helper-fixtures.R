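# shared fixture builders; everything is generated in code at test time

random_hermitian_pd <- function(n, seed, ridge = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n) + 1i * rnorm(n * n), n)
  A %*% Conj(t(A)) / n + ridge * diag(n)
}

# both-triangles penalized objective (the solver's contract)
cglasso_objective <- function(Phi, Theta, P) {
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  pen <- Mod(Phi)
  diag(pen) <- 0
  -sum(log(ev)) + Re(sum(Theta * t(Phi))) + sum(P * pen)
}

# zooming grid search over the 4-parameter Hermitian 2x2 problem;
# independent of the package solver
oracle_glasso_2x2 <- function(Theta, lam, zooms = 14) {
  iv <- solve(Theta)
  ctr <- c(Re(iv[1, 1]), Re(iv[2, 2]), Re(iv[1, 2]), Im(iv[1, 2]))
  wid <- pmax(abs(ctr), 1) * 1.5
  P <- matrix(lam, 2, 2); diag(P) <- 0
  obj <- function(p) {
    phi <- matrix(c(p[1], p[3] - 1i * p[4], p[3] + 1i * p[4], p[2]), 2, 2)
    cglasso_objective(phi, Theta, P)
  }
  v <- NULL
  for (zoom in seq_len(zooms)) {
    gr <- lapply(1:4, function(k) seq(ctr[k] - wid[k], ctr[k] + wid[k],
                                      length.out = 9))
    g <- as.matrix(expand.grid(gr))
    v <- apply(g, 1L, obj)
    ctr <- unname(g[which.min(v), ])
    wid <- wid / 3
  }
  list(par = ctr, value = min(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
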