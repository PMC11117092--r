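# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a master seed
#'
#' Counter-based splitting so that simulation iterations use independent,
#' reproducible RNG streams while all randomness flows from one master seed.
#' The result always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer counter (iteration index, stage index).
#' @return an integer seed.
#' @export
derive_seed <- function(master, counter) {
  m <- as.double(master) %% 2147483647
  # multiplicative hash (Lehmer-style) on the counter stream
  s <- (m * 48271 + as.double(counter) * 16807 + 12345) %% 2147483647
  as.integer(s)
}

is_square <- function(x) is.matrix(x) && nrow(x) == ncol(x)

check_labels <- function(labels, n) {
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stopf("expected %d node labels, got %d", n, length(labels))
  if (anyDuplicated(labels)) stopf("node labels must be unique")
  labels
}

hermitianize <- function(m) (m + Conj(t(m))) / 2

max_offdiag_mod <- function(m) {
  n <- nrow(m)
  if (n < 2) return(0)
  mo <- Mod(m)
  diag(mo) <- 0
  max(mo)
}

upper_pairs <- function(n) which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
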