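# Independent brute-force oracle: sums products of one-step effects over
# every explicit walk of length m (walks may revisit nodes). Deliberately
# avoids matrix multiplication so it can cross-check the matrix-power path.
walk_effects_oracle <- function(M, m) {
  n <- nrow(M)
  out <- matrix(0, n, n, dimnames = dimnames(M))
  rec <- function(start, at, prod, steps) {
    if (steps == m) {
      out[start, at] <<- out[start, at] + prod
      return(invisible())
    }
    for (k in seq_len(n)) {
      if (M[at, k] != 0) rec(start, k, prod * M[at, k], steps + 1L)
    }
  }
  for (s in seq_len(n)) rec(s, s, 1, 0L)
  out
}

ti_oracle <- function(web, n) {
  M <- unclass(one_step_effects(web))
  acc <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  for (m in seq_len(n)) acc <- acc + walk_effects_oracle(M, m)
  acc <- acc / n
  diag(acc) <- 0
  acc
}

# Erdos-Renyi undirected web with at least one edge, labels a01..aNN
random_web <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    if (any(A)) break
  }
  labels <- sprintf("a%02d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  food_web(labels, edges = cbind(labels[idx[, 1L]], labels[idx[, 2L]]),
           web_id = paste0("er_", seed))
}

# strip effect_matrix class/metadata for value comparison
em <- function(x) {
  x <- unclass(x)
  attr(x, "steps") <- NULL
  attr(x, "normalized") <- NULL
  x
}
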