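#' One-step topological effect matrix
#'
#' The one-step effect of node i on node j is 1/D_j if i and j interact and
#' 0 otherwise, where D_j is the degree of j: each node divides the
#' influence it receives equally among its neighbours. Entry (i, j) is the
#' effect OF i ON j, so every column over a non-isolated node sums to 1.
#'
#' @param web a [food_web].
#' @return an `effect_matrix` (square numeric matrix in node order with
#'   attributes `steps = 1` and `normalized = FALSE`).
#' @export
one_step_effects <- function(web) {
  stopifnot(inherits(web, "food_web"))
  A <- adjacency_matrix(web)
  deg <- colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  M <- sweep(A, 2L, inv, `*`)
  effect_matrix(M, steps = 1L, normalized = FALSE)
}

effect_matrix <- function(values, steps, normalized) {
  structure(values, steps = as.integer(steps), normalized = normalized,
            class = c("effect_matrix", "matrix", "array"))
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("effect_matrix: ", nrow(x), " nodes, ", attr(x, "steps"), " step(s), ",
      if (isTRUE(attr(x, "normalized"))) "normalized" else "unnormalized",
      "\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' m-step walk effects
#'
#' The m-step effect of i on j sums, over every walk of length m from i to
#' j (walks may revisit nodes), the product of one-step effects along the
#' walk — i.e. the m-th power of the one-step matrix.
#'
#' @param one_step an `effect_matrix` with `steps = 1`.
#' @param m number of steps (>= 1).
#' @return an `effect_matrix` with `steps = m`.
#' @export
multi_step_effects <- function(one_step, m) {
  if (m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  M <- unclass(one_step)
  P <- M
  if (m > 1L) for (i in seq_len(m - 1L)) P <- P %*% M
  effect_matrix(P, steps = m, normalized = FALSE)
}

#' Pairwise TI^n topological importance matrix
#'
#' TI^n(i, j) aggregates the m-step effects of i on j for m = 1..n, by
#' default as their average (1/n times the sum); the diagonal is zeroed
#' because self-effects are never used downstream. With `normalize = TRUE`
#' (the default, matching the study configuration at n = 3) all entries are
#' divided by the grand total of off-diagonal entries so they sum to 1;
#' this rescaling changes no rank order, so the asymmetry graph's topology
#' is invariant to it.
#'
#' @param web a [food_web].
#' @param n number of steps to aggregate (default 3).
#' @param normalize divide by the grand off-diagonal total.
#' @param aggregate `"mean"` (the standard 1/n average) or `"sum"` (plain
#'   sum, for sensitivity checks).
#' @return an `effect_matrix` with `steps = n`.
#' @export
ti_matrix <- function(web, n = 3, normalize = TRUE,
                      aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  M <- unclass(one_step_effects(web))
  acc <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  P <- diag(nrow(M))
  for (m in seq_len(n)) {
    P <- P %*% M
    acc <- acc + P
  }
  if (aggregate == "mean") acc <- acc / n
  diag(acc) <- 0
  if (normalize) {
    total <- sum(acc)
    if (total <= 0) {
      stop("cannot normalize: all off-diagonal TI^n effects are zero ",
           "(edgeless graph?)")
    }
    acc <- acc / total
  }
  effect_matrix(acc, steps = n, normalized = normalize)
}

#' Per-node topological importance
#'
#' The importance of node i is the total effect it exerts on all other
#' nodes: the i-th row sum of the TI^n matrix (the diagonal is already
#' zero). Used as a topological index for keystone-species assessment.
#'
#' @param ti an `effect_matrix` from [ti_matrix].
#' @param sorted return in descending order of importance.
#' @return named numeric vector of importances.
#' @export
node_ti <- function(ti, sorted = FALSE) {
  v <- rowSums(unclass(ti))
  if (sorted) v <- sort(v, decreasing = TRUE)
  v
}

#' Write an effect matrix as CSV
#' @param ti an `effect_matrix`.
#' @param path output path.
#' @export
write_effect_matrix <- function(ti, path) {
  utils::write.csv(as.data.frame(unclass(ti)), path, row.names = TRUE)
  invisible(path)
}
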