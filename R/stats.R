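#' Kendall rank correlation for one variable pair
#'
#' Tie-corrected Kendall tau (tau-b) with a two-sided p-value via
#' `stats::cor.test` — exact for small samples without ties, normal
#' approximation otherwise. Pairs with a missing value in either sequence
#' are dropped first; fewer than 3 complete pairs, or zero variance in
#' either sequence, yields a missing result.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `tau`, `p`, `n_used`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    warning("fewer than 3 complete pairs; Kendall tau not computed")
    return(list(tau = NA_real_, p = NA_real_, n_used = n))
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(tau = NA_real_, p = NA_real_, n_used = n))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, n_used = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values: sort ascending, q_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1, returned in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise Kendall correlation screen over an indicator table
#'
#' Tests every unordered pair of indicator columns (21 variables give 210
#' pairs) with pairwise-complete observations, then applies
#' Benjamini-Hochberg adjustment jointly across all computable raw
#' p-values; the BH family size is the number of computable pairs, not a
#' fixed 210 (constant or all-missing columns are excluded with a log
#' message). Significance is flagged at q < 0.05.
#'
#' @param indicators data frame from [indicator_table] (a `web_id` /
#'   `threshold` column, if present, is ignored).
#' @param alpha significance level on the adjusted q-values.
#' @return a `correlation_table`: long data frame (var1, var2, tau, p, q,
#'   n_used, significant) with the square tau matrix and a star matrix
#'   (thresholds 0.05/0.01/0.001 on q) attached as attributes `tau_matrix`
#'   and `stars`.
#' @export
correlation_table <- function(indicators, alpha = 0.05) {
  vars <- setdiff(names(indicators), c("web_id", "threshold"))
  X <- indicators[, vars, drop = FALSE]
  if (nrow(X) < 3L) stop("correlation screen needs at least 3 webs")
  pairs <- utils::combn(vars, 2L)
  res <- apply(pairs, 2L, function(pr) {
    r <- suppressWarnings(kendall_tau(X[[pr[1L]]], X[[pr[2L]]]))
    c(tau = r$tau, p = r$p, n_used = r$n_used)
  })
  tab <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    tau = res["tau", ], p = res["p", ],
                    q = NA_real_, n_used = as.integer(res["n_used", ]),
                    stringsAsFactors = FALSE)
  computable <- !is.na(tab$p)
  if (any(!computable)) {
    message(sum(!computable), " variable pair(s) excluded from the BH ",
            "family (constant or insufficient data)")
  }
  tab$q[computable] <- bh_adjust(tab$p[computable])
  tab$significant <- !is.na(tab$q) & tab$q < alpha

  tau_m <- matrix(NA_real_, length(vars), length(vars),
                  dimnames = list(vars, vars))
  diag(tau_m) <- 1
  stars <- matrix("", length(vars), length(vars),
                  dimnames = list(vars, vars))
  for (i in seq_len(nrow(tab))) {
    tau_m[tab$var1[i], tab$var2[i]] <- tab$tau[i]
    tau_m[tab$var2[i], tab$var1[i]] <- tab$tau[i]
    s <- if (is.na(tab$q[i])) "" else if (tab$q[i] < 0.001) "***" else
      if (tab$q[i] < 0.01) "**" else if (tab$q[i] < 0.05) "*" else ""
    stars[tab$var1[i], tab$var2[i]] <- s
    stars[tab$var2[i], tab$var1[i]] <- s
  }
  structure(tab, tau_matrix = tau_m, stars = stars,
            class = c("correlation_table", "data.frame"))
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("correlation_table: ", nrow(x), " variable pairs, ",
      sum(x$significant, na.rm = TRUE), " significant at q < 0.05\n",
      sep = "")
  sig <- x[which(x$significant), , drop = FALSE]
  if (nrow(sig) > 0L) {
    print(as.data.frame(sig[order(sig$q), ]), row.names = FALSE,
          digits = 3)
  }
  invisible(x)
}

#' Export a correlation table
#'
#' @param ct a `correlation_table`.
#' @param path output path.
#' @param format `"long"` (var1, var2, tau, p, q, n_used, significant) or
#'   `"matrix"` (square tau matrix).
#' @export
write_correlation_table <- function(ct, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "long") {
    utils::write.csv(as.data.frame(ct), path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(attr(ct, "tau_matrix")), path,
                     row.names = TRUE)
  }
  invisible(path)
}
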