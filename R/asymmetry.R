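#' Pairwise asymmetry matrix
#'
#' The asymmetry of a node pair is the absolute difference between the two
#' directed TI^n effects: A(i, j) = |TI^n(i, j) - TI^n(j, i)|. The result
#' is symmetric with a zero diagonal.
#'
#' @param ti an `effect_matrix` from [ti_matrix].
#' @return symmetric non-negative numeric matrix in node order.
#' @export
asymmetry_matrix <- function(ti) {
  M <- unclass(ti)
  abs(M - t(M))
}

#' Link budget of the asymmetry graph
#'
#' The number of unordered pairs admitted at threshold fraction `t`:
#' `max(1, floor(t * N * (N - 1) / 2))`. The floor is promoted to one link
#' for small webs, so at the 1% threshold an 8-node web keeps a single
#' effect while a 67-node web keeps 22.
#'
#' @param N node count (>= 2).
#' @param t threshold fraction in (0, 1), default 0.01 (top 1%).
#' @return integer link count k.
#' @export
link_budget <- function(N, t = 0.01) {
  if (N < 2) stop("link budget requires N >= 2")
  if (t <= 0 || t >= 1) stop("t must be in (0, 1)")
  max(1L, as.integer(floor(t * N * (N - 1) / 2)))
}

#' Build the asymmetry graph
#'
#' Ranks all N(N-1)/2 unordered node pairs by asymmetry (descending) and
#' retains the top `link_budget(N, t)` pairs with strictly positive
#' asymmetry. Candidate pairs are NOT restricted to food-web links:
#' indirect-only pairs compete equally, so the asymmetry graph may contain
#' links absent from the food web. Each retained pair becomes one directed
#' link from the stronger affecter (larger TI^n towards the other node) to
#' the weaker, weighted by the asymmetry value. Ties at the cutoff rank are
#' broken deterministically by (asymmetry descending, source label, target
#' label). Zero-asymmetry pairs are never admitted, so the graph may hold
#' fewer than k links. Nodes incident to no retained link are excluded.
#'
#' This is the package's central operation; [asymmetry_graph] wraps the TI
#' computation and this builder into one call.
#'
#' @param asym symmetric asymmetry matrix from [asymmetry_matrix].
#' @param ti the `effect_matrix` the asymmetries came from (fixes link
#'   orientation).
#' @param t threshold fraction.
#' @return an object of class `asymmetry_graph` with fields `links`
#'   (data frame: source, target, weight), `nodes`, `threshold_fraction`,
#'   `link_budget`.
#' @export
build_asymmetry_graph <- function(asym, ti, t = 0.01) {
  stopifnot(identical(rownames(asym), rownames(unclass(ti))))
  N <- nrow(asym)
  k <- link_budget(N, t)
  labels <- rownames(asym)
  ut <- which(upper.tri(asym), arr.ind = TRUE)
  w <- asym[ut]
  pos <- w > 0
  if (!any(pos)) {
    warning("all pairwise asymmetries are zero; asymmetry graph is empty")
  }
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  M <- unclass(ti)
  # orient each pair from the stronger affecter to the weaker
  forward <- M[ut] >= M[ut[, c(2L, 1L), drop = FALSE]]
  src <- ifelse(forward, labels[ut[, 1L]], labels[ut[, 2L]])
  tgt <- ifelse(forward, labels[ut[, 2L]], labels[ut[, 1L]])
  ord <- order(-w, src, tgt)
  take <- ord[seq_len(min(k, length(ord)))]
  links <- data.frame(source = src[take], target = tgt[take],
                      weight = w[take], stringsAsFactors = FALSE)
  structure(
    list(links = links,
         nodes = sort(unique(c(links$source, links$target))),
         threshold_fraction = t,
         link_budget = k,
         n_steps = attr(ti, "steps"),
         web_nodes = labels),
    class = "asymmetry_graph"
  )
}

#' Compute the asymmetry graph of a food web
#'
#' One-call pipeline: normalized TI^n matrix, pairwise asymmetries, and the
#' thresholded directed asymmetry graph. Defaults reproduce the study
#' configuration (n = 3 steps, top 1% of pairs).
#'
#' @param web a [food_web].
#' @param n number of TI steps (default 3).
#' @param t threshold fraction (default 0.01).
#' @param normalize normalize the TI matrix (affects reported weights only,
#'   never the graph's topology).
#' @return an `asymmetry_graph`; the TI matrix is attached as `$ti`.
#' @export
asymmetry_graph <- function(web, n = 3, t = 0.01, normalize = TRUE) {
  ti <- ti_matrix(web, n = n, normalize = normalize)
  ag <- build_asymmetry_graph(asymmetry_matrix(ti), ti, t = t)
  ag$web_id <- web$web_id
  ag$ti <- ti
  ag
}

#' @export
print.asymmetry_graph <- function(x, ...) {
  cat("asymmetry_graph",
      if (!is.null(x$web_id)) paste0(" '", x$web_id, "'"),
      ": ", length(x$nodes), " nodes, ", nrow(x$links), " links ",
      "(budget ", x$link_budget, " at t = ", x$threshold_fraction,
      ", n = ", x$n_steps, " steps)\n", sep = "")
  cat(if (is_dag(x)) "directed acyclic graph" else "contains directed cycles",
      ", ", component_count(x), " weakly connected component(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.asymmetry_graph <- function(object, ...) {
  print(object)
  if (nrow(object$links) > 0L) {
    cat("\nlinks (by asymmetry):\n")
    print(object$links, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.asymmetry_graph <- function(x, ...) {
  g <- asymmetry_graph_as_igraph(x)
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    igraph::plot.igraph(g, edge.width = 1 + 4 * w / max(w),
                        edge.arrow.size = 0.5, ...)
  } else {
    igraph::plot.igraph(g, ...)
  }
  invisible(x)
}

asymmetry_graph_as_igraph <- function(ag) {
  igraph::graph_from_data_frame(
    ag$links, directed = TRUE,
    vertices = data.frame(name = ag$nodes, stringsAsFactors = FALSE)
  )
}

#' Is the asymmetry graph acyclic?
#'
#' TRUE iff the directed link set admits a topological order. The empty
#' graph is acyclic.
#'
#' @param ag an `asymmetry_graph`.
#' @return logical flag.
#' @export
is_dag <- function(ag) {
  if (nrow(ag$links) == 0L) return(TRUE)
  igraph::is_dag(asymmetry_graph_as_igraph(ag))
}

#' Weakly connected components of the asymmetry graph
#'
#' Counted over nodes incident to at least one link only; the empty graph
#' has zero components.
#'
#' @param ag an `asymmetry_graph`.
#' @return integer component count.
#' @export
component_count <- function(ag) {
  if (nrow(ag$links) == 0L) return(0L)
  igraph::count_components(asymmetry_graph_as_igraph(ag), mode = "weak")
}

#' Export an asymmetry graph
#'
#' @param ag an `asymmetry_graph`.
#' @param path output path.
#' @param format `"tsv"` (source, target, weight) or `"graphml"` (with a
#'   `weight` edge attribute).
#' @export
write_asymmetry_graph <- function(ag, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(ag$links, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(asymmetry_graph_as_igraph(ag), path,
                        format = "graphml")
  }
  invisible(path)
}
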