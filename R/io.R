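#' Read a food web from an edge list
#'
#' Reads a two-column, tab-separated edge list (one interaction per line,
#' `#`-comments and blank lines ignored, any third column dropped on
#' binarization). Self-loops and duplicate edges are removed.
#'
#' @param path path to a TSV file.
#' @param directed interpret rows as directed prey-to-predator links and
#'   derive the undirected edge set by symmetrization.
#' @param web_id label for the web; defaults to the file name.
#' @return a [food_web].
#' @export
read_edge_list <- function(path, directed = FALSE,
                           web_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) stop("empty edge list: ", path)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list row at line ", keep[bad[1L]], " of ", path)
  }
  el <- t(vapply(parts, function(p) p[1:2], character(2L)))
  nodes <- unique(c(el))
  if (directed) {
    food_web(nodes, trophic_edges = el, web_id = web_id)
  } else {
    food_web(nodes, edges = el, web_id = web_id)
  }
}

#' Write a food web as an edge list
#'
#' Writes the undirected edges (or the directed trophic edges) as a
#' two-column TSV that [read_edge_list] reads back to an identical graph.
#'
#' @param web a [food_web].
#' @param path output path.
#' @param directed write the directed trophic edges instead.
#' @export
write_edge_list <- function(web, path, directed = FALSE) {
  el <- if (directed) web$trophic_edges else web$undirected_edges
  if (is.null(el)) stop("web has no directed trophic edges to write")
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a food web from an Ecopath-style diet matrix
#'
#' Reads a CSV whose rows are prey, columns are predators, and cells hold
#' diet proportions in \[0, 1\]. A prey-to-predator link is recorded
#' wherever the proportion exceeds `presence_threshold` (default 0: any
#' trophic flow counts as a link; the threshold is configurable because
#' Ecopath exports may contain tiny numerical residue). Diagonal entries
#' (cannibalism) are dropped with a warning. The undirected binary web is
#' the symmetrized link set.
#'
#' @param path path to the CSV (first column = prey labels, header row =
#'   predator labels).
#' @param presence_threshold diet proportion strictly above which a link is
#'   recorded.
#' @param web_id label for the web; defaults to the file name.
#' @return a [food_web] with `trophic_edges`.
#' @export
read_diet_matrix <- function(path, presence_threshold = 0,
                             web_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  suppressWarnings(storage.mode(M) <- "numeric")
  if (anyNA(M)) stop("non-numeric cell(s) in diet matrix: ", path)
  if (any(M < 0)) stop("negative diet proportion(s) in: ", path)
  prey <- rownames(M)
  pred <- colnames(M)
  nodes <- unique(c(prey, pred))
  shared <- intersect(prey, pred)
  diag_hits <- shared[vapply(shared, function(s)
    M[s, s] > presence_threshold, logical(1L))]
  if (length(diag_hits) > 0L) {
    warning("cannibalistic diagonal entr", if (length(diag_hits) > 1L) "ies"
            else "y", " dropped for: ", paste(diag_hits, collapse = ", "))
    for (s in diag_hits) M[s, s] <- 0
  }
  hit <- which(M > presence_threshold, arr.ind = TRUE)
  te <- cbind(prey[hit[, 1L]], pred[hit[, 2L]])
  food_web(nodes, trophic_edges = te, web_id = web_id)
}

#' Attach per-node attributes from a CSV
#'
#' Reads a CSV with a `node` column and any of `biomass`, `ee`, `tl` and
#' attaches the values to the web. Labels not present in the web raise an
#' error naming them; nodes without a row keep absent attribute values.
#' Out-of-range ecotrophic efficiencies are accepted on read — filtering of
#' unrealistic values happens when indicators are computed.
#'
#' @param path path to the attribute CSV.
#' @param web the [food_web] to attach attributes to.
#' @return the web with `attributes` set.
#' @export
read_node_attributes <- function(path, web) {
  stopifnot(inherits(web, "food_web"))
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  web$attributes <- validate_attributes(df, web$nodes)
  web
}

#' Filter a collection of food webs
#'
#' Keeps webs with strictly more than `min_nodes` nodes whose id is not in
#' `exclude_ids`, preserving input order. The strict inequality follows the
#' study design of retaining only webs with more than 50 nodes; excluded ids
#' cover manual de-duplication of repeated models.
#'
#' @param webs list of [food_web] objects.
#' @param min_nodes keep webs with node count strictly greater than this.
#' @param exclude_ids character vector of web ids to drop.
#' @return the filtered list, in input order.
#' @export
filter_collection <- function(webs, min_nodes = 50, exclude_ids = character()) {
  keep <- vapply(webs, function(w) {
    length(w$nodes) > min_nodes && !(w$web_id %in% exclude_ids)
  }, logical(1L))
  webs[keep]
}
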