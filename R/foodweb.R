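#' Construct a food web
#'
#' A `food_web` is a binary, undirected interaction network over a set of
#' named compartments (species or trophic groups), optionally carrying the
#' directed prey-to-predator links it was derived from and per-node
#' attributes (biomass, ecotrophic efficiency, trophic level).
#'
#' Nodes are stored in lexicographic label order unless `keep_order = TRUE`;
#' every matrix produced downstream (effect matrices, asymmetry matrices)
#' indexes nodes in this fixed order. Self-loops (cannibalism) are dropped
#' with a warning because they would distort node degree and hence every
#' TI-based quantity.
#'
#' @param nodes character vector of node labels (duplicates removed).
#' @param edges two-column character matrix or data frame of undirected
#'   edges; may be `NULL` together with `trophic_edges`.
#' @param trophic_edges optional two-column matrix/data frame of directed
#'   prey-to-predator links; the undirected edge set is derived from it by
#'   symmetrization when `edges` is `NULL`.
#' @param attributes optional data frame with a `node` column and any of
#'   `biomass`, `ee`, `tl`.
#' @param web_id text label for the web.
#' @param keep_order keep node labels in the order given instead of sorting.
#' @return an object of class `food_web`.
#' @export
food_web <- function(nodes, edges = NULL, trophic_edges = NULL,
                     attributes = NULL, web_id = "web",
                     keep_order = FALSE) {
  nodes <- unique(as.character(nodes))
  if (!keep_order) nodes <- sort(nodes)
  if (any(is.na(nodes)) || any(nodes == "")) {
    stop("node labels must be non-missing, non-empty strings")
  }

  clean_pairs <- function(x, what) {
    if (is.null(x) || NROW(x) == 0L) {
      return(matrix(character(0), ncol = 2L,
                    dimnames = list(NULL, c("from", "to"))))
    }
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop(what, " must have two columns")
    x <- cbind(as.character(x[, 1L]), as.character(x[, 2L]))
    bad <- setdiff(c(x), nodes)
    if (length(bad) > 0L) {
      stop(what, " reference unknown node(s): ", paste(bad, collapse = ", "))
    }
    loops <- x[, 1L] == x[, 2L]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from ", what)
      x <- x[!loops, , drop = FALSE]
    }
    colnames(x) <- c("from", "to")
    x
  }

  te <- clean_pairs(trophic_edges, "trophic_edges")
  te <- unique(te)
  if (is.null(edges)) {
    ue <- te
  } else {
    ue <- clean_pairs(edges, "edges")
  }
  # canonical undirected representation: endpoints sorted within each row
  if (nrow(ue) > 0L) {
    ue <- t(apply(ue, 1L, sort))
    colnames(ue) <- c("from", "to")
    ue <- unique(ue)
  }

  if (!is.null(attributes)) {
    attributes <- validate_attributes(attributes, nodes)
  }

  structure(
    list(web_id = as.character(web_id)[1L],
         nodes = nodes,
         undirected_edges = ue,
         trophic_edges = if (nrow(te) > 0L || !is.null(trophic_edges)) te else NULL,
         attributes = attributes),
    class = "food_web"
  )
}

validate_attributes <- function(attributes, nodes) {
  attributes <- as.data.frame(attributes)
  if (!"node" %in% names(attributes)) {
    stop("attribute table must contain a 'node' column")
  }
  attributes$node <- as.character(attributes$node)
  dup <- attributes$node[duplicated(attributes$node)]
  if (length(dup) > 0L) {
    stop("duplicate attribute rows for node(s): ",
         paste(unique(dup), collapse = ", "))
  }
  unknown <- setdiff(attributes$node, nodes)
  if (length(unknown) > 0L) {
    stop("attribute rows for unknown node(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- intersect(c("node", "biomass", "ee", "tl"), names(attributes))
  attributes <- attributes[, keep, drop = FALSE]
  for (col in setdiff(keep, "node")) {
    attributes[[col]] <- as.numeric(attributes[[col]])
  }
  if ("biomass" %in% keep && any(attributes$biomass < 0, na.rm = TRUE)) {
    stop("biomass must be non-negative")
  }
  attributes
}

#' @export
print.food_web <- function(x, ...) {
  cat("food_web '", x$web_id, "': ", length(x$nodes), " nodes, ",
      nrow(x$undirected_edges), " undirected links",
      if (!is.null(x$trophic_edges))
        paste0(" (", nrow(x$trophic_edges), " directed trophic links)"),
      "\n", sep = "")
  if (!is.null(x$attributes)) {
    cat("attributes: ",
        paste(setdiff(names(x$attributes), "node"), collapse = ", "),
        " for ", nrow(x$attributes), " nodes\n", sep = "")
  }
  invisible(x)
}

#' Number of nodes / links of a food web
#' @param web a `food_web`.
#' @return integer count.
#' @export
n_nodes <- function(web) length(web$nodes)

#' @rdname n_nodes
#' @export
n_links <- function(web) nrow(web$undirected_edges)

#' Convert a food web to an igraph object
#'
#' @param web a `food_web`.
#' @param directed use the directed prey-to-predator links (requires
#'   `trophic_edges`).
#' @return an `igraph` graph whose vertices follow the web's node order.
#' @export
as_igraph <- function(web, directed = FALSE) {
  stopifnot(inherits(web, "food_web"))
  if (directed) {
    if (is.null(web$trophic_edges)) {
      stop("web '", web$web_id, "' has no directed trophic edges")
    }
    el <- web$trophic_edges
  } else {
    el <- web$undirected_edges
  }
  igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = web$nodes, stringsAsFactors = FALSE)
  )
}

#' Adjacency matrix of the undirected binary web
#' @param web a `food_web`.
#' @return symmetric 0/1 matrix in node order.
#' @keywords internal
adjacency_matrix <- function(web) {
  n <- length(web$nodes)
  A <- matrix(0, n, n, dimnames = list(web$nodes, web$nodes))
  if (nrow(web$undirected_edges) > 0L) {
    idx <- cbind(match(web$undirected_edges[, 1L], web$nodes),
                 match(web$undirected_edges[, 2L], web$nodes))
    A[idx] <- 1
    A[idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}
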