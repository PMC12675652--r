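#' Prey-averaged trophic levels
#'
#' Solves the standard Ecopath convention exactly: basal species (no prey)
#' have trophic level 1; every other species has level 1 plus the
#' unweighted mean level of its prey. The defining linear system
#' `(I - W) TL = 1`, with W the row-normalized prey matrix, is solved
#' directly, so trophic loops (other than self-loops, which the food-web
#' container already removes) are permitted whenever the system is
#' non-singular.
#'
#' If the web carries precomputed `tl` attributes for every node, those
#' take precedence (`method = "provided"`); otherwise directed trophic
#' edges are required.
#'
#' @param web a [food_web].
#' @return a `trophic_assignment`: list with `levels` (named numeric, all
#'   >= 1), `basal` (labels of prey-less nodes) and `method`
#'   (`"prey-averaged"` or `"provided"`).
#' @export
trophic_levels <- function(web) {
  stopifnot(inherits(web, "food_web"))
  nodes <- web$nodes
  tl_attr <- NULL
  if (!is.null(web$attributes) && "tl" %in% names(web$attributes)) {
    tl_attr <- web$attributes$tl[match(nodes, web$attributes$node)]
  }
  if (!is.null(tl_attr) && !anyNA(tl_attr)) {
    names(tl_attr) <- nodes
    basal <- nodes[abs(tl_attr - 1) < 1e-9]
    return(structure(list(levels = tl_attr, basal = basal,
                          method = "provided"),
                     class = "trophic_assignment"))
  }
  if (is.null(web$trophic_edges)) {
    stop("web '", web$web_id, "' has neither directed trophic edges nor ",
         "complete 'tl' attributes")
  }
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  te <- web$trophic_edges
  if (nrow(te) > 0L) {
    # row = consumer, column = prey
    W[cbind(match(te[, 2L], nodes), match(te[, 1L], nodes))] <- 1
  }
  nprey <- rowSums(W)
  eats <- nprey > 0
  W[eats, ] <- W[eats, , drop = FALSE] / nprey[eats]
  levels <- tryCatch(
    solve(diag(n) - W, rep(1, n)),
    error = function(e) {
      g <- as_igraph(web, directed = TRUE)
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1L)]
      stop("trophic-level system is singular; strongly connected trophic ",
           "cycle involves: ", paste(sort(cyc), collapse = ", "),
           call. = FALSE)
    }
  )
  names(levels) <- nodes
  structure(list(levels = levels, basal = nodes[!eats],
                 method = "prey-averaged"),
            class = "trophic_assignment")
}

#' @export
print.trophic_assignment <- function(x, ...) {
  cat("trophic_assignment (", x$method, "): ", length(x$levels),
      " nodes, ", length(x$basal), " basal, max TL ",
      format(max(x$levels), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Export trophic levels as CSV
#' @param tl a `trophic_assignment`.
#' @param path output path.
#' @export
write_trophic_levels <- function(tl, path) {
  df <- data.frame(node = names(tl$levels), level = unname(tl$levels),
                   basal = names(tl$levels) %in% tl$basal)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classify asymmetry-graph links as bottom-up or top-down
#'
#' A link s -> t is bottom-up when the source sits at a lower trophic level
#' than the target (food-provision direction), top-down when higher
#' (consumer-control direction), and lateral when the two levels are equal
#' to within 1e-9. Lateral links are counted in neither class: the
#' bottom-up/top-down dichotomy presumes unequal levels, and silently
#' assigning ties would bias the counts.
#'
#' @param ag an `asymmetry_graph`.
#' @param tl a `trophic_assignment` covering every asymmetry-graph node.
#' @return list with `classes` (the link data frame plus a `class` column),
#'   `bu`, `td` and `lateral` counts.
#' @export
classify_links <- function(ag, tl) {
  links <- ag$links
  missing_tl <- setdiff(ag$nodes, names(tl$levels))
  if (length(missing_tl) > 0L) {
    stop("no trophic level for asymmetry-graph node(s): ",
         paste(missing_tl, collapse = ", "))
  }
  if (nrow(links) == 0L) {
    links$class <- character(0)
    return(list(classes = links, bu = 0L, td = 0L, lateral = 0L))
  }
  d <- tl$levels[links$target] - tl$levels[links$source]
  cls <- ifelse(abs(d) <= 1e-9, "lateral",
                ifelse(d > 0, "bottom-up", "top-down"))
  links$class <- cls
  list(classes = links,
       bu = sum(cls == "bottom-up"),
       td = sum(cls == "top-down"),
       lateral = sum(cls == "lateral"))
}
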