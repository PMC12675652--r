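indicator_columns <- c(
  "web_id", "Nfw", "Lfw", "Cfw", "avDISTfw", "Tfw", "avTLfw", "maxTLfw",
  "carn_ratio", "Nag", "Lag", "COMPag", "BUag", "TDag", "td_bu_ratio",
  "Nsoag", "Nsiag", "Nag_over_Nfw", "Lag_over_Lfw", "Sh", "TB", "EE"
)

#' Food-web structural indicators
#'
#' Eight topological properties of the undirected binary web: node count
#' (Nfw), link count (Lfw), connectance Cfw = Lfw / (Nfw(Nfw-1)/2), mean
#' shortest-path length avDISTfw (over connected unordered pairs only;
#' unreachable pairs are excluded and their count logged), global
#' transitivity Tfw (3 x triangles / connected triples), average and
#' maximum trophic level, and the fraction of nodes with TL > 2
#' (carnivores/omnivores; exact herbivores at TL = 2 are excluded via a
#' 1e-9 tolerance).
#'
#' @param web a [food_web] with at least 2 nodes.
#' @param tl a `trophic_assignment` for the web.
#' @return named list of the eight indicators.
#' @export
foodweb_indicators <- function(web, tl) {
  N <- length(web$nodes)
  if (N < 2L) stop("food-web indicators require at least 2 nodes")
  L <- nrow(web$undirected_edges)
  g <- as_igraph(web, directed = FALSE)
  D <- igraph::distances(g)
  finite <- is.finite(D[upper.tri(D)])
  if (any(!finite)) {
    message(sum(!finite), " unreachable pair(s) excluded from avDISTfw in ",
            "web '", web$web_id, "'")
  }
  avdist <- if (any(finite)) mean(D[upper.tri(D)][finite]) else NA_real_
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0  # no connected triples
  lv <- tl$levels[web$nodes]
  list(Nfw = N,
       Lfw = L,
       Cfw = L / (N * (N - 1) / 2),
       avDISTfw = avdist,
       Tfw = trans,
       avTLfw = mean(lv),
       maxTLfw = max(lv),
       carn_ratio = sum(lv > 2 + 1e-9) / N)
}

#' Asymmetry-graph structural indicators
#'
#' Eight properties of the directed asymmetry graph: node count (Nag), link
#' count (Lag), weak-component count (COMPag), bottom-up and top-down link
#' counts (BUag, TDag), their ratio TDag/BUag (missing when BUag = 0 —
#' neither zero nor infinity), source count Nsoag (only outgoing links) and
#' sink count Nsiag (only incoming links).
#'
#' @param ag an `asymmetry_graph`.
#' @param classes result of [classify_links] for `ag`.
#' @return named list of the eight indicators.
#' @export
asymgraph_indicators <- function(ag, classes) {
  links <- ag$links
  outdeg <- table(factor(links$source, levels = ag$nodes))
  indeg <- table(factor(links$target, levels = ag$nodes))
  list(Nag = length(ag$nodes),
       Lag = nrow(links),
       COMPag = component_count(ag),
       BUag = classes$bu,
       TDag = classes$td,
       td_bu_ratio = if (classes$bu > 0) classes$td / classes$bu else NA_real_,
       Nsoag = sum(outdeg > 0 & indeg == 0),
       Nsiag = sum(indeg > 0 & outdeg == 0))
}

#' Combined food-web / asymmetry-graph ratios
#'
#' Nag/Nfw and Lag/Lfw. Lag may exceed Lfw in principle because asymmetry
#' links can join indirect pairs; only Nag <= Nfw is guaranteed.
#'
#' @param fw result of [foodweb_indicators].
#' @param ag result of [asymgraph_indicators].
#' @return named list with `Nag_over_Nfw` and `Lag_over_Lfw`.
#' @export
combined_ratios <- function(fw, ag) {
  list(Nag_over_Nfw = ag$Nag / fw$Nfw,
       Lag_over_Lfw = if (fw$Lfw > 0) ag$Lag / fw$Lfw else NA_real_)
}

#' Non-network ecosystem indicators
#'
#' Total biomass TB (sum of node biomasses), Shannon diversity
#' Sh = -sum p_i ln p_i over nodes with positive biomass (p_i the biomass
#' proportion, natural log), and mean ecotrophic efficiency EE over values
#' inside `ee_valid_range`. EE values outside the range are unrealistic
#' under the Ecopath balance convention (EE <= 1) and are omitted with a
#' log message naming node and value.
#'
#' @param web a [food_web] with attributes.
#' @param ee_valid_range length-2 numeric interval of admissible EE values.
#' @return named list with `Sh`, `TB`, `EE` (missing where inputs are
#'   absent).
#' @export
nonnetwork_indicators <- function(web, ee_valid_range = c(0, 1)) {
  out <- list(Sh = NA_real_, TB = NA_real_, EE = NA_real_)
  at <- web$attributes
  if (!is.null(at) && "biomass" %in% names(at)) {
    b <- at$biomass[!is.na(at$biomass)]
    if (length(b) > 0L) {
      out$TB <- sum(b)
      p <- b[b > 0] / sum(b[b > 0])
      out$Sh <- -sum(p * log(p))
    }
  }
  if (!is.null(at) && "ee" %in% names(at)) {
    ok <- !is.na(at$ee)
    valid <- ok & at$ee >= ee_valid_range[1L] & at$ee <= ee_valid_range[2L]
    dropped <- which(ok & !valid)
    for (i in dropped) {
      message("omitting unrealistic EE for node '", at$node[i], "' (",
              format(at$ee[i]), ") in web '", web$web_id, "'")
    }
    if (any(valid)) out$EE <- mean(at$ee[valid])
  }
  out
}

#' All 21 systemic indicators for one web
#'
#' Runs the full per-web pipeline: trophic levels, TI^n matrix, asymmetry
#' graph, link classification, and the 8 + 8 + 2 + 3 indicators.
#'
#' @param web a [food_web].
#' @param t asymmetry threshold fraction (default 0.01).
#' @param n number of TI steps (default 3).
#' @param ee_valid_range admissible ecotrophic-efficiency interval.
#' @return one-row data frame in the fixed 21-variable column order (plus
#'   `web_id`).
#' @export
indicator_record <- function(web, t = 0.01, n = 3, ee_valid_range = c(0, 1)) {
  tl <- trophic_levels(web)
  ag <- asymmetry_graph(web, n = n, t = t)
  cls <- classify_links(ag, tl)
  fw <- foodweb_indicators(web, tl)
  agi <- asymgraph_indicators(ag, cls)
  comb <- combined_ratios(fw, agi)
  nn <- nonnetwork_indicators(web, ee_valid_range)
  rec <- c(list(web_id = web$web_id), fw, agi, comb, nn)
  as.data.frame(rec[indicator_columns], stringsAsFactors = FALSE)
}

#' Indicator table for a collection of webs
#'
#' One row per web in the fixed 21-variable order. A web whose pipeline
#' fails yields a row of missing values (with the error logged) and the
#' batch continues.
#'
#' @param webs list of [food_web] objects.
#' @param t asymmetry threshold fraction.
#' @param n number of TI steps.
#' @param ee_valid_range admissible ecotrophic-efficiency interval.
#' @return data frame with one row per web and 22 columns (`web_id` + 21
#'   indicators).
#' @export
indicator_table <- function(webs, t = 0.01, n = 3,
                            ee_valid_range = c(0, 1)) {
  rows <- lapply(webs, function(w) {
    tryCatch(
      suppressMessages(indicator_record(w, t = t, n = n,
                                        ee_valid_range = ee_valid_range)),
      error = function(e) {
        message("indicator pipeline failed for web '", w$web_id, "': ",
                conditionMessage(e))
        row <- as.data.frame(
          c(list(web_id = w$web_id),
            stats::setNames(as.list(rep(NA_real_,
                                        length(indicator_columns) - 1L)),
                            indicator_columns[-1L])),
          stringsAsFactors = FALSE)
        row
      })
  })
  do.call(rbind, rows)
}

#' Indicator rows across sensitivity thresholds
#'
#' Recomputes the asymmetry-graph-dependent indicators at each threshold in
#' `thresholds` (defaults to the study's sensitivity set 0.5%, 1%, 5%, 10%,
#' 20%) and returns one row per web and threshold with a leading
#' `threshold` column.
#'
#' @param webs list of [food_web] objects.
#' @param thresholds numeric vector of threshold fractions.
#' @param n number of TI steps.
#' @return data frame with `threshold` + the indicator columns.
#' @export
sensitivity_table <- function(webs, thresholds = c(0.005, 0.01, 0.05,
                                                   0.10, 0.20), n = 3) {
  out <- lapply(thresholds, function(t) {
    cbind(threshold = t, indicator_table(webs, t = t, n = n))
  })
  do.call(rbind, out)
}
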