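#' Generate a niche-model food web
#'
#' Classic niche-model construction: each species draws a niche value
#' uniform on (0, 1) and a feeding range of beta-distributed width
#' calibrated so the expected directed connectance (links / N^2) matches
#' `connectance`; the range centre is drawn below the species' own niche
#' value, and a species eats every species whose niche value falls inside
#' its range. Self-loops are removed. A candidate web is redrawn (from the
#' same seeded stream) until it is connected, has no trophically duplicate
#' species, and contains at least one basal species; generation fails after
#' `max_tries` attempts.
#'
#' @param n_species number of species (>= 5).
#' @param connectance target directed connectance in (0, 1).
#' @param seed integer seed; same seed gives bit-identical webs.
#' @param web_id label for the web.
#' @param max_tries bound on redraws.
#' @return a [food_web] with directed trophic edges, nodes labelled
#'   `s001..sNNN` in niche order.
#' @export
niche_model_web <- function(n_species, connectance, seed,
                            web_id = paste0("niche_", seed),
                            max_tries = 200L) {
  if (n_species < 5L) stop("niche model needs at least 5 species")
  if (connectance <= 0 || connectance >= 1) {
    stop("connectance must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  beta <- 1 / (2 * connectance) - 1
  if (beta <= 0) stop("connectance too high for the niche model")
  n <- n_species
  adjacency <- function(eta, lo, hi) {
    eats <- outer(seq_len(n), seq_len(n),
                  function(i, j) eta[j] >= lo[i] & eta[j] <= hi[i])
    diag(eats) <- FALSE
    eats
  }
  draw_range <- function(eta_i) {
    r <- eta_i * stats::rbeta(1L, 1, beta)
    ctr <- stats::runif(1L, r / 2, pmin(eta_i, 1 - r / 2))
    c(ctr - r / 2, ctr + r / 2)
  }
  for (try in seq_len(max_tries)) {
    eta <- sort(stats::runif(n))
    rng <- vapply(eta, draw_range, numeric(2L))
    lo <- rng[1L, ]; hi <- rng[2L, ]
    lo[1L] <- 1; hi[1L] <- 0  # smallest-niche species is guaranteed basal
    # repair pass (classic procedure): species that end up isolated or
    # trophically identical to another get a fresh feeding range
    for (repair in 1:50) {
      eats <- adjacency(eta, lo, hi)
      link <- eats | t(eats)
      bad <- which(colSums(link) == 0L)
      sig <- apply(cbind(eats, t(eats)), 1L, paste, collapse = "")
      bad <- union(bad, which(duplicated(sig)))
      bad <- setdiff(bad, 1L)
      if (length(bad) == 0L) break
      for (i in bad) {
        rng_i <- draw_range(eta[i])
        lo[i] <- rng_i[1L]; hi[i] <- rng_i[2L]
      }
    }
    eats <- adjacency(eta, lo, hi)
    sig <- apply(cbind(eats, t(eats)), 1L, paste, collapse = "")
    if (anyDuplicated(sig)) next
    idx <- which(eats, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    labels <- sprintf("s%03d", seq_len(n))
    te <- cbind(labels[idx[, 2L]], labels[idx[, 1L]])  # prey -> predator
    web <- food_web(labels, trophic_edges = te, web_id = web_id)
    g <- as_igraph(web, directed = FALSE)
    if (!igraph::is_connected(g)) next
    if (length(trophic_basal(web)) == 0L) next
    if (inherits(tryCatch(trophic_levels(web), error = function(e) e),
                 "error")) next  # pathological trophic cycle: redraw
    return(web)
  }
  stop("could not generate an admissible niche-model web in ",
       max_tries, " tries (n = ", n_species, ", C = ", connectance, ")")
}

trophic_basal <- function(web) {
  consumers <- unique(web$trophic_edges[, 2L])
  setdiff(web$nodes, consumers)
}

#' Generate an Ecopath-style synthetic food web
#'
#' Emulates the compartment structure of mass-balance (Ecopath) models,
#' which differs from the pure niche model in one ecologically crucial
#' respect: the basal guild (producers and detritus) is an explicit,
#' sizeable fraction of compartments and is consumed by much of the web,
#' so node degree declines with trophic level — few, sparsely linked top
#' predators over a richly connected base. The web is built from
#'
#' * `basal_fraction * n_species` basal resources with no prey;
#' * consumers wired among themselves by the classic niche rule (niche
#'   values uniform, contiguous feeding ranges of beta-distributed width
#'   calibrated to `connectance` among consumers);
#' * consumer-basal links drawn independently with probability
#'   `0.05 + 0.75 * (1 - eta)^2` for a consumer at niche position `eta`:
#'   low-position consumers (herbivores, detritivores) feed on most basal
#'   resources, top consumers rarely. Every consumer keeps at least one
#'   prey and every basal resource at least one consumer.
#'
#' Candidate webs are redrawn until connected with solvable trophic
#' levels. Fully seed-deterministic.
#'
#' @param n_species total number of compartments.
#' @param connectance target directed connectance among consumers.
#' @param basal_fraction fraction of compartments that are basal.
#' @param seed integer seed.
#' @param web_id label for the web.
#' @param max_tries bound on redraws.
#' @return a [food_web] with directed trophic edges; basal resources are
#'   labelled `b...`, consumers `c...` in niche order.
#' @export
ecopath_web <- function(n_species, connectance, basal_fraction = 0.2,
                        seed = 1, web_id = paste0("ecopath_", seed),
                        max_tries = 200L) {
  if (n_species < 5L) stop("needs at least 5 species")
  if (connectance <= 0 || connectance >= 1) {
    stop("connectance must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  n_b <- max(2L, round(basal_fraction * n_species))
  n_c <- n_species - n_b
  if (n_c < 3L) stop("basal_fraction leaves too few consumers")
  beta <- 1 / connectance - 1
  if (beta <= 0) stop("connectance too high")
  for (try in seq_len(max_tries)) {
    eta <- sort(stats::runif(n_c))
    r <- pmin(eta, stats::rbeta(n_c, 1, beta))
    ctr <- stats::runif(n_c, r / 2, pmin(eta, 1 - r / 2))
    lo <- ctr - r / 2
    hi <- ctr + r / 2
    cc <- outer(seq_len(n_c), seq_len(n_c),
                function(i, j) eta[j] >= lo[i] & eta[j] <= hi[i])
    diag(cc) <- FALSE
    q <- 0.05 + 0.75 * (1 - eta)^2
    cb <- matrix(stats::runif(n_c * n_b), n_c, n_b) < q
    none <- which(rowSums(cc) + rowSums(cb) == 0L)
    for (i in none) cb[i, sample.int(n_b, 1L)] <- TRUE
    orphan <- which(colSums(cb) == 0L)
    for (b in orphan) cb[sample.int(n_c, 1L, prob = q), b] <- TRUE
    blabs <- sprintf("b%03d", seq_len(n_b))
    clabs <- sprintf("c%03d", seq_len(n_c))
    i1 <- which(cc, arr.ind = TRUE)
    i2 <- which(cb, arr.ind = TRUE)
    te <- rbind(cbind(clabs[i1[, 2L]], clabs[i1[, 1L]]),
                cbind(blabs[i2[, 2L]], clabs[i2[, 1L]]))
    web <- food_web(c(blabs, clabs), trophic_edges = te, web_id = web_id)
    if (!igraph::is_connected(as_igraph(web))) next
    if (inherits(tryCatch(trophic_levels(web), error = function(e) e),
                 "error")) next
    return(web)
  }
  stop("could not generate an admissible web in ", max_tries, " tries")
}

#' Attach synthetic biomass and ecotrophic-efficiency attributes
#'
#' Emulates Ecopath outputs: biomass is lognormal with median decaying
#' geometrically in trophic level — median at level TL is
#' `basal_biomass * decay^(TL - 1)`, so with the default decay of 0.1 per
#' level a level-3 species carries a median biomass 1% of a producer's.
#' Ecotrophic efficiency is uniform on `ee_range`. Both draws are
#' seed-deterministic.
#'
#' @param web a [food_web] whose trophic levels are computable.
#' @param seed integer seed.
#' @param basal_biomass median biomass (mass per area) at trophic level 1.
#' @param decay multiplicative biomass decay per trophic level, in (0, 1).
#' @param sdlog lognormal shape on the log scale.
#' @param ee_range uniform interval for ecotrophic efficiency.
#' @return the web with `attributes` attached (biomass, ee, tl).
#' @export
assign_attributes <- function(web, seed, basal_biomass = 100,
                              decay = 0.1, sdlog = 1,
                              ee_range = c(0, 1)) {
  set.seed(as.integer(seed))
  tl <- trophic_levels(web)$levels
  medians <- basal_biomass * decay^(tl - 1)
  biomass <- stats::rlnorm(length(tl), meanlog = log(medians), sdlog = sdlog)
  ee <- stats::runif(length(tl), ee_range[1L], ee_range[2L])
  web$attributes <- data.frame(node = web$nodes,
                               biomass = unname(biomass),
                               ee = unname(ee),
                               tl = unname(tl),
                               stringsAsFactors = FALSE)
  web
}

#' Generate a synthetic food-web collection
#'
#' A seeded stand-in for a curated mass-balance model collection:
#' `n_webs` webs with species counts, consumer connectances and basal
#' fractions drawn uniformly from the given ranges (defaults emulate a
#' filtered collection of webs with more than 50 compartments, typical
#' food-web connectance, and the spread of basal-guild sizes seen across
#' ecosystem types), each with lognormal biomass decaying in trophic
#' level and uniform ecotrophic efficiency. Webs are built with
#' [ecopath_web] by default; `generator = "niche"` substitutes the pure
#' niche model.
#'
#' @param n_webs number of webs (default 34, the study's collection size).
#' @param seed integer master seed; all per-web seeds derive from it.
#' @param species_range inclusive integer range of species counts.
#' @param connectance_range range of target consumer connectance.
#' @param basal_fraction_range range of basal-guild fractions (ignored by
#'   the pure niche generator).
#' @param generator topology generator, `"ecopath"` or `"niche"`.
#' @param ... passed to [assign_attributes].
#' @return list of attributed [food_web] objects.
#' @export
synthetic_collection <- function(n_webs = 34, seed = 1,
                                 species_range = c(55L, 90L),
                                 connectance_range = c(0.05, 0.12),
                                 basal_fraction_range = c(0.1, 0.3),
                                 generator = c("ecopath", "niche"),
                                 ...) {
  generator <- match.arg(generator)
  set.seed(as.integer(seed))
  sizes <- sample(seq(species_range[1L], species_range[2L]), n_webs,
                  replace = TRUE)
  conns <- stats::runif(n_webs, connectance_range[1L], connectance_range[2L])
  fbs <- stats::runif(n_webs, basal_fraction_range[1L],
                      basal_fraction_range[2L])
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * n_webs)
  lapply(seq_len(n_webs), function(i) {
    w <- if (generator == "ecopath") {
      ecopath_web(sizes[i], conns[i], basal_fraction = fbs[i],
                  seed = sub_seeds[i], web_id = sprintf("synth_%03d", i))
    } else {
      niche_model_web(sizes[i], conns[i], seed = sub_seeds[i],
                      web_id = sprintf("synth_%03d", i))
    }
    assign_attributes(w, seed = sub_seeds[n_webs + i], ...)
  })
}

#' Canonical small fixture webs
#'
#' Named list of tiny webs used throughout the documentation and tests:
#' `path3` (A-B-C), `star4` (centre `c0` with three leaves), `cycle4`,
#' `complete4`, `chainPHC` (directed producer -> herbivore -> carnivore)
#' and `toy8`, a synthetic 8-node, 9-link web in the spirit of a classic
#' didactic example (the published example's exact topology is not
#' recoverable from text, so `toy8`'s wiring is this package's own).
#'
#' @return named list of [food_web] objects.
#' @export
fixtures <- function() {
  list(
    path3 = food_web(c("A", "B", "C"),
                     edges = rbind(c("A", "B"), c("B", "C")),
                     web_id = "path3"),
    star4 = food_web(c("c0", "l1", "l2", "l3"),
                     edges = rbind(c("c0", "l1"), c("c0", "l2"),
                                   c("c0", "l3")),
                     web_id = "star4"),
    cycle4 = food_web(c("A", "B", "C", "D"),
                      edges = rbind(c("A", "B"), c("B", "C"),
                                    c("C", "D"), c("D", "A")),
                      web_id = "cycle4"),
    complete4 = food_web(c("A", "B", "C", "D"),
                         edges = t(utils::combn(c("A", "B", "C", "D"), 2L)),
                         web_id = "complete4"),
    chainPHC = food_web(c("P", "H", "C"),
                        trophic_edges = rbind(c("P", "H"), c("H", "C")),
                        web_id = "chainPHC"),
    toy8 = food_web(LETTERS[1:8],
                    trophic_edges = rbind(
                      c("A", "C"), c("A", "D"), c("B", "D"), c("B", "E"),
                      c("C", "F"), c("D", "F"), c("D", "G"), c("E", "G"),
                      c("F", "H")),
                    web_id = "toy8")
  )
}
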