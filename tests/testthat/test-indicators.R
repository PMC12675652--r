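fx <- fixtures()

flat_tl <- function(web) {
  structure(list(levels = stats::setNames(rep(1, length(web$nodes)),
                                          web$nodes),
                 basal = web$nodes, method = "provided"),
            class = "trophic_assignment")
}

test_that("food-web indicators match closed forms on small graphs", {
  k4 <- foodweb_indicators(fx$complete4, flat_tl(fx$complete4))
  expect_equal(k4$Cfw, 1)
  expect_equal(k4$Tfw, 1)
  expect_equal(k4$avDISTfw, 1)

  p3 <- foodweb_indicators(fx$path3, flat_tl(fx$path3))
  expect_equal(p3$avDISTfw, 4 / 3)
  expect_equal(p3$Tfw, 0)
  expect_equal(p3$Cfw, 2 / 3)

  tl <- trophic_levels(fx$chainPHC)
  chain <- foodweb_indicators(fx$chainPHC, tl)
  expect_equal(chain$carn_ratio, 1 / 3)  # only the carnivore has TL > 2
  expect_equal(chain$avTLfw, 2)
  expect_equal(chain$maxTLfw, 3)

  expect_error(foodweb_indicators(food_web("A"), flat_tl(food_web("A"))),
               "at least 2")
})

test_that("disconnected webs average distances over reachable pairs only", {
  w <- food_web(c("A", "B", "C", "D"),
                edges = rbind(c("A", "B"), c("C", "D")))
  expect_message(res <- foodweb_indicators(w, flat_tl(w)), "unreachable")
  expect_equal(res$avDISTfw, 1)  # two reachable pairs, both at distance 1
})

test_that("asymmetry-graph indicators count sources, sinks, components", {
  ag <- structure(list(
    links = data.frame(source = c("X", "X"), target = c("Y", "Z"),
                       weight = c(1, 2)),
    nodes = c("X", "Y", "Z")), class = "asymmetry_graph")
  cls <- list(classes = ag$links, bu = 2L, td = 0L, lateral = 0L)
  res <- asymgraph_indicators(ag, cls)
  expect_equal(res$Nag, 3L)
  expect_equal(res$Lag, 2L)
  expect_equal(res$COMPag, 1L)
  expect_equal(res$Nsoag, 1L)
  expect_equal(res$Nsiag, 2L)
  expect_equal(res$td_bu_ratio, 0)

  suppressWarnings(empty <- asymmetry_graph(fx$cycle4, t = 0.2))
  cls0 <- list(classes = empty$links, bu = 0L, td = 0L, lateral = 0L)
  res0 <- asymgraph_indicators(empty, cls0)
  expect_equal(res0$Nag + res0$Lag + res0$COMPag + res0$Nsoag + res0$Nsiag,
               0L)
  expect_true(is.na(res0$td_bu_ratio))
})

test_that("combined ratios divide asymmetry-graph counts by web counts", {
  r <- combined_ratios(list(Nfw = 67, Lfw = 708), list(Nag = 26, Lag = 22))
  expect_equal(r$Nag_over_Nfw, 26 / 67)
  expect_equal(r$Lag_over_Lfw, 22 / 708)
  r0 <- combined_ratios(list(Nfw = 10, Lfw = 12), list(Nag = 0, Lag = 0))
  expect_equal(r0$Nag_over_Nfw, 0)
  expect_equal(r0$Lag_over_Lfw, 0)
})

test_that("non-network indicators compute Sh, TB and EE with filtering", {
  w <- food_web(c("A", "B", "C"), edges = rbind(c("A", "B"), c("B", "C")))
  w$attributes <- data.frame(node = c("A", "B", "C"),
                             biomass = c(2, 3, NA),
                             ee = c(0.5, 1.7, 0.3))
  expect_message(res <- nonnetwork_indicators(w), "unrealistic EE")
  expect_equal(res$TB, 5)
  expect_equal(res$Sh, -(0.4 * log(0.4) + 0.6 * log(0.6)))
  expect_equal(res$EE, 0.4)

  # equal biomass maximizes Shannon at ln k; single compartment gives 0
  w$attributes$biomass <- c(1, 1, 1)
  expect_equal(suppressMessages(nonnetwork_indicators(w))$Sh, log(3))
  w$attributes$biomass <- c(5, 0, 0)
  expect_equal(suppressMessages(nonnetwork_indicators(w))$Sh, 0)

  # all EE invalid -> missing
  w$attributes$ee <- c(1.5, 2, -1)
  expect_true(is.na(suppressMessages(nonnetwork_indicators(w))$EE))
  bare <- food_web(c("A", "B"), edges = rbind(c("A", "B")))
  res_b <- nonnetwork_indicators(bare)
  expect_true(all(is.na(unlist(res_b))))
})

test_that("the indicator table has the fixed 21-variable layout", {
  coll <- synthetic_collection(n_webs = 3, seed = 21,
                               species_range = c(20L, 30L))
  tab <- indicator_table(coll)
  expect_equal(nrow(tab), 3L)
  expect_equal(ncol(tab), 22L)
  expect_equal(names(tab)[1], "web_id")
  expect_equal(names(tab),
               c("web_id", "Nfw", "Lfw", "Cfw", "avDISTfw", "Tfw", "avTLfw",
                 "maxTLfw", "carn_ratio", "Nag", "Lag", "COMPag", "BUag",
                 "TDag", "td_bu_ratio", "Nsoag", "Nsiag", "Nag_over_Nfw",
                 "Lag_over_Lfw", "Sh", "TB", "EE"))
  expect_true(all(tab$Nag <= tab$Nfw))
  expect_true(all(tab$BUag + tab$TDag <= tab$Lag))

  # web without attributes yields missing non-network indicators
  stripped <- coll[[1]]
  stripped$attributes <- NULL
  tab2 <- indicator_table(list(stripped))
  expect_true(all(is.na(c(tab2$Sh, tab2$TB, tab2$EE))))
  expect_false(is.na(tab2$Cfw))

  # determinism
  expect_equal(indicator_table(coll), tab)
})

test_that("a failing web yields a missing row and the batch continues", {
  bad <- food_web(c("A", "B"), edges = rbind(c("A", "B")))  # no trophic info
  good <- fixtures()$chainPHC
  expect_message(tab <- indicator_table(list(bad, good)), "failed")
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$Nfw[1]))
  expect_false(is.na(tab$Nfw[2]))
})

test_that("indicators are invariant under node relabeling", {
  w <- niche_model_web(20, 0.15, seed = 2)
  w <- assign_attributes(w, seed = 3)
  set.seed(99)
  perm <- setNames(sprintf("z%02d", sample(20)), w$nodes)
  at2 <- w$attributes
  at2$node <- unname(perm[at2$node])
  w2 <- food_web(unname(perm[w$nodes]),
                 trophic_edges = cbind(perm[w$trophic_edges[, 1]],
                                       perm[w$trophic_edges[, 2]]),
                 attributes = at2, web_id = w$web_id)
  t1 <- indicator_record(w)
  t2 <- indicator_record(w2)
  expect_equal(t1[, -1], t2[, -1], tolerance = 1e-10)
})

test_that("sensitivity mode emits one row per web and threshold", {
  coll <- synthetic_collection(n_webs = 2, seed = 5,
                               species_range = c(15L, 20L))
  tab <- sensitivity_table(coll)
  expect_equal(nrow(tab), 10L)
  expect_equal(sort(unique(tab$threshold)), c(0.005, 0.01, 0.05, 0.1, 0.2))
  # larger thresholds admit at least as many links
  by_web <- split(tab, tab$web_id)
  for (b in by_web) expect_true(all(diff(b$Lag[order(b$threshold)]) >= 0))
})
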