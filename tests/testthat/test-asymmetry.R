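fx <- fixtures()

test_that("asymmetry matrix matches hand-derived values and is symmetric", {
  ti <- ti_matrix(fx$path3, n = 3, normalize = FALSE)
  A <- asymmetry_matrix(ti)
  expect_equal(A["A", "B"], 1 / 3)
  expect_equal(A["A", "C"], 0)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, 3), ignore_attr = TRUE)

  As <- asymmetry_matrix(ti_matrix(fx$star4, n = 3, normalize = FALSE))
  expect_equal(As["c0", "l1"], 4 / 9)

  Ac <- asymmetry_matrix(ti_matrix(fx$cycle4, n = 3, normalize = FALSE))
  expect_true(all(Ac == 0))
})

test_that("link budget floors with a minimum of one", {
  expect_equal(link_budget(8, 0.01), 1L)
  expect_equal(link_budget(67, 0.01), 22L)
  expect_equal(link_budget(2, 0.01), 1L)
  expect_error(link_budget(1, 0.01), "N >= 2")
  expect_error(link_budget(10, 0), "t must be")
})

test_that("asymmetry graph retains top pairs oriented to the weaker node", {
  ag <- asymmetry_graph(fx$path3, t = 0.5)  # budget 1 of 3 pairs
  expect_equal(nrow(ag$links), 1L)
  # asym(A,B) == asym(B,C); tie broken by source then target label: B->A
  expect_equal(ag$links$source, "B")
  expect_equal(ag$links$target, "A")

  ags <- asymmetry_graph(fx$star4, t = 0.01)  # budget 1
  expect_equal(ags$links$source, "c0")
  expect_equal(ags$links$target, "l1")

  # weights come from the normalized TI; unnormalized gives 4/9 on the star
  ags_raw <- build_asymmetry_graph(
    asymmetry_matrix(ti_matrix(fx$star4, normalize = FALSE)),
    ti_matrix(fx$star4, normalize = FALSE), t = 0.01)
  expect_equal(ags_raw$links$weight, 4 / 9)
})

test_that("zero-asymmetry pairs are never admitted", {
  expect_warning(agc <- asymmetry_graph(fx$cycle4, t = 0.2), "zero")
  expect_equal(nrow(agc$links), 0L)
  expect_equal(length(agc$nodes), 0L)
  expect_equal(component_count(agc), 0L)
  expect_true(is_dag(agc))

  expect_warning(agk <- asymmetry_graph(fx$complete4, t = 0.2), "zero")
  expect_equal(nrow(agk$links), 0L)
})

test_that("asymmetry graph is invariant to TI scale", {
  w <- random_web(10, 0.3, 5)
  ti <- ti_matrix(w, normalize = FALSE)
  ag1 <- build_asymmetry_graph(asymmetry_matrix(ti), ti, t = 0.1)
  ti2 <- ti
  ti2[] <- unclass(ti) * 37.5
  ag2 <- build_asymmetry_graph(asymmetry_matrix(ti2), ti2, t = 0.1)
  expect_equal(ag1$links$source, ag2$links$source)
  expect_equal(ag1$links$target, ag2$links$target)
  expect_equal(ag1$nodes, ag2$nodes)
})

test_that("link sets nest monotonically in the threshold", {
  w <- random_web(12, 0.3, 9)
  key <- function(ag) paste(ag$links$source, ag$links$target)
  k_small <- key(asymmetry_graph(w, t = 0.05))
  k_large <- key(asymmetry_graph(w, t = 0.2))
  expect_true(all(k_small %in% k_large))
  expect_lte(length(k_small), length(k_large))
})

test_that("budget bounds the link count; equality away from ties and zeros", {
  for (seed in 1:5) {
    w <- random_web(12, 0.35, seed)
    ag <- asymmetry_graph(w, t = 0.1)
    expect_lte(nrow(ag$links), ag$link_budget)
    A <- asymmetry_matrix(ti_matrix(w))
    n_pos <- sum(A[upper.tri(A)] > 0)
    expect_equal(nrow(ag$links), min(ag$link_budget, n_pos))
  }
})

test_that("DAG detection and component counts behave on explicit link sets", {
  mk <- function(links) {
    structure(list(links = links,
                   nodes = sort(unique(c(links$source, links$target))),
                   threshold_fraction = 0.01, link_budget = 10L),
              class = "asymmetry_graph")
  }
  chain <- mk(data.frame(source = c("X", "Y"), target = c("Y", "Z"),
                         weight = c(1, 1)))
  expect_true(is_dag(chain))
  expect_equal(component_count(chain), 1L)
  cyc <- mk(data.frame(source = c("X", "Y"), target = c("Y", "X"),
                       weight = c(1, 1)))
  expect_false(is_dag(cyc))
  two <- mk(data.frame(source = c("X", "Z"), target = c("Y", "W"),
                       weight = c(1, 1)))
  expect_equal(component_count(two), 2L)
})

test_that("asymmetry graphs export to TSV and GraphML", {
  ag <- asymmetry_graph(fx$star4, t = 0.01)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_asymmetry_graph(ag, f, "tsv")
  back <- utils::read.delim(f)
  expect_equal(back$source, ag$links$source)
  expect_equal(back$weight, ag$links$weight)

  g <- withr::local_tempfile(fileext = ".graphml")
  write_asymmetry_graph(ag, g, "graphml")
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(gg), nrow(ag$links))
  expect_equal(sort(igraph::E(gg)$weight), sort(ag$links$weight))
})
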