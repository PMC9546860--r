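# builds a fake history entry from node sets + perfs on a given graph
hist_entry <- function(graph, node_sets, perfs, gains = NULL) {
  list(node_sets = node_sets,
       edge_sets = lapply(node_sets, function(ns)
         gdforest:::induced_edge_keys(graph, ns)),
       perfs = perfs,
       depths = rep(2L, length(node_sets)),
       gain_tallies = gains %||% lapply(node_sets, function(ns)
         setNames(numeric(0), character(0))))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("edge importance accumulates perf over iterations and slots", {
  g <- path_graph(c("a", "b", "c"))
  h1 <- hist_entry(g, list(c("a", "b")), 0.8)
  tly <- accumulate_edge_importance(list(h1))
  expect_equal(unname(tly["a\tb"]), 0.8)

  # edgeless node set contributes nothing
  g2 <- gdf_graph(cbind("a", "b"), nodes = c("a", "b", "z"))
  h2 <- hist_entry(g2, list(c("a", "z")), 0.9)
  expect_length(accumulate_edge_importance(list(h2)), 0L)

  # two iterations of the same slot sum (oracle: direct summation)
  ha <- hist_entry(g, list(c("a", "b")), 0.8)
  hb <- hist_entry(g, list(c("a", "b")), 1.0)
  expect_equal(unname(accumulate_edge_importance(list(ha, hb))["a\tb"]), 1.8)
})

test_that("normalized edge importance divides by edges and slots", {
  g <- path_graph(c("a", "b", "c"))
  expect_equal(normalized_edge_importance(c("a", "b"),
                                          c("a\tb" = 0.8), 1, g), 0.8)
  expect_equal(normalized_edge_importance(c("a", "b", "c"),
                                          c("a\tb" = 1, "b\tc" = 0), 1, g),
               0.5)
  # persistent perfect module attains exactly 1
  niter <- 7; ntree <- 3
  hist <- replicate(niter, hist_entry(
    g, rep(list(c("a", "b", "c")), ntree), rep(1, ntree)), simplify = FALSE)
  tly <- accumulate_edge_importance(hist)
  expect_equal(normalized_edge_importance(c("a", "b", "c"), tly,
                                          niter * ntree, g), 1)
  expect_warning(
    v <- normalized_edge_importance("a", tly, niter * ntree,
                                    gdf_graph(nodes = c("a", "b"))),
    "no edges")
  expect_equal(v, 0)
})

# a minimal hand-built model for ranking tests
fake_model <- function(graph, pop_sets, pop_perfs, hist) {
  pop <- Map(function(ns, pf) {
    list(tree = NULL, walk = ns, nodes = sort(ns),
         edge_keys = gdforest:::induced_edge_keys(graph, ns),
         in_bag = integer(), oob = integer(), perf = pf, depth = 2L)
  }, pop_sets, pop_perfs)
  structure(list(population = pop, history = hist, graph = graph,
                 modalities = "a",
                 config = gdf_config(ntree = length(pop), niter = length(hist))),
            class = "gdf_model")
}

test_that("rank_modules scores, deduplicates and breaks ties to subsets", {
  g <- path_graph(c("a", "b", "c", "d"))
  # history: the 3-node module persists at perf 1 in both slots/iters;
  # the 4-node superset shows up half the time
  core <- c("a", "b", "c")
  sup <- c("a", "b", "c", "d")
  hist <- list(hist_entry(g, list(core, sup), c(1, 1)),
               hist_entry(g, list(core, core), c(1, 1)))
  m <- fake_model(g, list(core, sup, core), c(1, 1, 1), hist)
  r <- rank_modules(m)
  expect_equal(nrow(r), 2L)
  expect_equal(r$nodes[[1]], core)
  expect_equal(r$perf, c(1, 1))
  # superset's added edges dilute the mean edge importance
  expect_lt(r$score[2], r$score[1])
  expect_equal(r$score, r$mean_edge_importance + r$perf)
  expect_equal(r$rank, 1:2)

  # single unique module -> rank 1
  m2 <- fake_model(g, list(core), 0.9, list(hist_entry(g, list(core), 0.9)))
  expect_equal(nrow(rank_modules(m2)), 1L)
})

test_that("module score matches the printed-scale example", {
  # a module at perf 1 whose mean normalized edge importance is 0.67
  g <- path_graph(c("a", "b", "c"))
  hist <- lapply(1:100, function(i) {
    # module present in 67 of 100 iterations at perf 1 (one slot)
    if (i <= 67) hist_entry(g, list(c("a", "b", "c")), 1)
    else hist_entry(g, list("a"), 0.5)
  })
  m <- fake_model(g, list(c("a", "b", "c")), 1, hist)
  r <- rank_modules(m)
  expect_equal(r$mean_edge_importance[1], 0.67)
  expect_equal(r$score[1], 1.67)
})

test_that("feature importance accumulates and normalizes gains", {
  g <- path_graph(c("g1", "g2"))
  gains1 <- list(c("g1\tmrna" = 0.5))
  h1 <- hist_entry(g, list(c("g1", "g2")), 1, gains = gains1)
  tly <- accumulate_feature_importance(list(h1))
  expect_equal(unname(tly["g1\tmrna"]), 0.5)
  expect_false("g2\tmrna" %in% names(tly))

  # two iterations with the identical tree double the tally
  tly2 <- accumulate_feature_importance(list(h1, h1))
  expect_equal(unname(tly2["g1\tmrna"]), 1.0)

  expect_equal(unname(normalized_feature_importance(c(x = 5), 50)["x"]), 0.1)
  expect_length(normalized_feature_importance(setNames(numeric(), character()),
                                              10), 0L)
  set.seed(1)
  v <- setNames(runif(5), letters[1:5])
  expect_equal(normalized_feature_importance(v, 7), v / 7)
})

test_that("nested modules with equal perf rank by edge dilution", {
  # Star graph: hub h with leaves l1..l3. Core module {h,l1} persists in
  # every slot; supersets add edges with smaller tallies.
  g <- gdf_graph(cbind("h", c("l1", "l2", "l3")))
  core <- c("h", "l1")
  s1 <- c("h", "l1", "l2")
  s2 <- c("h", "l1", "l2", "l3")
  hist <- lapply(1:10, function(i) {
    hist_entry(g, list(core, if (i <= 5) s1 else core,
                       if (i <= 2) s2 else core),
               c(1, 1, 1))
  })
  m <- fake_model(g, list(core, s1, s2), c(1, 1, 1), hist)
  r <- rank_modules(m)
  expect_equal(vapply(r$nodes, length, 0L), c(2L, 3L, 4L))
  expect_true(all(diff(r$score) < 0))
})

test_that("module_detail_report has |nodes| x m rows and sorted edges", {
  ds <- make_dataset(synthetic_spec(n_nodes = 10, n_samples = 200,
                                    modal_layout = "cross", seed = 3))
  model <- fit_gdf(ds$graph, ds$data, gdf_config(ntree = 10, niter = 4,
                                                 seed = 4))
  r <- rank_modules(model)
  rep1 <- module_detail_report(model, 1)
  expect_equal(nrow(rep1$features), length(r$nodes[[1]]) * 2L)
  expect_setequal(unique(rep1$features$modality), c("a", "b"))
  expect_true(all(rep1$features$imp_f >= 0))
  if (nrow(rep1$edges) > 1) {
    expect_true(!is.unsorted(rev(rep1$edges$imp_e_raw)))
  }
  # modality with no splits still present, value 0
  expect_error(module_detail_report(model, nrow(r) + 1), "unknown module")
  rep2 <- module_detail_report(model, r$nodes[[1]])
  expect_equal(rep2$features, rep1$features)
})
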