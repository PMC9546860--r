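# a small planted world reused across tests (cheap: 150 samples, 12 nodes)
small_world <- function(seed = 5, n_nodes = 12, n_samples = 150) {
  make_dataset(synthetic_spec(n_nodes = n_nodes, n_samples = n_samples,
                              seed = seed))
}

test_that("gdf_config validates its fields", {
  cfg <- gdf_config(ntree = 10, niter = 5)
  expect_s3_class(cfg, "gdf_config")
  expect_error(gdf_config(ntree = 0), "ntree")
  expect_error(gdf_config(niter = -1), "niter")
  expect_error(gdf_config(min_depth = 1), "min_depth")
  expect_error(gdf_config(initial_depth = 1, min_depth = 2), "initial_depth")
  expect_error(gdf_config(performance = "accuracy"))
})

test_that("init_forest builds ntree scored records from walks", {
  ds <- small_world()
  set.seed(1)
  m <- init_forest(ds$graph, ds$data, gdf_config(ntree = 15, niter = 0))
  expect_length(m$population, 15L)
  perfs <- vapply(m$population, `[[`, 0, "perf")
  expect_true(all(perfs >= 0 & perfs <= 1))
  # auto mode: the mtry rule in steps, so floor(sqrt(|V|)) + 1 visits
  depth0 <- default_walk_depth(ds$graph) + 1L
  expect_equal(m$initial_depth, depth0)
  expect_true(all(vapply(m$population, `[[`, 0, "depth") == depth0))
  for (r in m$population) {
    expect_lte(length(r$nodes), depth0)
    expect_equal(nrow(r$tree$features),
                 length(r$nodes) * length(ds$data$modalities))
    expect_length(r$walk, depth0)
  }

  # two-node graph, ntree = 1
  d2 <- tiny_data(n = 30, nodes = c("a", "b"))
  g2 <- path_graph(c("a", "b"))
  set.seed(2)
  m2 <- init_forest(g2, d2, gdf_config(ntree = 1, niter = 0))
  expect_length(m2$population, 1L)
  expect_lte(length(m2$population[[1]]$nodes), 2L)

  # determinism: identical fingerprints under a fixed seed
  fp <- function(mm) list(lapply(mm$population, `[[`, "nodes"),
                          vapply(mm$population, `[[`, 0, "perf"))
  set.seed(3); a <- init_forest(ds$graph, ds$data, gdf_config(ntree = 8))
  set.seed(3); b <- init_forest(ds$graph, ds$data, gdf_config(ntree = 8))
  expect_identical(fp(a), fp(b))
})

test_that("resample_population draws proportionally to performance", {
  recs <- list(list(perf = 1.0, id = 1), list(perf = 0.0, id = 2))
  set.seed(4)
  out <- resample_population(recs, 50)
  expect_true(all(vapply(out, `[[`, 0, "id") == 1))

  # equal perfs: empirically uniform (chi-square)
  recs3 <- lapply(1:3, function(i) list(perf = 0.7, id = i))
  set.seed(5)
  ids <- vapply(resample_population(rep(recs3, length.out = 3), 10000)[],
                `[[`, 0, "id")
  p <- stats::chisq.test(table(ids), p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.01)

  expect_length(resample_population(recs[1], 7), 7L)
  expect_warning(resample_population(list(list(perf = 0), list(perf = 0)), 4),
                 "uniformly")
})

test_that("fit_gdf with niter = 0 is init_forest and history stays empty", {
  ds <- small_world()
  m <- fit_gdf(ds$graph, ds$data, gdf_config(ntree = 6, niter = 0, seed = 7))
  set.seed(7)
  m0 <- init_forest(ds$graph, ds$data, gdf_config(ntree = 6, niter = 0,
                                                  seed = 7))
  expect_identical(lapply(m$population, `[[`, "nodes"),
                   lapply(m0$population, `[[`, "nodes"))
  expect_length(m$history, 0L)
  expect_equal(m$total_slots, 0L)
  expect_length(m$edge_tally, 0L)
})

test_that("greedy invariants hold across iterations", {
  ds <- small_world(seed = 11)
  cfg <- gdf_config(ntree = 12, niter = 8, seed = 13)
  m <- fit_gdf(ds$graph, ds$data, cfg)
  expect_length(m$history, 8L)
  d0 <- m$initial_depth
  prev_depths <- NULL
  for (h in m$history) {
    # population size constant
    expect_length(h$perfs, 12L)
    # paired acceptance: stored perf >= the incumbent's refreshed estimate
    expect_true(all(h$perfs >= h$incumbent_perfs - 1e-12))
    # depth bounds
    expect_true(all(h$depths >= cfg$min_depth & h$depths <= d0))
    prev_depths <- h$depths
  }
  expect_length(m$population, 12L)
  # depth monotonicity along surviving lineages is implied by construction
  # (depth is only ever set to max(depth - 1, min_depth)); check final state
  expect_true(all(vapply(m$population, `[[`, 0, "depth") >= cfg$min_depth))

  # determinism end to end
  m2 <- fit_gdf(ds$graph, ds$data, cfg)
  expect_identical(lapply(m$population, `[[`, "nodes"),
                   lapply(m2$population, `[[`, "nodes"))
  expect_identical(m$edge_tally, m2$edge_tally)
})

test_that("selection does not degrade the population", {
  # mean perf at the end >= mean perf at initialization (across seeds)
  deltas <- vapply(1:5, function(s) {
    ds <- small_world(seed = 20 + s)
    m <- fit_gdf(ds$graph, ds$data,
                 gdf_config(ntree = 10, niter = 6, seed = 30 + s))
    mean(m$history[[6]]$perfs) -
      mean(m$history[[1]]$incumbent_perfs)
  }, 0)
  expect_gt(mean(deltas), 0)
})

test_that("forest_predict averages tree probabilities", {
  ds <- small_world(seed = 41)
  m <- fit_gdf(ds$graph, ds$data, gdf_config(ntree = 5, niter = 2, seed = 42))
  pr <- forest_predict(m, ds$data, 1:10)
  per_tree <- vapply(m$population, function(r)
    predict_proba(r$tree, ds$data, 1:10), numeric(10))
  expect_equal(pr, rowMeans(per_tree))

  # population of identical trees equals the single tree
  m1 <- m
  m1$population <- rep(m$population[1], 4)
  expect_equal(forest_predict(m1, ds$data, 1:10),
               predict_proba(m$population[[1]]$tree, ds$data, 1:10))
})

test_that("forest_oob_auc aggregates out-of-bag votes", {
  ds <- small_world(seed = 51)
  m <- fit_gdf(ds$graph, ds$data, gdf_config(ntree = 20, niter = 2, seed = 52))
  a <- suppressWarnings(forest_oob_auc(m, ds$data))
  expect_true(a >= 0 && a <= 1)

  # identical single-leaf (constant) trees give all-tied scores -> 0.5
  d2 <- tiny_data(n = 40, nodes = c("a", "b"), seed = 3)
  g2 <- path_graph(c("a", "b"))
  set.seed(53)
  mc <- init_forest(g2, d2, gdf_config(ntree = 10, niter = 0, min_leaf = 40))
  # min_leaf = n forces single-leaf trees
  expect_true(all(vapply(mc$population, function(r)
    length(r$tree$feature) == 1L, TRUE)))
  # make the constants identical across trees (the tie-only contract)
  for (k in seq_along(mc$population)) mc$population[[k]]$tree$prob <- 0.5
  expect_equal(suppressWarnings(forest_oob_auc(mc, d2)), 0.5)
})

test_that("models survive a JSON round trip", {
  ds <- small_world(seed = 61)
  m <- fit_gdf(ds$graph, ds$data, gdf_config(ntree = 6, niter = 3, seed = 62))
  f <- withr::local_tempfile(fileext = ".json")
  gdf_save_model(m, f)
  m2 <- gdf_load_model(f)
  expect_equal(forest_predict(m2, ds$data, 1:15),
               forest_predict(m, ds$data, 1:15))
  r1 <- rank_modules(m)
  r2 <- rank_modules(m2)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  expect_equal(m2$total_slots, m$total_slots)
  expect_equal(m2$edge_tally, m$edge_tally)
})
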