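#' Configuration of a greedy decision forest run
#'
#' @param ntree population size, held constant across iterations
#'   (default 500).
#' @param niter number of greedy propose/accept/resample iterations
#'   (default 100).
#' @param initial_depth starting random-walk depth (the \code{mtry}
#'   analogue), or \code{"auto"} for \code{floor(sqrt(|V|))} clamped to >= 2.
#' @param min_depth smallest walk depth a lineage may shrink to; >= 2 so
#'   every surviving module can contain an edge (default 2).
#' @param seed integer seed applied by \code{\link{fit_gdf}}; \code{NULL}
#'   uses the current RNG state.
#' @param performance performance metric label; only \code{"auc"}
#'   (out-of-bag ROC-AUC) is implemented.
#' @param min_leaf minimum samples per tree leaf.
#' @return a list of class \code{gdf_config}.
#' @export
gdf_config <- function(ntree = 500L, niter = 100L, initial_depth = "auto",
                       min_depth = 2L, seed = NULL, performance = "auc",
                       min_leaf = 1L) {
  ntree <- as.integer(ntree); niter <- as.integer(niter)
  min_depth <- as.integer(min_depth)
  if (is.na(ntree) || ntree < 1L) stop("ntree must be >= 1")
  if (is.na(niter) || niter < 0L) stop("niter must be >= 0")
  if (is.na(min_depth) || min_depth < 2L) stop("min_depth must be >= 2")
  if (!identical(initial_depth, "auto")) {
    initial_depth <- as.integer(initial_depth)
    if (is.na(initial_depth) || initial_depth < min_depth) {
      stop("initial_depth must be 'auto' or an integer >= min_depth")
    }
  }
  performance <- match.arg(performance, "auc")
  structure(list(ntree = ntree, niter = niter, initial_depth = initial_depth,
                 min_depth = min_depth, seed = seed,
                 performance = performance, min_leaf = as.integer(min_leaf)),
            class = "gdf_config")
}

# internal: build one TreeRecord from a realized walk.
# feature multiset = every modality of every visited node (repeats kept);
# the tree is fitted on a fresh bootstrap and scored on its out-of-bag set.
record_from_walk <- function(walk_seq, depth, graph, data, min_leaf) {
  nodes <- sort(unique(walk_seq), method = "radix")
  m <- length(data$modalities)
  features <- data.frame(
    node = rep(nodes, each = m),
    modality = rep(data$modalities, length(nodes)),
    stringsAsFactors = FALSE)
  features <- features[order(features$node, features$modality,
                             method = "radix"), , drop = FALSE]
  X <- design_matrix(data, features)
  bs <- bootstrap_sample(length(data$samples))
  tree <- fit_tree_raw(X[bs$in_bag, , drop = FALSE], data$labels[bs$in_bag],
                       features, min_leaf)
  if (length(bs$oob)) {
    scores <- predict_tree_cpp(tree$feature, tree$threshold, tree$left,
                               tree$right, tree$prob,
                               X[bs$oob, , drop = FALSE])
    perf <- auc_or_chance(scores, data$labels[bs$oob])
  } else {
    perf <- 0.5
  }
  list(tree = tree, walk = walk_seq, nodes = nodes,
       edge_keys = induced_edge_keys(graph, nodes),
       in_bag = bs$in_bag, oob = bs$oob, perf = perf, depth = depth)
}

#' Initialize a greedy decision forest
#'
#' Creates \code{ntree} tree records: each starts a uniform random walk of
#' \code{initial_depth} visited nodes on the full graph, takes all modalities
#' of the visited nodes as its feature set, fits a tree on a fresh bootstrap
#' and scores it on the out-of-bag samples.
#'
#' @param graph a \code{gdf_graph}, harmonized with \code{data}.
#' @param data a \code{multi_omics} object.
#' @param config a \code{\link{gdf_config}}.
#' @return object of class \code{gdf_model} with an empty history.
#' @export
init_forest <- function(graph, data, config = gdf_config()) {
  depth0 <- if (identical(config$initial_depth, "auto")) {
    # the mtry rule gives the walk length in steps; a walk of s steps
    # visits s + 1 nodes (igraph convention), so the initial visit count
    # is floor(sqrt(|V|)) + 1
    default_walk_depth(graph) + 1L
  } else {
    config$initial_depth
  }
  if (length(graph$nodes) < config$min_depth) {
    stop("graph has fewer nodes than min_depth")
  }
  if (depth0 < config$min_depth) depth0 <- config$min_depth
  extra <- setdiff(data$nodes, graph$nodes)
  if (length(setdiff(graph$nodes, data$nodes))) {
    stop("graph and data are not harmonized; run harmonize() first")
  }
  population <- vector("list", config$ntree)
  for (k in seq_len(config$ntree)) {
    w <- random_walk(graph, start = NULL, depth = depth0)
    population[[k]] <- record_from_walk(w$sequence, depth0, graph, data,
                                        config$min_leaf)
  }
  structure(list(population = population, history = list(), config = config,
                 graph = graph, modalities = data$modalities,
                 initial_depth = depth0),
            class = "gdf_model")
}

#' One greedy iteration: propose, accept, resample
#'
#' For every population slot a shrunken proposal is drawn: a random walk of
#' \code{max(depth - 1, min_depth)} visited nodes, seeded at a uniformly
#' chosen node of the slot's current node set and free to move over the
#' whole graph (so a module can be trimmed, shifted, or completed with a
#' neighbouring node), fitted on a fresh bootstrap. The incumbent tree is
#' re-scored on the proposal's out-of-bag samples, and the proposal replaces
#' the incumbent iff its performance on that common out-of-bag set is at
#' least the incumbent's (a paired comparison; equality is accepted because
#' the aim is a minimal feature set at non-decreasing performance). A
#' retained incumbent keeps its tree, nodes and depth but stores the
#' refreshed performance estimate. After all slots are updated the
#' post-acceptance population is appended to the history and \code{ntree}
#' slots are resampled with replacement with probability proportional to
#' performance.
#'
#' @param model a \code{gdf_model}.
#' @param graph,data the harmonized inputs used to fit \code{model}.
#' @return the updated \code{gdf_model}.
#' @export
greedy_step <- function(model, graph, data) {
  cfg <- model$config
  pop <- model$population
  inc_perfs <- numeric(length(pop))
  for (k in seq_along(pop)) {
    rec <- pop[[k]]
    nd <- max(rec$depth - 1L, cfg$min_depth)
    start <- rec$nodes[sample.int(length(rec$nodes), 1L)]
    w <- random_walk(graph, start = start, depth = nd)
    prop <- record_from_walk(w$sequence, nd, graph, data, cfg$min_leaf)
    inc_perf <- if (length(prop$oob)) {
      auc_or_chance(predict_proba(rec$tree, data, prop$oob),
                    data$labels[prop$oob])
    } else 0.5
    inc_perfs[k] <- inc_perf
    if (prop$perf >= inc_perf) {
      pop[[k]] <- prop
    } else {
      rec$perf <- inc_perf
      pop[[k]] <- rec
    }
  }
  model$population <- pop
  model$history[[length(model$history) + 1L]] <- list(
    node_sets = lapply(pop, `[[`, "nodes"),
    edge_sets = lapply(pop, `[[`, "edge_keys"),
    perfs = vapply(pop, `[[`, 0, "perf"),
    incumbent_perfs = inc_perfs,
    depths = vapply(pop, function(r) as.integer(r$depth), 0L),
    gain_tallies = lapply(pop, function(r) r$tree$gain_tally))
  model$population <- resample_population(pop, cfg$ntree)
  model
}

#' Resample a tree population proportionally to performance
#'
#' Draws \code{ntree} records with replacement, record \code{j} with
#' probability \code{perf_j / sum(perf)}. If every performance is zero the
#' draw is uniform (with a warning).
#'
#' @param records list of tree records (each with a \code{perf} field).
#' @param ntree number of draws; defaults to \code{length(records)}.
#' @return list of \code{ntree} records.
#' @export
resample_population <- function(records, ntree = length(records)) {
  perfs <- vapply(records, `[[`, 0, "perf")
  if (any(perfs < 0)) stop("performances must be non-negative")
  if (all(perfs == 0)) {
    warning("all performances are zero; resampling uniformly")
    perfs <- rep(1, length(perfs))
  }
  idx <- sample.int(length(records), ntree, replace = TRUE, prob = perfs)
  records[idx]
}

#' Fit a greedy decision forest
#'
#' Runs \code{\link{init_forest}} followed by \code{niter} calls of
#' \code{\link{greedy_step}}, then accumulates the edge and feature
#' importance tallies from the recorded history. All randomness flows from
#' \code{config$seed} (if set).
#'
#' @param graph a \code{gdf_graph}.
#' @param data a \code{multi_omics} object sharing the graph's node set (run
#'   \code{\link{harmonize}} first if needed).
#' @param config a \code{\link{gdf_config}}.
#' @return a \code{gdf_model}: final population, per-iteration history,
#'   accumulated \code{edge_tally} / \code{feature_tally} and
#'   \code{total_slots = niter * ntree}.
#' @export
fit_gdf <- function(graph, data, config = gdf_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  model <- init_forest(graph, data, config)
  for (t in seq_len(config$niter)) {
    model <- greedy_step(model, graph, data)
    if (gdf_verbose()) {
      h <- model$history[[t]]
      gdf_log("iter %d: mean perf %.3f, max perf %.3f, %d unique modules",
              t, mean(h$perfs), max(h$perfs),
              length(unique(vapply(h$node_sets, paste, "", collapse = "\t"))))
    }
  }
  model$total_slots <- config$niter * config$ntree
  model$edge_tally <- accumulate_edge_importance(model)
  model$feature_tally <- accumulate_feature_importance(model)
  model
}

#' @export
print.gdf_model <- function(x, ...) {
  perfs <- vapply(x$population, `[[`, 0, "perf")
  cat(sprintf(
    "<gdf_model> ntree=%d, %d greedy iterations done; perf mean %.3f max %.3f; %d unique modules\n",
    length(x$population), length(x$history), mean(perfs), max(perfs),
    length(unique(vapply(x$population, function(r)
      paste(r$nodes, collapse = "\t"), "")))))
  invisible(x)
}

#' Forest probability predictions
#'
#' Mean of the per-tree class-1 probabilities over the final population.
#'
#' @param model a \code{gdf_model}.
#' @param data a \code{multi_omics} object resolving all model features.
#' @param sample_indices integer indices or \code{NULL} for all samples.
#' @return numeric vector of class-1 probabilities.
#' @export
forest_predict <- function(model, data, sample_indices = NULL) {
  preds <- lapply(model$population, function(r)
    predict_proba(r$tree, data, sample_indices))
  Reduce(`+`, preds) / length(preds)
}

#' Out-of-bag ROC-AUC of the forest
#'
#' Each sample is scored by the mean class-1 probability over the final
#' population trees whose out-of-bag set contains it; the AUC of these
#' aggregated scores against the labels is returned. Samples that are in-bag
#' for every tree are skipped with a warning.
#'
#' @param model a \code{gdf_model} fitted on \code{data}.
#' @param data the training \code{multi_omics} object.
#' @return out-of-bag AUC.
#' @export
forest_oob_auc <- function(model, data) {
  n <- length(data$samples)
  sums <- numeric(n)
  cnts <- integer(n)
  for (r in model$population) {
    if (!length(r$oob)) next
    sums[r$oob] <- sums[r$oob] + predict_proba(r$tree, data, r$oob)
    cnts[r$oob] <- cnts[r$oob] + 1L
  }
  covered <- cnts > 0L
  if (!any(covered)) stop("no sample is out-of-bag for any tree")
  if (!all(covered)) {
    warning(sum(!covered), " sample(s) in-bag for every tree; skipped")
  }
  roc_auc(sums[covered] / cnts[covered], data$labels[covered])
}
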