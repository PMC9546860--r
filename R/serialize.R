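# JSON model serialization. Trees are stored as their flat arrays so a saved
# model remains human-inspectable (every split rule is readable) and fully
# usable for prediction, ranking and explanation after reload. The full
# per-iteration history is not persisted; the accumulated edge/feature
# tallies and total_slots, which are what ranking and reporting consume, are.

#' Save a fitted model as JSON
#'
#' @param model a fitted \code{gdf_model}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
gdf_save_model <- function(model, path) {
  pop <- lapply(model$population, function(r) {
    t <- r$tree
    list(nodes = r$nodes, perf = r$perf, depth = r$depth, walk = r$walk,
         tree = list(feature = t$feature, threshold = t$threshold,
                     left = t$left, right = t$right, prob = t$prob,
                     n = t$n, node_gain = t$node_gain,
                     feature_node = t$features$node,
                     feature_modality = t$features$modality,
                     gain_tally = as.list(t$gain_tally),
                     n_train = t$n_train))
  })
  obj <- list(
    format = "gdforest-model", version = 1L,
    config = unclass(model$config),
    modalities = model$modalities,
    graph = list(nodes = model$graph$nodes,
                 edges_from = model$graph$edges[, 1L],
                 edges_to = model$graph$edges[, 2L]),
    total_slots = model$total_slots %||%
      (length(model$history) * length(model$population)),
    edge_tally = as.list(model$edge_tally %||%
                           accumulate_edge_importance(model)),
    feature_tally = as.list(model$feature_tally %||%
                              accumulate_feature_importance(model)),
    population = pop)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a model saved by \code{\link{gdf_save_model}}
#'
#' @param path JSON file path.
#' @return a \code{gdf_model} (without the per-iteration history, which is
#'   not persisted; the accumulated tallies are).
#' @export
gdf_load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "gdforest-model")) {
    stop("not a gdforest model file: ", path)
  }
  chr <- function(x) vapply(x, as.character, "")
  num <- function(x) {  # JSON null (serialized NA, e.g. leaf thresholds) -> NA
    vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  }
  int <- function(x) vapply(x, function(v) as.integer(v), 0L)
  graph <- gdf_graph(
    if (length(obj$graph$edges_from)) {
      cbind(chr(obj$graph$edges_from), chr(obj$graph$edges_to))
    } else NULL,
    nodes = chr(obj$graph$nodes))
  named_num <- function(x) {
    if (!length(x)) return(setNames(numeric(), character()))
    setNames(num(x), names(x))
  }
  pop <- lapply(obj$population, function(r) {
    t <- r$tree
    features <- data.frame(node = chr(t$feature_node),
                           modality = chr(t$feature_modality),
                           stringsAsFactors = FALSE)
    tree <- structure(
      list(feature = int(t$feature), threshold = num(t$threshold),
           left = int(t$left), right = int(t$right), prob = num(t$prob),
           n = int(t$n), node_gain = num(t$node_gain), features = features,
           gain_tally = named_num(t$gain_tally),
           n_train = as.integer(t$n_train)),
      class = "gdf_tree")
    nodes <- chr(r$nodes)
    list(tree = tree, walk = chr(r$walk), nodes = nodes,
         edge_keys = induced_edge_keys(graph, nodes),
         in_bag = integer(), oob = integer(),
         perf = as.numeric(r$perf), depth = as.integer(r$depth))
  })
  cfg <- obj$config
  config <- gdf_config(
    ntree = cfg$ntree, niter = cfg$niter,
    initial_depth = if (identical(cfg$initial_depth, "auto")) "auto"
                    else as.integer(cfg$initial_depth),
    min_depth = cfg$min_depth, seed = cfg$seed,
    performance = cfg$performance, min_leaf = cfg$min_leaf)
  structure(list(population = pop, history = list(), config = config,
                 graph = graph, modalities = chr(obj$modalities),
                 total_slots = as.numeric(obj$total_slots),
                 edge_tally = named_num(obj$edge_tally),
                 feature_tally = named_num(obj$feature_tally)),
            class = "gdf_model")
}
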