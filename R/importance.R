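#' Accumulate edge importance over the greedy history
#'
#' For every recorded iteration and every population slot, the slot's
#' out-of-bag performance is added to every graph edge with both endpoints
#' in the slot's node set. Edges therefore score both by the performance of
#' the modules containing them and by how often they persist in the
#' population ("less important edges are purified during the selective
#' greedy process").
#'
#' @param history a \code{gdf_model} or its \code{history} list.
#' @return named numeric vector: cumulative importance per edge key
#'   (tab-separated sorted endpoint pair).
#' @export
accumulate_edge_importance <- function(history) {
  if (inherits(history, "gdf_model")) history <- history$history
  keys <- character(); w <- numeric()
  for (h in history) {
    ln <- lengths(h$edge_sets)
    keys <- c(keys, unlist(h$edge_sets, use.names = FALSE))
    w <- c(w, rep(h$perfs, ln))
  }
  if (!length(keys)) return(setNames(numeric(), character()))
  tly <- vapply(split(w, keys), sum, 0)
  tly[order(names(tly), method = "radix")]
}

#' Normalized edge importance of a module
#'
#' Cumulative importance of the module's induced edges divided by the number
#' of those edges and by the number of slots (\code{niter * ntree}), so a
#' module whose edges persist in every slot of every iteration at perfect
#' performance scores exactly 1. (The per-slot normalization keeps the score
#' on the same scale as a single performance value; the raw cumulative tally
#' remains available from \code{\link{accumulate_edge_importance}}.)
#'
#' @param module_nodes character vector of module node ids.
#' @param edge_tally named vector from
#'   \code{\link{accumulate_edge_importance}}.
#' @param total_slots \code{niter * ntree}.
#' @param graph the \code{gdf_graph} defining induced edges.
#' @return mean normalized edge importance; 0 (with a warning) for an
#'   edgeless module.
#' @export
normalized_edge_importance <- function(module_nodes, edge_tally, total_slots,
                                       graph) {
  keys <- induced_edge_keys(graph, module_nodes)
  if (!length(keys)) {
    warning("module induces no edges; edge importance set to 0")
    return(0)
  }
  if (total_slots <= 0) return(0)
  vals <- edge_tally[keys]
  vals[is.na(vals)] <- 0
  sum(vals) / (length(keys) * total_slots)
}

#' Rank the detected modules
#'
#' Deduplicates the final population by node set; each unique module's
#' performance is the mean out-of-bag AUC over its representative trees (a
#' max would inflate frequent modules by an order-statistic bias, since
#' every stored perf is a noisy AUC draw), its score is \code{mean
#' normalized edge importance + performance}, and modules are ranked by
#' score (ties: fewer nodes first, then lexicographic node set).
#'
#' @param model a fitted \code{gdf_model}.
#' @return data frame of class \code{gdf_module_ranking} with columns
#'   \code{rank}, \code{module} (comma-separated node ids), \code{n_nodes},
#'   \code{n_edges}, \code{mean_edge_importance}, \code{perf}, \code{score},
#'   and a list column \code{nodes}.
#' @export
rank_modules <- function(model) {
  pop <- model$population
  keys <- vapply(pop, function(r) paste(r$nodes, collapse = "\t"), "")
  perfs <- vapply(pop, `[[`, 0, "perf")
  uk <- unique(keys)
  edge_tally <- model$edge_tally %||% accumulate_edge_importance(model)
  total_slots <- model$total_slots %||%
    (length(model$history) * length(model$population))
  nodes_list <- lapply(strsplit(uk, "\t", fixed = TRUE), identity)
  perf_u <- vapply(uk, function(k) mean(perfs[keys == k]), 0, USE.NAMES = FALSE)
  imp_e <- numeric(length(uk))
  n_edge <- integer(length(uk))
  for (i in seq_along(uk)) {
    ek <- induced_edge_keys(model$graph, nodes_list[[i]])
    n_edge[i] <- length(ek)
    if (length(ek) && total_slots > 0) {
      v <- edge_tally[ek]
      v[is.na(v)] <- 0
      imp_e[i] <- sum(v) / (length(ek) * total_slots)
    }
  }
  score <- imp_e + perf_u
  o <- order(-score, lengths(nodes_list), uk, method = "radix")
  out <- data.frame(
    rank = seq_along(uk),
    module = vapply(nodes_list[o], paste, "", collapse = ","),
    n_nodes = lengths(nodes_list)[o],
    n_edges = n_edge[o],
    mean_edge_importance = imp_e[o],
    perf = perf_u[o],
    score = score[o],
    stringsAsFactors = FALSE)
  out$nodes <- I(nodes_list[o])
  class(out) <- c("gdf_module_ranking", "data.frame")
  out
}

#' @export
print.gdf_module_ranking <- function(x, ...) {
  cat("Detected modules (score = mean edge importance + OOB performance)\n")
  df <- as.data.frame(x)[, c("rank", "module", "mean_edge_importance",
                             "perf", "score")]
  df$mean_edge_importance <- round(df$mean_edge_importance, 3)
  df$score <- round(df$score, 3)
  print(head(df, 20L), row.names = FALSE)
  if (nrow(df) > 20L) cat("... and", nrow(df) - 20L, "more\n")
  invisible(x)
}

#' Accumulate Gini-gain feature importance over the greedy history
#'
#' Sums each tree's realized (weighted) Gini gains per feature across all
#' slots and iterations.
#'
#' @param history a \code{gdf_model} or its \code{history} list.
#' @return named numeric vector keyed by tab-separated (node, modality).
#' @export
accumulate_feature_importance <- function(history) {
  if (inherits(history, "gdf_model")) history <- history$history
  keys <- character(); w <- numeric()
  for (h in history) {
    for (g in h$gain_tallies) {
      nz <- g != 0
      if (any(nz)) {
        keys <- c(keys, names(g)[nz])
        w <- c(w, g[nz])
      }
    }
  }
  if (!length(keys)) return(setNames(numeric(), character()))
  tly <- vapply(split(w, keys), sum, 0)
  tly[order(names(tly), method = "radix")]
}

#' Normalize a feature importance tally by the number of slots
#'
#' @param feature_tally named vector from
#'   \code{\link{accumulate_feature_importance}}.
#' @param total_slots \code{niter * ntree} (> 0).
#' @return the tally divided elementwise by \code{total_slots}.
#' @export
normalized_feature_importance <- function(feature_tally, total_slots) {
  if (total_slots <= 0) stop("total_slots must be positive")
  feature_tally / total_slots
}

#' Per-node, per-modality importance detail of one module
#'
#' Tabulates the normalized Gini-gain feature importance for every (node,
#' modality) pair of the module (pairs never used for splitting get 0) and
#' the module's induced edges with raw and slot-normalized edge importance,
#' highest-scoring edge first.
#'
#' @param model a fitted \code{gdf_model}.
#' @param module a rank (row number of \code{\link{rank_modules}}) or a
#'   character vector of node ids equal to one ranked module.
#' @return list with data frames \code{features} (node, modality, imp_f) and
#'   \code{edges} (from, to, imp_e, imp_e_raw).
#' @export
module_detail_report <- function(model, module) {
  ranking <- rank_modules(model)
  if (is.numeric(module) && length(module) == 1L) {
    if (module < 1 || module > nrow(ranking)) stop("unknown module rank")
    nodes <- ranking$nodes[[module]]
  } else {
    nodes <- sort(as.character(module), method = "radix")
    hit <- vapply(ranking$nodes, function(x) identical(x, nodes), TRUE)
    if (!any(hit)) stop("module not found among ranked modules")
  }
  total_slots <- model$total_slots %||%
    (length(model$history) * length(model$population))
  ftally <- model$feature_tally %||% accumulate_feature_importance(model)
  feats <- expand.grid(modality = model$modalities, node = nodes,
                       stringsAsFactors = FALSE)[, c("node", "modality")]
  fk <- feature_key(feats$node, feats$modality)
  v <- ftally[fk]
  v[is.na(v)] <- 0
  feats$imp_f <- if (total_slots > 0) unname(v) / total_slots else unname(v)
  etally <- model$edge_tally %||% accumulate_edge_importance(model)
  ek <- induced_edge_keys(model$graph, nodes)
  ev <- etally[ek]
  ev[is.na(ev)] <- 0
  parts <- strsplit(ek, "\t", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    imp_e = if (total_slots > 0) unname(ev) / total_slots else unname(ev),
    imp_e_raw = unname(ev),
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$imp_e_raw, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(features = feats, edges = edges)
}
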