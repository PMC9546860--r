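#' Specification of a synthetic planted-module benchmark
#'
#' Describes one benchmark world: a scale-free (preferential-attachment)
#' graph, Bernoulli(0.5) binary node features for \code{n_samples} samples,
#' and a planted connected module of \code{module_size} nodes whose features
#' determine the class label through a Boolean function of two AND pairs
#' (\code{(x1 & x2) OP (x3 & x4)} with \code{OP} one of XOR / OR / AND). In
#' the cross-modal layout every node carries both modalities, but the label
#' reads modality a of the 1st and 3rd planted nodes and modality b of the
#' 2nd and 4th.
#'
#' @param n_nodes graph size (default 30).
#' @param power preferential-attachment exponent (default 1.2).
#' @param n_samples number of samples (default 1000).
#' @param module_size planted module size (default 4; the Boolean logics are
#'   defined for size 4).
#' @param logic one of \code{"xor"}, \code{"or"}, \code{"and"}.
#' @param modal_layout \code{"single"} (one modality) or \code{"cross"}
#'   (two modalities, label reads alternating modalities).
#' @param seed integer seed, applied by \code{\link{make_dataset}}.
#' @return list of class \code{gdf_synth_spec}.
#' @export
synthetic_spec <- function(n_nodes = 30L, power = 1.2, n_samples = 1000L,
                           module_size = 4L, logic = c("xor", "or", "and"),
                           modal_layout = c("single", "cross"), seed = NULL) {
  logic <- match.arg(logic)
  modal_layout <- match.arg(modal_layout)
  n_nodes <- as.integer(n_nodes)
  module_size <- as.integer(module_size)
  if (module_size < 2L) stop("module_size must be >= 2")
  if (n_nodes <= module_size) stop("n_nodes must exceed module_size")
  structure(list(n_nodes = n_nodes, power = power,
                 n_samples = as.integer(n_samples),
                 module_size = module_size, logic = logic,
                 modal_layout = modal_layout, seed = seed),
            class = "gdf_synth_spec")
}

#' Scale-free graph by preferential attachment
#'
#' Sequential attachment with one edge per arriving node (so the graph is a
#' connected tree with \code{n_nodes - 1} edges): node \code{t} attaches to
#' an existing node drawn with probability proportional to
#' \code{degree^power + zero_appeal}. The additive \code{zero_appeal}
#' (default 1) follows the convention of the igraph generator this emulates;
#' it tempers hub condensation, which matters for superlinear powers.
#' Node ids are zero-padded (\code{v01 ...}) so lexicographic and
#' construction order agree. Uses the current RNG stream.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param power attachment exponent; 0 gives uniform attachment.
#' @param zero_appeal additive baseline attractiveness per node.
#' @return a \code{gdf_graph}.
#' @export
generate_barabasi <- function(n_nodes, power = 1.2, zero_appeal = 1) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) stop("need at least 2 nodes")
  ids <- sprintf("v%0*d", nchar(as.character(n_nodes)), seq_len(n_nodes))
  from <- to <- character(n_nodes - 1L)
  deg <- integer(n_nodes)
  deg[1:2] <- 1L
  from[1L] <- ids[1L]; to[1L] <- ids[2L]
  if (n_nodes > 2L) for (t in 3:n_nodes) {
    w <- deg[seq_len(t - 1L)]^power + zero_appeal
    tgt <- sample.int(t - 1L, 1L, prob = w)
    from[t - 1L] <- ids[tgt]; to[t - 1L] <- ids[t]
    deg[tgt] <- deg[tgt] + 1L
    deg[t] <- 1L
  }
  gdf_graph(cbind(from, to), nodes = ids)
}

#' Plant a connected module by random-walk accretion
#'
#' Starts a uniform random walk and collects distinct visited nodes until
#' \code{module_size} are found; the returned nodes induce a connected
#' subgraph by construction. The order of the returned vector is discovery
#' order (it determines which node plays which role in the label logic).
#'
#' @param graph a connected \code{gdf_graph}.
#' @param module_size number of nodes to collect.
#' @return character vector of node ids, in discovery order.
#' @export
plant_module <- function(graph, module_size) {
  n <- length(graph$nodes)
  module_size <- as.integer(module_size)
  if (module_size > n) stop("module_size exceeds the number of nodes")
  cur <- sample.int(n, 1L)
  sel <- cur
  steps <- 0L
  max_steps <- 10000L * module_size
  while (length(sel) < module_size) {
    nb <- graph$adj[[cur]]
    if (!length(nb)) stop("graph must be connected to plant a module")
    cur <- nb[sample.int(length(nb), 1L)]
    if (!(cur %in% sel)) sel <- c(sel, cur)
    steps <- steps + 1L
    if (steps > max_steps) stop("random walk failed to collect a module")
  }
  graph$nodes[sel]
}

#' Boolean label from four planted feature columns
#'
#' \code{y = (x1 & x2) OP (x3 & x4)} per sample, with \code{OP} XOR, OR or
#' AND. A pure function of its inputs.
#'
#' @param planted_features numeric matrix with 4 columns of binary (0/1)
#'   values, one row per sample, columns already in role order (for the
#'   cross-modal layout the caller selects the modality of each column).
#' @param logic \code{"xor"}, \code{"or"} or \code{"and"}.
#' @return integer vector of 0/1 labels.
#' @export
generate_labels <- function(planted_features, logic = c("xor", "or", "and")) {
  logic <- match.arg(logic)
  x <- as.matrix(planted_features)
  if (ncol(x) != 4L) stop("the defined logics need exactly 4 planted columns")
  if (!all(x %in% c(0, 1))) stop("planted features must be binary 0/1")
  a <- x[, 1L] == 1 & x[, 2L] == 1
  b <- x[, 3L] == 1 & x[, 4L] == 1
  y <- switch(logic, xor = xor(a, b), or = a | b, and = a & b)
  as.integer(y)
}

#' Generate a planted-module benchmark dataset
#'
#' Builds the world described by a \code{\link{synthetic_spec}}: the graph
#' (or reuses \code{graph} if supplied, e.g. to vary only features and the
#' planted module on a fixed topology), a planted connected module,
#' independent Bernoulli(0.5) features for every node and modality, and the
#' Boolean labels. Fully determined by \code{spec$seed}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param graph optional pre-built \code{gdf_graph} to reuse.
#' @param planted optional pre-selected planted nodes (discovery order);
#'   requires \code{graph}. Use to hold the whole instance fixed while
#'   re-drawing only features and labels.
#' @return list of class \code{gdf_planted}: \code{graph}, \code{data}
#'   (a \code{multi_omics}), \code{planted_nodes} (discovery order),
#'   \code{logic}, \code{spec}.
#' @export
make_dataset <- function(spec, graph = NULL, planted = NULL) {
  if (!inherits(spec, "gdf_synth_spec")) stop("`spec` must be a synthetic_spec")
  if (!is.null(planted) && is.null(graph)) {
    stop("`planted` requires `graph`")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(graph)) graph <- generate_barabasi(spec$n_nodes, spec$power)
  if (is.null(planted)) planted <- plant_module(graph, spec$module_size)
  if (length(planted) != spec$module_size ||
      !all(planted %in% graph$nodes)) {
    stop("`planted` must name module_size nodes of `graph`")
  }
  n <- spec$n_samples
  nn <- length(graph$nodes)
  samples <- sprintf("s%0*d", nchar(as.character(n)), seq_len(n))
  mods <- if (spec$modal_layout == "single") "a" else c("a", "b")
  mats <- lapply(mods, function(mod) {
    matrix(as.double(rbinom(n * nn, 1L, 0.5)), n, nn,
           dimnames = list(samples, graph$nodes))
  })
  names(mats) <- mods
  if (spec$modal_layout == "single") {
    x <- mats$a[, planted, drop = FALSE]
  } else {
    x <- cbind(mats$a[, planted[1L]], mats$b[, planted[2L]],
               mats$a[, planted[3L]], mats$b[, planted[4L]])
  }
  y <- generate_labels(x, spec$logic)
  data <- multi_omics_data(mats, setNames(y, samples))
  structure(list(graph = graph, data = data, planted_nodes = planted,
                 logic = spec$logic, spec = spec),
            class = "gdf_planted")
}

#' @export
print.gdf_planted <- function(x, ...) {
  cat(sprintf(
    "<gdf_planted> %d-node graph (power %.2g), %d samples, logic %s (%s-modal)\n  planted: %s\n",
    length(x$graph$nodes), x$spec$power, length(x$data$samples), x$logic,
    x$spec$modal_layout, paste(x$planted_nodes, collapse = ", ")))
  invisible(x)
}

#' Coverage / convergence experiment on planted benchmarks
#'
#' For every value of \code{niter_grid} and every replicate, generates a
#' benchmark dataset, fits a greedy decision forest and records whether the
#' top-ranked module's node set exactly equals the planted set (coverage),
#' the number of unique modules in the final population, and the forest
#' out-of-bag AUC. With \code{vary_topology = FALSE} the graph topology is
#' generated once from the spec seed and only the planted module and the
#' feature values are re-drawn per replicate; with \code{TRUE} everything is
#' regenerated.
#'
#' @param spec a \code{\link{synthetic_spec}} (its seed drives all
#'   replicate seeds).
#' @param niter_grid integer vector of greedy iteration counts.
#' @param replicates number of independent replicates per grid value.
#' @param vary_topology regenerate the graph per replicate?
#' @param config a \code{\link{gdf_config}}; its \code{niter} and
#'   \code{seed} fields are overridden per run.
#' @return data frame of class \code{gdf_benchmark} with one row per
#'   (niter, replicate): \code{niter}, \code{replicate}, \code{recovered},
#'   \code{n_unique_modules}, \code{forest_oob_auc}; coverage per grid value
#'   is attached as attribute \code{"coverage"}.
#' @export
run_convergence_experiment <- function(spec, niter_grid, replicates = 10L,
                                       vary_topology = FALSE,
                                       config = gdf_config(ntree = 100L)) {
  base_seed <- spec$seed %||% config$seed %||% 1L
  set.seed(base_seed)
  rep_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(niter_grid) * replicates),
    nrow = replicates)
  fixed_graph <- NULL
  if (!vary_topology) {
    set.seed(base_seed)
    fixed_graph <- generate_barabasi(spec$n_nodes, spec$power)
  }
  rows <- list()
  for (gi in seq_along(niter_grid)) {
    ni <- niter_grid[gi]
    for (r in seq_len(replicates)) {
      set.seed(rep_seeds[r, gi])
      spec_r <- spec
      spec_r$seed <- NULL  # stay inside this replicate's stream
      ds <- make_dataset(spec_r, graph = fixed_graph)
      cfg <- config
      cfg$niter <- as.integer(ni)
      cfg$seed <- NULL
      model <- fit_gdf(ds$graph, ds$data, cfg)
      ranking <- rank_modules(model)
      rows[[length(rows) + 1L]] <- data.frame(
        niter = ni, replicate = r,
        recovered = setequal(ranking$nodes[[1L]], ds$planted_nodes),
        n_unique_modules = nrow(ranking),
        # small ntree leaves some samples in-bag everywhere; expected here
        forest_oob_auc = suppressWarnings(forest_oob_auc(model, ds$data)))
    }
  }
  out <- do.call(rbind, rows)
  cov <- vapply(split(out$recovered, out$niter), mean, 0)
  attr(out, "coverage") <- cov
  class(out) <- c("gdf_benchmark", "data.frame")
  out
}
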