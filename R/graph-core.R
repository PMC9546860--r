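#' Undirected graph over named nodes
#'
#' Lightweight undirected graph used throughout the package. Nodes are
#' case-sensitive character identifiers, stored sorted so that every seeded
#' operation is reproducible. Edges are deduplicated unordered pairs;
#' self-loops are dropped; directed input is symmetrized. An optional
#' confidence in \code{[0, 1]} can be attached per edge (kept as metadata;
#' walks are unweighted).
#'
#' @param edges two-column character matrix or data frame of endpoints, or
#'   \code{NULL} for an edgeless graph.
#' @param nodes optional character vector of node ids; ids appearing in
#'   \code{edges} are added automatically. Use this to keep isolated nodes.
#' @param confidence optional numeric vector, one value per row of
#'   \code{edges}. Duplicated edges keep the maximum confidence.
#' @return an object of class \code{gdf_graph} with fields \code{nodes}
#'   (sorted character), \code{edges} (two-column character matrix, each row
#'   a sorted pair, rows in lexicographic order), \code{confidence} (named
#'   numeric or \code{NULL}) and an adjacency index.
#' @export
gdf_graph <- function(edges = NULL, nodes = NULL, confidence = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have exactly two columns")
    storage.mode(edges) <- "character"
    if (!is.null(confidence) && length(confidence) != nrow(edges)) {
      stop("`confidence` must have one value per edge row")
    }
    keep <- edges[, 1L] != edges[, 2L]  # no self-loops
    edges <- edges[keep, , drop = FALSE]
    confidence <- confidence[keep]
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    key <- paste(a, b, sep = "\t")
    if (!is.null(confidence) && length(key)) {
      confidence <- vapply(split(confidence, key), max, 0)  # named, by key
    } else {
      confidence <- NULL
    }
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
    o <- order(a, b, method = "radix")
    edges <- cbind(a[o], b[o])
    if (!is.null(confidence)) confidence <- confidence[paste(edges[, 1L], edges[, 2L], sep = "\t")]
  } else {
    edges <- matrix(character(), ncol = 2L)
    confidence <- NULL
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))), method = "radix")
  if (!length(nodes)) stop("graph has no nodes")
  i1 <- match(edges[, 1L], nodes)
  i2 <- match(edges[, 2L], nodes)
  adj <- split(c(i2, i1), factor(c(i1, i2), levels = seq_along(nodes)))
  adj <- lapply(adj, function(v) sort(unname(v)))
  names(adj) <- NULL
  structure(
    list(nodes = nodes, edges = edges, confidence = confidence, adj = adj),
    class = "gdf_graph"
  )
}

#' @export
print.gdf_graph <- function(x, ...) {
  cat(sprintf("<gdf_graph> %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$confidence)) "" else " (with confidence)"))
  invisible(x)
}

#' Number of nodes / edges
#' @param graph a \code{gdf_graph}
#' @return integer count
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Read an undirected graph from a delimited edge list
#'
#' Accepts whitespace- or tab-delimited files with two node-id columns and an
#' optional third numeric confidence column (STRING-style exports work as-is).
#' A header row is auto-detected by a non-numeric third field and skipped.
#' Edges are deduplicated and symmetrized; self-loops are dropped.
#'
#' @param path file path.
#' @param min_confidence drop rows whose confidence is below this value
#'   before building the graph; requires a confidence column. \code{NULL}
#'   keeps everything.
#' @return a \code{\link{gdf_graph}}.
#' @export
read_edge_list <- function(path, min_confidence = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (!length(toks)) stop("edge list is empty: ", path)
  # header: first row whose third field exists and is not numeric
  first <- toks[[1L]]
  if (length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3L])))) {
    toks <- toks[-1L]
    lineno <- lineno[-1L]
    if (!length(toks)) stop("edge list has a header but no data rows: ", path)
  }
  nf <- lengths(toks)
  if (any(nf < 2L)) {
    stop(sprintf("malformed edge list row at line %d of %s (need >= 2 fields)",
                 lineno[which(nf < 2L)[1L]], path))
  }
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  conf <- NULL
  if (all(nf >= 3L)) {
    conf <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
    if (anyNA(conf)) {
      stop(sprintf("non-numeric confidence at line %d of %s",
                   lineno[which(is.na(conf))[1L]], path))
    }
  }
  if (!is.null(min_confidence)) {
    if (is.null(conf)) {
      stop("min_confidence given but the file has no confidence column")
    }
    sel <- conf >= min_confidence
    from <- from[sel]; to <- to[sel]; conf <- conf[sel]
    if (!length(from)) {
      stop(sprintf("no edges left after filtering at min_confidence = %g",
                   min_confidence))
    }
  }
  self <- from == to
  if (all(self)) stop("graph is empty (only self-loops in ", path, ")")
  gdf_graph(cbind(from, to), confidence = conf)
}

#' Default random-walk depth
#'
#' The walk depth (the \code{mtry} analogue: how many node visits feed one
#' tree) defaults to \code{floor(sqrt(|V|))}, the usual rule of thumb for the
#' number of candidate features per tree, clamped to at least 2 for graphs
#' with two or more nodes so a module can contain an edge.
#'
#' @param graph a \code{gdf_graph}
#' @return a positive integer
#' @export
default_walk_depth <- function(graph) {
  n <- length(graph$nodes)
  d <- as.integer(floor(sqrt(n)))
  if (n >= 2L) max(d, 2L) else 1L
}

#' Random walk on a graph
#'
#' Performs a uniform random walk of \code{depth} visited nodes (repeats
#' allowed). A node with no neighbours repeats itself, so walks started on
#' isolated nodes are "stuck". Randomness comes from the current R RNG
#' stream; seed upstream for reproducibility.
#'
#' @param graph a \code{gdf_graph}
#' @param start start node id, or \code{NULL} to draw one uniformly.
#' @param depth number of visited nodes including the start (>= 1).
#' @return object of class \code{gdf_walk}: list with \code{sequence}
#'   (character vector of length \code{depth}) and \code{depth}.
#' @export
random_walk <- function(graph, start = NULL, depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("`depth` must be a positive integer")
  nodes <- graph$nodes
  if (is.null(start)) {
    cur <- sample.int(length(nodes), 1L)
  } else {
    cur <- match(start, nodes)
    if (is.na(cur)) stop("start node not in graph: ", start)
  }
  seq_idx <- integer(depth)
  seq_idx[1L] <- cur
  if (depth >= 2L) {
    adj <- graph$adj
    for (i in 2:depth) {
      nb <- adj[[cur]]
      if (length(nb)) cur <- nb[sample.int(length(nb), 1L)]
      seq_idx[i] <- cur
    }
  }
  structure(list(sequence = nodes[seq_idx], depth = depth),
            class = "gdf_walk")
}

#' @export
print.gdf_walk <- function(x, ...) {
  cat(sprintf("<gdf_walk depth=%d> %s\n", x$depth,
              paste(x$sequence, collapse = " -> ")))
  invisible(x)
}

#' Induced subgraph
#'
#' Returns the subgraph containing exactly the given nodes and every edge of
#' \code{graph} with both endpoints in the set.
#'
#' @param graph a \code{gdf_graph}
#' @param nodes character vector of node ids, all present in \code{graph}.
#' @return a \code{gdf_graph}
#' @export
induced_subgraph <- function(graph, nodes) {
  nodes <- unique(as.character(nodes))
  missing <- setdiff(nodes, graph$nodes)
  if (length(missing)) {
    stop("unknown node id(s): ", paste(missing, collapse = ", "))
  }
  e <- graph$edges
  sel <- e[, 1L] %in% nodes & e[, 2L] %in% nodes
  conf <- if (is.null(graph$confidence)) NULL else unname(graph$confidence[sel])
  gdf_graph(if (any(sel)) e[sel, , drop = FALSE] else NULL,
            nodes = nodes,
            confidence = conf)
}

# internal: keys of edges induced by a node set (no validation, hot path)
induced_edge_keys <- function(graph, nodes) {
  e <- graph$edges
  sel <- e[, 1L] %in% nodes & e[, 2L] %in% nodes
  if (!any(sel)) return(character())
  paste(e[sel, 1L], e[sel, 2L], sep = "\t")
}

#' Write a scored module as GraphML
#'
#' Emits a GraphML file with an \code{imp_e} edge attribute so the module can
#' be rendered with edge thickness proportional to edge importance.
#'
#' @param module_nodes character vector of node ids.
#' @param edge_scores data frame with columns \code{from}, \code{to},
#'   \code{score} (or \code{NULL} / zero rows for a node-only file).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_module_graph <- function(module_nodes, edge_scores = NULL, path) {
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  nodes <- sort(unique(as.character(module_nodes)))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"imp_e\" for=\"edge\" attr.name=\"imp_e\" attr.type=\"double\"/>",
    "  <graph id=\"module\" edgedefault=\"undirected\">",
    sprintf("    <node id=\"%s\"/>", xml_escape(nodes))
  )
  if (!is.null(edge_scores) && NROW(edge_scores) > 0L) {
    lines <- c(lines, sprintf(
      "    <edge source=\"%s\" target=\"%s\"><data key=\"imp_e\">%s</data></edge>",
      xml_escape(as.character(edge_scores$from)),
      xml_escape(as.character(edge_scores$to)),
      format(as.numeric(edge_scores$score), digits = 15)
    ))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write module graph to ", path)
  invisible(path)
}
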