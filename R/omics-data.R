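#' Multi-modal feature container keyed by network node
#'
#' Holds one samples-by-nodes numeric matrix per modality (for example mRNA
#' expression and DNA methylation), all sharing the same sample and node
#' ordering, plus one binary label per sample. Feature values are used as-is:
#' trees are scale invariant, so no normalization is ever applied. Missing
#' values are refused, not imputed.
#'
#' @param matrices named list of numeric matrices (samples x nodes) with
#'   rownames = sample ids and colnames = node ids. All matrices must have
#'   identical dimnames (after sorting, which this constructor applies).
#' @param labels binary vector (values 0/1), named by sample id or in the
#'   row order of the matrices. Both classes must be present.
#' @return object of class \code{multi_omics} with fields \code{modalities},
#'   \code{matrices}, \code{samples}, \code{labels}, \code{nodes},
#'   \code{node_index}.
#' @export
multi_omics_data <- function(matrices, labels) {
  if (!is.list(matrices) || !length(matrices) || is.null(names(matrices)) ||
      any(!nzchar(names(matrices)))) {
    stop("`matrices` must be a non-empty named list")
  }
  mods <- names(matrices)
  if (anyDuplicated(mods)) stop("duplicated modality names")
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("every modality matrix needs sample rownames and node colnames")
    }
    m
  })
  samples <- sort(rownames(matrices[[1L]]), method = "radix")
  nodes <- sort(colnames(matrices[[1L]]), method = "radix")
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (anyDuplicated(rownames(m))) {
      stop("duplicated sample id in modality '", mods[i], "'")
    }
    if (!setequal(rownames(m), samples) || !setequal(colnames(m), nodes)) {
      stop("modality '", mods[i],
           "' does not share the sample/node sets of the first modality")
    }
    m <- m[samples, nodes, drop = FALSE]
    if (anyNA(m)) stop("missing values in modality '", mods[i],
                       "' (no silent imputation)")
    matrices[[i]] <- m
  }
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), samples)) {
      stop("label names do not match the sample ids")
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop("labels must have one value per sample")
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary, encoded 0/1")
  }
  if (length(unique(labels)) != 2L) {
    stop("labels must contain both classes")
  }
  structure(
    list(modalities = mods, matrices = matrices, samples = samples,
         labels = setNames(labels, samples), nodes = nodes,
         node_index = setNames(seq_along(nodes), nodes)),
    class = "multi_omics"
  )
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf(
    "<multi_omics> %d samples x %d nodes, %d modalit%s (%s); classes 0/1: %d/%d\n",
    length(x$samples), length(x$nodes), length(x$modalities),
    if (length(x$modalities) == 1L) "y" else "ies",
    paste(x$modalities, collapse = ", "),
    sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Read modality matrices and labels from delimited files
#'
#' Each modality file is a delimited samples-by-nodes table: header of node
#' ids, first column of sample ids. The label file has two columns
#' (sample id, label in \{0,1\}). Matrices are aligned to the intersection of
#' sample ids across all files (strict intersection, no imputation) and to
#' the intersection of node ids across modalities, in sorted order.
#'
#' @param paths character vector of modality file paths; names, if given,
#'   become modality names (else file basenames are used).
#' @param label_path path of the two-column label file.
#' @return a \code{\link{multi_omics_data}} object.
#' @export
read_modalities <- function(paths, label_path) {
  if (!length(paths)) stop("need at least one modality file")
  mods <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  if (any(!nzchar(mods))) mods <- tools::file_path_sans_ext(basename(paths))
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("modality file not found: ", p)
    dt <- data.table::fread(p, header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1L]])
    if (anyDuplicated(ids)) {
      stop("duplicated sample id '", ids[duplicated(ids)][1L], "' in ", p)
    }
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  })
  if (!file.exists(label_path)) stop("label file not found: ", label_path)
  lab <- data.table::fread(label_path, header = TRUE, data.table = FALSE)
  if (ncol(lab) < 2L) stop("label file needs two columns: sample id, label")
  lab_ids <- as.character(lab[[1L]])
  if (anyDuplicated(lab_ids)) stop("duplicated sample id in label file")
  lab_val <- suppressWarnings(as.numeric(lab[[2L]]))
  if (anyNA(lab_val) || !all(lab_val %in% c(0, 1))) {
    stop("label file has non-binary values (must be 0/1)")
  }
  samples <- Reduce(intersect, c(lapply(tabs, rownames), list(lab_ids)))
  if (!length(samples)) stop("no samples shared by all modalities and labels")
  for (i in seq_along(tabs)) {
    if (!length(intersect(rownames(tabs[[i]]), samples))) {
      stop("modality '", mods[i], "' shares no samples with the others")
    }
  }
  samples <- sort(samples, method = "radix")
  nodes <- sort(Reduce(intersect, lapply(tabs, colnames)), method = "radix")
  if (!length(nodes)) stop("no node ids shared by all modalities")
  mats <- lapply(tabs, function(m) m[samples, nodes, drop = FALSE])
  names(mats) <- mods
  labels <- setNames(as.integer(lab_val), lab_ids)[samples]
  multi_omics_data(mats, labels)
}

#' Restrict data and graph to their common node set
#'
#' Keeps only nodes present both in every modality and in the graph; the
#' graph keeps only edges within the retained node set. Idempotent.
#'
#' @param data a \code{multi_omics} object.
#' @param graph a \code{gdf_graph}.
#' @return list with elements \code{data} and \code{graph}.
#' @export
harmonize <- function(data, graph) {
  common <- intersect(data$nodes, graph$nodes)
  if (!length(common)) {
    stop("graph and feature matrices share no node identifiers")
  }
  if (length(common) == length(data$nodes) &&
      length(common) == length(graph$nodes)) {
    return(list(data = data, graph = graph))
  }
  mats <- lapply(data$matrices, function(m) m[, common, drop = FALSE])
  list(data = multi_omics_data(mats, data$labels),
       graph = induced_subgraph(graph, common))
}

#' Subset a multi-omics container by sample
#'
#' @param data a \code{multi_omics} object.
#' @param samples integer indices or character sample ids.
#' @return a \code{multi_omics} object. Fails if the subset drops a class.
#' @export
subset_samples <- function(data, samples) {
  if (is.character(samples)) {
    idx <- match(samples, data$samples)
    if (anyNA(idx)) stop("unknown sample id(s)")
  } else {
    idx <- as.integer(samples)
  }
  mats <- lapply(data$matrices, function(m) m[idx, , drop = FALSE])
  multi_omics_data(mats, data$labels[idx])
}

#' Stratified train/test split
#'
#' Splits samples into disjoint train and test sets, stratified by label:
#' per class, \code{round(test_fraction * n_class)} samples (clamped so that
#' both sides keep at least one sample of each class) go to the test set.
#' Uses the current RNG stream.
#'
#' @param data a \code{multi_omics} object.
#' @param test_fraction fraction of samples in the test set, in (0, 1).
#' @return list with \code{multi_omics} elements \code{train} and \code{test}.
#' @export
split_train_test <- function(data, test_fraction) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be strictly between 0 and 1")
  }
  y <- data$labels
  test_idx <- integer()
  for (cls in c(0L, 1L)) {
    pool <- which(y == cls)
    if (length(pool) < 2L) {
      stop("class ", cls, " has fewer than 2 samples; cannot split")
    }
    k <- min(max(round(test_fraction * length(pool)), 1L), length(pool) - 1L)
    test_idx <- c(test_idx, pool[sample.int(length(pool), k)])
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  list(train = subset_samples(data, train_idx),
       test = subset_samples(data, test_idx))
}
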