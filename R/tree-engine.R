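#' Gini impurity of a class-count vector
#'
#' \code{sum_c p_c (1 - p_c)} over the class proportions \code{p_c}; lies in
#' \code{[0, 1 - 1/C]} for \code{C} classes.
#'
#' @param class_counts vector of non-negative integers, total > 0.
#' @return impurity, a single real.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  n <- sum(class_counts)
  if (n <= 0) stop("all class counts are zero")
  p <- class_counts / n
  sum(p * (1 - p))
}

#' Gini gain of a binary split
#'
#' Parent impurity minus the sample-weighted impurities of the two children.
#' Always non-negative for a valid split (Gini is concave).
#'
#' @param parent_counts,left_counts,right_counts class-count vectors;
#'   \code{left + right} must equal \code{parent} elementwise and both
#'   children must be non-empty.
#' @return the gain, a single real >= 0.
#' @export
gini_gain <- function(parent_counts, left_counts, right_counts) {
  if (!isTRUE(all.equal(left_counts + right_counts, parent_counts))) {
    stop("left + right counts must equal the parent counts")
  }
  nl <- sum(left_counts); nr <- sum(right_counts)
  if (nl == 0 || nr == 0) stop("both children must be non-empty")
  n <- nl + nr
  gini_impurity(parent_counts) -
    (nl / n) * gini_impurity(left_counts) -
    (nr / n) * gini_impurity(right_counts)
}

#' Reference a feature by node and modality
#'
#' A feature is one modality's column of one network node. The canonical
#' ordering used everywhere (design-matrix columns, tie-breaking) is
#' lexicographic by (node, modality).
#'
#' @param node,modality character vectors (recycled to common length).
#' @return data frame with columns \code{node} and \code{modality}.
#' @export
feature_ref <- function(node, modality) {
  data.frame(node = as.character(node), modality = as.character(modality),
             stringsAsFactors = FALSE)
}

# internal: distinct feature refs in canonical order
canonical_features <- function(feature_set) {
  key <- feature_key(feature_set$node, feature_set$modality)
  f <- feature_set[!duplicated(key), , drop = FALSE]
  f[order(f$node, f$modality, method = "radix"), , drop = FALSE]
}

# internal: n x p design matrix for distinct feature refs (hot path)
design_matrix <- function(data, features, sample_indices = NULL) {
  p <- nrow(features)
  cols <- data$node_index[features$node]
  if (anyNA(cols)) {
    stop("unknown node id(s) in feature set: ",
         paste(unique(features$node[is.na(cols)]), collapse = ", "))
  }
  if (is.null(sample_indices)) {
    n <- length(data$samples)
    X <- matrix(0, n, p)
    for (j in seq_len(p)) {
      X[, j] <- data$matrices[[features$modality[j]]][, cols[j]]
    }
  } else {
    n <- length(sample_indices)
    X <- matrix(0, n, p)
    for (j in seq_len(p)) {
      X[, j] <- data$matrices[[features$modality[j]]][sample_indices, cols[j]]
    }
  }
  X
}

# internal: wrap the compiled CART fit into a gdf_tree
fit_tree_raw <- function(X, y, features, min_leaf) {
  t <- fit_tree_cpp(X, as.integer(y), as.integer(min_leaf))
  keys <- feature_key(features$node, features$modality)
  gain_tally <- setNames(numeric(nrow(features)), keys)
  used <- t$feature > 0L
  if (any(used)) {
    g <- vapply(split(t$gain[used], t$feature[used]), sum, 0)
    gain_tally[as.integer(names(g))] <- g
  }
  structure(
    list(feature = t$feature, threshold = t$threshold, left = t$left,
         right = t$right, prob = t$prob, n = t$n, node_gain = t$gain,
         features = features, gain_tally = gain_tally,
         n_train = nrow(X)),
    class = "gdf_tree"
  )
}

#' Fit a CART decision tree on a restricted multi-modal feature set
#'
#' Recursively splits on the (feature, threshold) pair with maximal Gini
#' gain; thresholds are midpoints between consecutive distinct in-bag values
#' (binary features therefore split at 0.5). Stops at pure nodes, when no
#' split has strictly positive gain, or below \code{2 * min_leaf} samples.
#' Leaves store the class-1 proportion. Ties are broken towards the
#' lexicographically first (node, modality) and the smallest threshold, so
#' fitting is deterministic. The realized, in-bag-fraction-weighted Gini
#' gain of every split is accumulated per feature in \code{gain_tally}; the
#' tally sums to the tree's total impurity decrease.
#'
#' @param data a \code{multi_omics} object.
#' @param feature_set data frame with columns \code{node}, \code{modality}
#'   (a multiset; duplicates are kept for bookkeeping but do not enlarge the
#'   hypothesis space).
#' @param sample_indices integer indices of the training (in-bag) samples;
#'   \code{NULL} uses all samples.
#' @param min_leaf minimum samples per leaf (default 1).
#' @return object of class \code{gdf_tree}.
#' @export
fit_tree <- function(data, feature_set, sample_indices = NULL, min_leaf = 1L) {
  if (is.null(feature_set) || !NROW(feature_set)) {
    stop("`feature_set` must be non-empty")
  }
  features <- canonical_features(feature_set)
  idx <- sample_indices %||% seq_along(data$samples)
  X <- design_matrix(data, features, idx)
  tree <- fit_tree_raw(X, data$labels[idx], features, min_leaf)
  tree$feature_multiset <- feature_set
  tree
}

#' @export
print.gdf_tree <- function(x, ...) {
  cat(sprintf("<gdf_tree> %d nodes (%d leaves), %d candidate features\n",
              length(x$feature), sum(x$feature == 0L), nrow(x$features)))
  invisible(x)
}

#' Class-1 probabilities from a fitted tree
#'
#' @param tree a \code{gdf_tree}.
#' @param data a \code{multi_omics} object resolving every feature of the
#'   tree.
#' @param sample_indices integer indices or \code{NULL} for all samples.
#' @return numeric vector of class-1 probabilities.
#' @export
predict_proba <- function(tree, data, sample_indices = NULL) {
  X <- design_matrix(data, tree$features, sample_indices)
  predict_tree_cpp(tree$feature, tree$threshold, tree$left, tree$right,
                   tree$prob, X)
}

#' Indented text dump of a tree (debug aid)
#'
#' @param tree a \code{gdf_tree}.
#' @return character vector, one line per tree node.
#' @export
tree_text <- function(tree) {
  out <- character()
  rec <- function(i, ind) {
    pad <- strrep("  ", ind)
    if (tree$feature[i] == 0L) {
      out[[length(out) + 1L]] <<- sprintf("%sleaf p1=%.4g n=%d", pad,
                                          tree$prob[i], tree$n[i])
    } else {
      f <- tree$features[tree$feature[i], ]
      out[[length(out) + 1L]] <<- sprintf(
        "%s%s[%s] <= %.4g n=%d gain=%.4g", pad, f$node, f$modality,
        tree$threshold[i], tree$n[i], tree$node_gain[i])
      rec(tree$left[i], ind + 1L)
      rec(tree$right[i], ind + 1L)
    }
  }
  rec(1L, 0L)
  out
}

#' ROC-AUC (Mann-Whitney concordance)
#'
#' Fraction of (positive, negative) pairs with the positive scored higher;
#' ties count 0.5. Errors with condition class \code{gdf_undefined_auc} when
#' only one class is present (callers in the greedy loop substitute 0.5).
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1), same length.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("labels must be 0/1 and scores non-missing")
  }
  npos <- sum(y == 1L)
  nneg <- length(y) - npos
  if (npos == 0L || nneg == 0L) {
    stop(errorCondition("ROC-AUC undefined: only one class present",
                        class = "gdf_undefined_auc"))
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# internal: AUC with the chance-level fallback for single-class label sets
auc_or_chance <- function(scores, labels) {
  if (length(unique(labels)) < 2L) {
    gdf_log("OOB set single-class; using chance performance 0.5")
    return(0.5)
  }
  roc_auc(scores, labels)
}

#' Bootstrap sample with out-of-bag complement
#'
#' Draws \code{n} indices with replacement; the out-of-bag set is the set of
#' indices never drawn (expected fraction about \code{1/e}).
#'
#' @param n number of samples (>= 2).
#' @return list with integer vectors \code{in_bag} (length \code{n}) and
#'   \code{oob}.
#' @export
bootstrap_sample <- function(n) {
  if (n < 2L) stop("need at least 2 samples to bootstrap")
  in_bag <- sample.int(n, n, replace = TRUE)
  oob <- which(tabulate(in_bag, nbins = n) == 0L)
  list(in_bag = in_bag, oob = oob)
}
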