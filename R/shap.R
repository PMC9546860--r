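# Path-dependent TreeSHAP. The attribution of each feature is its exact
# Shapley value under the conditional expectation defined by descending the
# tree and weighting both children by their training-sample covers whenever
# the conditioning set does not fix the split feature. Implemented with the
# standard polynomial EXTEND/UNWIND bookkeeping over the unique features on
# the current path (duplicate occurrences of a feature are unwound and
# re-extended, so repeated walk visits are handled exactly).

# m is a list of parallel vectors (d feature id, z zero fraction, o one
# fraction, w path weight); row 1 is the root dummy (d = 0).
shap_extend <- function(m, pz, po, pi) {
  l <- length(m$d)
  m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0L) 1 else 0)
  if (l >= 1L) for (i in l:1L) {
    m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / (l + 1)
    m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
  }
  m
}

# undo the extension that introduced path element i (i >= 2)
shap_unwind <- function(m, i) {
  L <- length(m$d)
  n <- m$w[L]
  oi <- m$o[i]; zi <- m$z[i]
  w <- m$w
  if (oi != 0) {
    for (j in (L - 1L):1L) {
      t <- w[j]
      w[j] <- n * L / (j * oi)
      n <- t - w[j] * zi * (L - j) / L
    }
  } else {
    for (j in (L - 1L):1L) {
      w[j] <- w[j] * L / (zi * (L - j))
    }
  }
  list(d = m$d[-i], z = m$z[-i], o = m$o[-i], w = w[seq_len(L - 1L)])
}

# sum of the unwound weights without materialising the unwound path
shap_unwound_sum <- function(m, i) {
  L <- length(m$d)
  n <- m$w[L]
  oi <- m$o[i]; zi <- m$z[i]
  total <- 0
  if (oi != 0) {
    for (j in (L - 1L):1L) {
      t <- n * L / (j * oi)
      total <- total + t
      n <- m$w[j] - t * zi * (L - j) / L
    }
  } else {
    for (j in (L - 1L):1L) {
      total <- total + m$w[j] * L / (zi * (L - j))
    }
  }
  total
}

# SHAP values of one sample for one gdf_tree; x indexed like tree$features
tree_shap_one <- function(tree, x) {
  p <- nrow(tree$features)
  phi <- numeric(p)
  feat <- tree$feature; thr <- tree$threshold
  lch <- tree$left; rch <- tree$right
  cover <- tree$n; val <- tree$prob

  recurse <- function(j, m, pz, po, pi) {
    m <- shap_extend(m, pz, po, pi)
    if (feat[j] == 0L) {
      L <- length(m$d)
      if (L > 1L) for (i in 2:L) {
        w <- shap_unwound_sum(m, i)
        phi[m$d[i]] <<- phi[m$d[i]] + w * (m$o[i] - m$z[i]) * val[j]
      }
    } else {
      d <- feat[j]
      if (x[d] <= thr[j]) { h <- lch[j]; c <- rch[j] }
      else { h <- rch[j]; c <- lch[j] }
      iz <- 1; io <- 1
      k <- match(d, m$d)
      if (!is.na(k)) {
        iz <- m$z[k]; io <- m$o[k]
        m <- shap_unwind(m, k)
      }
      recurse(h, m, iz * cover[h] / cover[j], io, d)
      recurse(c, m, iz * cover[c] / cover[j], 0, d)
    }
  }
  recurse(1L, list(d = integer(), z = numeric(), o = numeric(),
                   w = numeric()), 1, 1, 0L)
  phi
}

# cover-weighted expected tree prediction (= mean prediction over the
# training in-bag samples); the baseline that makes local additivity exact
tree_expected_value <- function(tree) {
  leaves <- tree$feature == 0L
  sum(tree$prob[leaves] * tree$n[leaves]) / tree$n[1L]
}

# union of per-tree features across a model, canonical order
model_features <- function(model) {
  if (inherits(model, "gdf_tree")) return(model$features)
  all <- do.call(rbind, lapply(model$population, function(r) r$tree$features))
  canonical_features(all)
}

#' SHAP values for a tree or a greedy decision forest
#'
#' Path-dependent TreeSHAP attributions. For a forest, the attribution is
#' the mean of the per-tree attributions (valid because the forest predicts
#' the mean probability and Shapley values are linear in the model). The
#' baseline is the cover-weighted expected prediction, i.e. the mean
#' prediction over each tree's in-bag training samples, which makes the
#' additivity identity \code{prediction = baseline + rowSums(values)} exact.
#' Passing an explicit \code{background} replaces the reported baseline by
#' the mean prediction over those samples (additivity then holds only to the
#' extent the background matches the training distribution).
#'
#' @param model a \code{gdf_tree} or \code{gdf_model}.
#' @param data a \code{multi_omics} object resolving all model features.
#' @param sample_indices integer indices or \code{NULL} for all samples.
#' @param background optional integer indices of background samples used for
#'   the reported baseline; \code{NULL} (default) uses the exact
#'   cover-weighted baseline.
#' @return object of class \code{gdf_shap}: list with \code{baseline},
#'   \code{values} (samples x features matrix, columns keyed
#'   node\\tmodality) and \code{features} (data frame).
#' @export
shap_values <- function(model, data, sample_indices = NULL,
                        background = NULL) {
  idx <- sample_indices %||% seq_along(data$samples)
  trees <- if (inherits(model, "gdf_tree")) list(model)
           else lapply(model$population, `[[`, "tree")
  feats <- model_features(model)
  fkeys <- feature_key(feats$node, feats$modality)
  vals <- matrix(0, length(idx), nrow(feats),
                 dimnames = list(data$samples[idx], fkeys))
  baseline <- 0
  for (tree in trees) {
    tk <- feature_key(tree$features$node, tree$features$modality)
    cols <- match(tk, fkeys)
    X <- design_matrix(data, tree$features, idx)
    for (i in seq_along(idx)) {
      vals[i, cols] <- vals[i, cols] + tree_shap_one(tree, X[i, ])
    }
    baseline <- baseline +
      if (is.null(background)) tree_expected_value(tree)
      else mean(predict_proba(tree, data, background))
  }
  vals <- vals / length(trees)
  baseline <- baseline / length(trees)
  structure(list(baseline = baseline, values = vals, features = feats),
            class = "gdf_shap")
}

#' @export
print.gdf_shap <- function(x, ...) {
  cat(sprintf("<gdf_shap> %d samples x %d features, baseline %.4g\n",
              nrow(x$values), ncol(x$values), x$baseline))
  invisible(x)
}

#' Global SHAP feature importance
#'
#' Mean absolute SHAP value per feature across samples.
#'
#' @param per_sample_values a \code{gdf_shap} object or its values matrix.
#' @return named numeric vector (keys node\\tmodality).
#' @export
shap_feature_importance <- function(per_sample_values) {
  v <- if (inherits(per_sample_values, "gdf_shap")) per_sample_values$values
       else per_sample_values
  if (!NROW(v)) stop("empty SHAP value matrix")
  colMeans(abs(v))
}

#' Aggregate SHAP feature importance per network node
#'
#' Sums the per-feature importances of all modalities of each node
#' (additivity of Shapley values across features justifies the sum).
#'
#' @param feature_importance named vector from
#'   \code{\link{shap_feature_importance}} (keys node\\tmodality).
#' @return named numeric vector per node id.
#' @export
shap_node_importance <- function(feature_importance) {
  nodes <- vapply(strsplit(names(feature_importance), "\t", fixed = TRUE),
                  `[`, "", 1L)
  out <- vapply(split(unname(feature_importance), nodes), sum, 0)
  out[order(names(out), method = "radix")]
}

# conditional expectation of a tree prediction given the features in the
# bitmask `mask` (1-based feature bits); unconditioned splits average the
# children by cover. Used by the interaction enumeration.
tree_cond_exp <- function(tree, x, mask) {
  rec <- function(j) {
    f <- tree$feature[j]
    if (f == 0L) return(tree$prob[j])
    if (bitwAnd(mask, bitwShiftL(1L, f - 1L)) != 0L) {
      if (x[f] <= tree$threshold[j]) rec(tree$left[j]) else rec(tree$right[j])
    } else {
      (tree$n[tree$left[j]] * rec(tree$left[j]) +
         tree$n[tree$right[j]] * rec(tree$right[j])) / tree$n[j]
    }
  }
  rec(1L)
}

# exact Shapley values and pairwise interaction values of one tree for one
# sample, by enumeration over feature subsets (p <= ~15)
tree_interactions_one <- function(tree, x) {
  p <- nrow(tree$features)
  nmask <- bitwShiftL(1L, p)
  ce <- numeric(nmask)
  for (msk in 0:(nmask - 1L)) ce[msk + 1L] <- tree_cond_exp(tree, x, msk)
  sizes <- vapply(0:(nmask - 1L), function(m) sum(bitwAnd(
    m, bitwShiftL(1L, 0:(p - 1L))) != 0L), 0L)
  lf <- lfactorial(0:p)
  phi <- numeric(p)
  # main Shapley values
  for (j in seq_len(p)) {
    bj <- bitwShiftL(1L, j - 1L)
    for (msk in 0:(nmask - 1L)) {
      if (bitwAnd(msk, bj) != 0L) next
      s <- sizes[msk + 1L]
      w <- exp(lf[s + 1L] + lf[p - s] - lf[p + 1L])
      phi[j] <- phi[j] + w * (ce[bitwOr(msk, bj) + 1L] - ce[msk + 1L])
    }
  }
  inter <- matrix(0, p, p)
  if (p >= 2L) {
    for (i in seq_len(p - 1L)) {
      bi <- bitwShiftL(1L, i - 1L)
      for (j in (i + 1L):p) {
        bj <- bitwShiftL(1L, j - 1L)
        acc <- 0
        for (msk in 0:(nmask - 1L)) {
          if (bitwAnd(msk, bitwOr(bi, bj)) != 0L) next
          s <- sizes[msk + 1L]
          w <- exp(lf[s + 1L] + lf[p - s - 1L] - lf[p]) / 2
          acc <- acc + w * (ce[bitwOr(msk, bitwOr(bi, bj)) + 1L] -
                              ce[bitwOr(msk, bi) + 1L] -
                              ce[bitwOr(msk, bj) + 1L] + ce[msk + 1L])
        }
        inter[i, j] <- inter[j, i] <- acc
      }
    }
  }
  diag(inter) <- phi - rowSums(inter)
  inter
}

#' SHAP interaction values
#'
#' Pairwise Shapley interaction values (diagonal = main effects), computed
#' exactly by subset enumeration under the same path-dependent conditional
#' expectation as \code{\link{shap_values}}. Row sums of a sample's
#' interaction matrix recover its SHAP values. Global pair importance is the
#' mean absolute interaction across samples; feature pairs whose nodes are
#' joined by a graph edge are reported separately as an edge-level
#' explanation. Enumeration is exponential in the feature count, so trees
#' are limited to \code{max_features} distinct features.
#'
#' @param model a \code{gdf_tree} or \code{gdf_model} (forest interactions
#'   are the mean of per-tree interactions).
#' @param data a \code{multi_omics} object.
#' @param sample_indices integer indices or \code{NULL} for all samples.
#' @param graph optional \code{gdf_graph} for the edge aggregation; defaults
#'   to the model's graph when available.
#' @param max_features refuse trees with more distinct features than this.
#' @return list with \code{per_sample} (array samples x p x p),
#'   \code{global} (p x p matrix of mean absolute values), \code{features},
#'   and \code{edges} (data frame of edge-mapped pair importances, largest
#'   first).
#' @export
shap_interactions <- function(model, data, sample_indices = NULL,
                              graph = NULL, max_features = 15L) {
  idx <- sample_indices %||% seq_along(data$samples)
  trees <- if (inherits(model, "gdf_tree")) list(model)
           else lapply(model$population, `[[`, "tree")
  if (is.null(graph) && inherits(model, "gdf_model")) graph <- model$graph
  feats <- model_features(model)
  fkeys <- feature_key(feats$node, feats$modality)
  p <- nrow(feats)
  arr <- array(0, dim = c(length(idx), p, p),
               dimnames = list(data$samples[idx], fkeys, fkeys))
  for (tree in trees) {
    pt <- nrow(tree$features)
    if (pt > max_features) {
      stop("tree has ", pt, " distinct features; interaction enumeration ",
           "is capped at max_features = ", max_features)
    }
    tk <- feature_key(tree$features$node, tree$features$modality)
    cols <- match(tk, fkeys)
    X <- design_matrix(data, tree$features, idx)
    for (i in seq_along(idx)) {
      arr[i, cols, cols] <- arr[i, cols, cols] +
        tree_interactions_one(tree, X[i, ])
    }
  }
  arr <- arr / length(trees)
  global <- apply(abs(arr), c(2, 3), mean)
  edges <- NULL
  if (!is.null(graph) && p >= 2L) {
    rows <- list()
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      ni <- feats$node[i]; nj <- feats$node[j]
      if (ni == nj) next
      if (edge_key(ni, nj) %in% edge_key(graph$edges[, 1L],
                                         graph$edges[, 2L])) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_i = fkeys[i], feature_j = fkeys[j],
          node_i = min(ni, nj), node_j = max(ni, nj),
          importance = global[i, j], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      edges <- do.call(rbind, rows)
      edges <- edges[order(-edges$importance), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  list(per_sample = arr, global = global, features = feats, edges = edges)
}

#' Ranked signed attributions for one sample
#'
#' @param model a \code{gdf_tree} or \code{gdf_model}.
#' @param data a \code{multi_omics} object.
#' @param sample a sample id or single integer index.
#' @return data frame (node, modality, sv) sorted by \code{abs(sv)}
#'   descending; exact zeros are dropped (a constant model yields zero rows).
#' @export
explain_sample <- function(model, data, sample) {
  idx <- if (is.character(sample)) match(sample, data$samples)
         else as.integer(sample)
  if (is.na(idx) || idx < 1L || idx > length(data$samples)) {
    stop("unknown sample: ", sample)
  }
  sv <- shap_values(model, data, sample_indices = idx)
  v <- sv$values[1L, ]
  keep <- v != 0
  out <- data.frame(node = sv$features$node[keep],
                    modality = sv$features$modality[keep],
                    sv = unname(v[keep]), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$sv)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the top percent of scored elements
#'
#' Retains exactly \code{ceiling(percent/100 * length(x))} elements with the
#' largest values (the "top 1\%" filter used when plotting explanation
#' summaries).
#'
#' @param x named numeric vector.
#' @param percent percentage to keep (default 1).
#' @return the retained elements, sorted decreasing.
#' @export
top_percent <- function(x, percent = 1) {
  if (!length(x)) return(x)
  k <- ceiling(percent / 100 * length(x))
  sort(x, decreasing = TRUE)[seq_len(k)]
}
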