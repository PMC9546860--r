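# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (pair enumeration, exhaustive
# search, subset enumeration) and never call the code paths they verify.

# ROC-AUC by explicit enumeration of all (positive, negative) pairs
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# best (feature, threshold) split by exhaustive search, mirroring the
# contract: max Gini gain, ties to lowest column then smallest threshold
best_split_brute <- function(X, y, min_leaf = 1L) {
  gini <- function(v) {
    if (!length(v)) return(0)
    p <- mean(v)
    2 * p * (1 - p)
  }
  n <- length(y)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2L) next
    thr <- (u[-length(u)] + u[-1L]) / 2
    for (t in thr) {
      l <- y[X[, j] <= t]
      r <- y[X[, j] > t]
      if (length(l) < min_leaf || length(r) < min_leaf) next
      g <- gini(y) - length(l) / n * gini(l) - length(r) / n * gini(r)
      if (g > best$gain) {  # exact: ties keep the first (lowest) feature
        best <- list(gain = g, feature = j, threshold = t)
      }
    }
  }
  best
}

# conditional expectation of a tree prediction with the features in `keep`
# (integer indices) fixed at x, others marginalized by cover weights --
# written independently of the package's internal traversal
oracle_cond_exp <- function(tree, x, keep) {
  walk <- function(i) {
    f <- tree$feature[i]
    if (f == 0L) return(tree$prob[i])
    if (f %in% keep) {
      if (x[f] <= tree$threshold[i]) walk(tree$left[i]) else walk(tree$right[i])
    } else {
      nl <- tree$n[tree$left[i]]
      nr <- tree$n[tree$right[i]]
      (nl * walk(tree$left[i]) + nr * walk(tree$right[i])) / (nl + nr)
    }
  }
  walk(1L)
}

# exact Shapley values by full subset enumeration (classic definition),
# with conditional expectations from oracle_cond_exp
shap_brute <- function(tree, x) {
  p <- nrow(tree$features)
  phi <- numeric(p)
  all_sets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) != 0))
  ce <- vapply(all_sets, function(s) oracle_cond_exp(tree, x, s), 0)
  names(ce) <- vapply(all_sets, paste, "", collapse = ",")
  for (j in seq_len(p)) {
    for (si in seq_along(all_sets)) {
      s <- all_sets[[si]]
      if (j %in% s) next
      sz <- length(s)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      sj <- sort(c(s, j))
      phi[j] <- phi[j] + w * (ce[paste(sj, collapse = ",")] - ce[si])
    }
  }
  phi
}

# total impurity decrease of a tree: root Gini minus cover-weighted leaf Gini
tree_impurity_decrease <- function(tree) {
  g <- function(p) 2 * p * (1 - p)
  leaves <- tree$feature == 0L
  g(tree$prob[1L]) - sum(tree$n[leaves] / tree$n[1L] * g(tree$prob[leaves]))
}

# small helpers to build fixtures ------------------------------------------

# path graph a-b-c-...
path_graph <- function(ids) {
  gdf_graph(cbind(ids[-length(ids)], ids[-1L]))
}

# a tiny multi_omics container from a named list of matrices
tiny_data <- function(n = 40, nodes = c("g1", "g2", "g3"),
                      modalities = "a", seed = 1, labels = NULL) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n))
  mats <- lapply(modalities, function(m) {
    matrix(rbinom(n * length(nodes), 1, 0.5), n,
           dimnames = list(samples, nodes))
  })
  names(mats) <- modalities
  if (is.null(labels)) {
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  }
  multi_omics_data(mats, setNames(labels, samples))
}

# random small fitted tree on random binary/continuous data, for SHAP tests
random_small_tree <- function(p = 4, n = 60, seed = 1, continuous = FALSE) {
  set.seed(seed)
  nodes <- sprintf("g%d", seq_len(p))
  samples <- sprintf("s%03d", seq_len(n))
  X <- if (continuous) matrix(runif(n * p), n) else matrix(rbinom(n * p, 1, 0.5), n)
  dimnames(X) <- list(samples, nodes)
  y <- rbinom(n, 1, plogis(X %*% runif(p, -2, 2) - mean(X %*% runif(p, -2, 2))))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  d <- multi_omics_data(list(a = X), setNames(y, samples))
  list(data = d,
       tree = fit_tree(d, feature_ref(nodes, "a")))
}
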