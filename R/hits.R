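#' Select co-evolutionary hits by adaptive clustering of DI values
#'
#' DI values of all position pairs are clustered by average-linkage
#' hierarchical clustering of their pairwise distances
#' `dDI_ab = sqrt((DI_a - DI_b)^2)` and the dendrogram is partitioned with
#' an adaptive gap cut: descending from the root, a merge is split into its
#' two branches whenever the merge height exceeds the internal height of its
#' branches by more than `mean(h) + k * sd(h)` over all merge heights `h`,
#' with `k` set by `deep_split` (0 = most conservative, 4 = most eager).
#' This isolates small, tight outlier clusters nested far above the dense
#' background of near-zero DI values. The most populous cluster is taken as
#' the background; members of every other cluster whose DI strictly exceeds
#' the background maximum are the hits. Clusters smaller than
#' `min_cluster_size` are absorbed into the background, as are clusters of
#' negative outliers (which fail the background-maximum filter).
#'
#' The selection depends only on the DI values: it is invariant under
#' relabeling of pair indices and under adding a constant to all values.
#'
#' @param di A `di_matrix` with `stage = "corrected"`.
#' @param L0 Repeat-unit width (the matrix width must be a multiple).
#' @param min_cluster_size Minimum cluster size kept apart from the
#'   background (default 2).
#' @param deep_split Integer 0-4 controlling split eagerness (default 1).
#' @return A `hit_set`: data.frame `pairs` with columns `i`, `j`, `di`,
#'   `cluster`, `class` (`intra_repeat`, `inter_repeat`,
#'   `symmetric_diagonal`), plus `background_cluster`, `n_clusters`, and the
#'   background maximum.
#' @export
cluster_hits <- function(di, L0, min_cluster_size = 2L, deep_split = 1L) {
  stopifnot(inherits(di, "di_matrix"))
  if (di$stage != "corrected")
    stop("cluster_hits expects a corrected-stage DI matrix")
  L <- nrow(di$values)
  if (L %% L0 != 0L) stop("matrix width ", L, " is not a multiple of L0 = ", L0)
  ut <- which(upper.tri(di$values), arr.ind = TRUE)
  vals <- di$values[ut]
  if (length(unique(vals)) < 3L) {
    warning("fewer than 3 distinct DI values: degenerate clustering, no hits")
    return(new_hit_set(empty_pairs(), background_cluster = 1L,
                       n_clusters = 1L, background_max = suppressWarnings(max(vals))))
  }
  labels <- gap_cut_cluster(vals, min_cluster_size = min_cluster_size,
                            deep_split = deep_split)
  sizes <- table(labels)
  background <- as.integer(names(sizes)[which.max(sizes)])
  bg_max <- max(vals[labels == background])
  keep <- labels != background & vals > bg_max
  pairs <- data.frame(i = ut[keep, 1], j = ut[keep, 2], di = vals[keep],
                      cluster = labels[keep],
                      class = classify_pair(ut[keep, 1], ut[keep, 2], L0),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$di), , drop = FALSE]
  rownames(pairs) <- NULL
  new_hit_set(pairs, background_cluster = background,
              n_clusters = length(sizes), background_max = bg_max)
}

empty_pairs <- function() {
  data.frame(i = integer(0), j = integer(0), di = numeric(0),
             cluster = integer(0), class = character(0),
             stringsAsFactors = FALSE)
}

new_hit_set <- function(pairs, background_cluster, n_clusters, background_max) {
  structure(list(pairs = pairs, background_cluster = background_cluster,
                 n_clusters = n_clusters, background_max = background_max),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat("hit_set:", nrow(x$pairs), "hits in",
      x$n_clusters - 1L, "outlier cluster(s); background max DI =",
      format(x$background_max, digits = 4), "\n")
  invisible(x)
}

# Adaptive gap cut of a 1-D value set. Returns integer cluster labels.
#
# A merge is split into its two branches when the merge height stands clear
# of the *core scatter* (mean internal merge height) of both branches by
# more than g = mean(h) + k * sd(h) over all merge heights h. Members of
# clusters below min_cluster_size are reassigned to the nearest surviving
# cluster by value, so a lone extreme value joins the adjacent outlier
# cluster rather than contaminating the background.
gap_cut_cluster <- function(vals, min_cluster_size = 2L, deep_split = 1L) {
  stopifnot(deep_split %in% 0:4)
  k <- c(3.5, 3.0, 2.5, 2.0, 1.5)[deep_split + 1L]
  hc <- hclust(dist(vals), method = "average")
  n <- length(vals)
  h <- hc$height
  g <- mean(h) + k * sd(h)
  # per-merge subtree aggregates (children precede parents in hclust order)
  n_merges <- nrow(hc$merge)
  sum_h <- cnt_h <- numeric(n_merges)
  for (m in seq_len(n_merges)) {
    for (kid in hc$merge[m, ]) {
      if (kid > 0) {
        sum_h[m] <- sum_h[m] + sum_h[kid]
        cnt_h[m] <- cnt_h[m] + cnt_h[kid]
      }
    }
    sum_h[m] <- sum_h[m] + h[m]
    cnt_h[m] <- cnt_h[m] + 1
  }
  scatter <- function(id) if (id < 0) 0 else sum_h[id] / cnt_h[id]
  labels <- integer(n)
  next_label <- 0L
  assign_cluster <- function(id) {
    next_label <<- next_label + 1L
    labels[subtree_leaves(hc, id)] <<- next_label
  }
  descend <- function(id) {
    if (id < 0) { assign_cluster(id); return(invisible(NULL)) }
    kids <- hc$merge[id, ]
    if (h[id] - scatter(kids[1]) > g && h[id] - scatter(kids[2]) > g) {
      descend(kids[1]); descend(kids[2])
    } else {
      assign_cluster(id)
    }
  }
  descend(n_merges)
  # dissolve undersized clusters into the nearest surviving cluster by value
  sizes <- table(labels)
  eligible <- as.integer(names(sizes)[sizes >= min_cluster_size])
  if (length(eligible) && length(eligible) < length(sizes)) {
    means <- vapply(eligible, function(cl) mean(vals[labels == cl]), numeric(1))
    for (idx in which(!(labels %in% eligible)))
      labels[idx] <- eligible[which.min(abs(vals[idx] - means))]
  }
  labels
}

# Leaf indices (into the original observations) under a merge node.
subtree_leaves <- function(hc, id) {
  if (id < 0) return(-id)
  stack <- id
  leaves <- integer(0)
  while (length(stack)) {
    top <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- hc$merge[top, ]
    for (kk in kids) {
      if (kk < 0) leaves <- c(leaves, -kk) else stack <- c(stack, kk)
    }
  }
  leaves
}

# Pair classification relative to the repeat grid.
classify_pair <- function(i, j, L0) {
  sep <- abs(j - i)
  unit_i <- (i - 1L) %/% L0
  unit_j <- (j - 1L) %/% L0
  out <- ifelse(sep %% L0 == 0L & sep > 0L, "symmetric_diagonal",
                ifelse(unit_i == unit_j, "intra_repeat", "inter_repeat"))
  out
}

#' Top-k pairs ranked by DI
#'
#' Ranked selection used for true-positive-rate curves, complementary to the
#' cluster-based hit selection.
#'
#' @param di A `di_matrix`.
#' @param k Number of pairs.
#' @param L0 Optional repeat-unit width to classify pairs.
#' @return data.frame `i`, `j`, `di` (and `class` when `L0` is given),
#'   ordered by decreasing DI.
#' @export
rank_hits <- function(di, k, L0 = NULL) {
  stopifnot(inherits(di, "di_matrix"), k >= 1)
  ut <- which(upper.tri(di$values), arr.ind = TRUE)
  vals <- di$values[ut]
  ord <- order(-vals)[seq_len(min(k, length(vals)))]
  out <- data.frame(i = ut[ord, 1], j = ut[ord, 2], di = vals[ord])
  if (!is.null(L0)) out$class <- classify_pair(out$i, out$j, L0)
  rownames(out) <- NULL
  out
}

#' Write a hit set as TSV
#'
#' @param hits A `hit_set`.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  stopifnot(inherits(hits, "hit_set"))
  write.table(hits$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
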