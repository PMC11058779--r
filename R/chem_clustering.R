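#' Log-transform a chemistry table
#'
#' Base-10 log of `value + offset`, columnwise. When a column contains
#' zeros its offset is half the smallest positive observed value of that
#' column; otherwise the offset is zero. Equalises the influence of extreme
#' values before Euclidean distances and clustering.
#'
#' @param chem data.frame with `site_id` plus non-negative numeric
#'   variables, or a numeric matrix.
#' @param vars variables to transform (default: all numeric columns).
#' @return site x variable numeric matrix of log10 values; offsets used are
#'   attached as attribute `offsets`.
#' @export
log_transform_chem <- function(chem, vars = NULL) {
  if (is.data.frame(chem)) {
    ids <- if ("site_id" %in% names(chem)) as.character(chem$site_id) else
      rownames(chem)
    num <- chem[vapply(chem, is.numeric, TRUE)]
    m <- as.matrix(num)
    rownames(m) <- ids
  } else {
    m <- as.matrix(chem)
  }
  if (!is.null(vars)) m <- m[, vars, drop = FALSE]
  assert_that(all(m >= 0, na.rm = TRUE),
              "log transform requires non-negative values")
  offsets <- apply(m, 2, function(col) {
    if (any(col == 0, na.rm = TRUE)) {
      pos <- col[col > 0]
      assert_that(length(pos) > 0, "column has no positive value to set an offset")
      min(pos) / 2
    } else 0
  })
  out <- log10(sweep(m, 2, offsets, "+"))
  attr(out, "offsets") <- offsets
  out
}

#' Ward.D2 hierarchical clustering of sites
#'
#' Agglomerates sites by the Ward.D2 criterion on a Euclidean distance
#' matrix (Lance-Williams recurrence on squared distances, square-root
#' heights), so each merge minimises the increase in within-cluster
#' variance. Merge heights are non-decreasing.
#'
#' @param dm distance matrix (square symmetric matrix or `dist`).
#' @return an `hclust` object (also class `sh_dendrogram`).
#' @export
ward_cluster <- function(dm) {
  d <- if (inherits(dm, "dist")) dm else {
    assert_that(is.matrix(dm) && nrow(dm) == ncol(dm), "need a square matrix or dist")
    stats::as.dist(dm)
  }
  assert_that(attr(d, "Size") >= 2, "clustering needs at least 2 sites")
  hc <- stats::hclust(d, method = "ward.D2")
  class(hc) <- c("sh_dendrogram", "hclust")
  hc
}

#' Cut a dendrogram into k spatial clusters
#'
#' Removes the `k - 1` tallest merges. When `order_by` (a named per-site
#' score, e.g. mWPI totals) is supplied, clusters are renumbered by
#' descending mean score so cluster 1 is the cleanest — the `SC-1 ... SC-k`
#' convention.
#'
#' @param dend an `hclust`/`sh_dendrogram`.
#' @param k number of clusters, `1 <= k <= n`.
#' @param order_by optional named numeric vector (site -> score).
#' @return named integer vector site -> cluster id in `1..k`.
#' @export
cut_tree <- function(dend, k, order_by = NULL) {
  n <- nrow(dend$merge) + 1L
  assert_that(k >= 1 && k <= n, "k must lie in 1..n")
  labels <- stats::cutree(dend, k = k)
  if (!is.null(order_by)) {
    assert_that(!is.null(names(order_by)) &&
                  all(names(labels) %in% names(order_by)),
                "order_by must be named and cover all sites")
    mean_score <- tapply(order_by[names(labels)], labels, mean)
    new_id <- rank(-mean_score, ties.method = "first")
    labels <- stats::setNames(as.integer(new_id[as.character(labels)]),
                              names(labels))
  }
  labels
}

#' Per-cluster chemistry summary
#'
#' Mean and min-max range of each variable within each cluster, computed on
#' the original (untransformed) scales.
#'
#' @param chem data.frame with `site_id` and numeric variables.
#' @param labels named vector site -> cluster id.
#' @return long data.frame: cluster, variable, mean, min, max, and a
#'   formatted `summary` string "mean (min-max)".
#' @export
cluster_summary <- function(chem, labels) {
  assert_that(all(as.character(chem$site_id) %in% names(labels)),
              "labels must cover all sites in chem")
  cl <- labels[as.character(chem$site_id)]
  vars <- names(chem)[vapply(chem, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    sub <- chem[cl == g, vars, drop = FALSE]
    data.frame(cluster = g, variable = vars,
               mean = vapply(sub, mean, 0),
               min = vapply(sub, min, 0),
               max = vapply(sub, max, 0))
  }))
  out$summary <- sprintf("%.3g (%.3g-%.3g)", out$mean, out$min, out$max)
  rownames(out) <- NULL
  out
}

#' Serialise a dendrogram
#'
#' `dendrogram_merges()` returns the merge list as a data.frame
#' (step, left, right, height; negative ids are leaves, positive ids earlier
#' merge steps). `write_dendrogram_newick()` writes the tree with heights in
#' Newick format via \pkg{ape}.
#'
#' @param dend an `hclust`/`sh_dendrogram`.
#' @return data.frame of merges.
#' @export
dendrogram_merges <- function(dend) {
  data.frame(step = seq_along(dend$height),
             left = dend$merge[, 1], right = dend$merge[, 2],
             height = dend$height)
}

#' @rdname dendrogram_merges
#' @param file path for the Newick file.
#' @export
write_dendrogram_newick <- function(dend, file) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  ape::write.tree(phy, file = file)
  invisible(file)
}
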