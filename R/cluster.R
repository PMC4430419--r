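# Coerce a feature table (data.frame with metric columns) or matrix to the
# numeric matrix used for clustering; rows with NObjects == 0 or missing
# metric values are dropped.
.feature_matrix <- function(x, metrics = feature_metrics()) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x))
  cols <- intersect(metrics, names(x))
  if (length(cols) < 2L) stop("feature table has fewer than two metric columns")
  m <- as.matrix(x[, cols, drop = FALSE])
  keep <- stats::complete.cases(m)
  if ("NObjects" %in% names(x)) keep <- keep & x$NObjects > 0
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing metrics or zero objects excluded")
  }
  m <- m[keep, , drop = FALSE]
  rn <- if ("image_id" %in% names(x)) x$image_id[keep] else which(keep)
  rownames(m) <- make.unique(as.character(rn))
  attr(m, "kept_rows") <- which(keep)
  m
}

#' Column-wise z-score standardization
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1,
#' the standardization applied before clustering so that metrics on
#' different scales contribute equally.
#'
#' @param x Numeric matrix, or a feature table (`data.frame`) whose metric
#'   columns are extracted; rows with `NObjects == 0` or missing values are
#'   excluded (and reported).
#' @return Standardized numeric matrix.
#' @export
standardize <- function(x) {
  m <- .feature_matrix(x)
  if (nrow(m) < 2L) stop("need at least two rows to standardize")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Two-dimensional clustergram
#'
#' Hierarchical agglomerative clustering (UPGMA / average linkage, Euclidean
#' distance) of both the rows and the columns of a standardized matrix, the
#' structure underlying a clustered heatmap: each merge height equals the
#' average pairwise Euclidean distance between the two clusters joined.
#'
#' @param z Numeric matrix, typically from [standardize()]; at least 2 rows
#'   and 2 columns, no `NA`/`NaN`.
#' @param distance Distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @param linkage Linkage passed to [stats::hclust()]
#'   (default `"average"`, i.e. UPGMA).
#' @return Object of class `clustergram`: list with `row_hclust`,
#'   `col_hclust` ([stats::hclust] trees), `row_order`, `col_order` (leaf
#'   permutations) and `z_matrix`.
#' @export
clustergram <- function(z, distance = "euclidean", linkage = "average") {
  if (anyNA(z)) stop("matrix contains NA/NaN; exclude incomplete rows first")
  if (nrow(z) < 2L || ncol(z) < 2L) stop("need at least 2 rows and 2 columns")
  rh <- stats::hclust(stats::dist(z, method = distance), method = linkage)
  ch <- stats::hclust(stats::dist(t(z), method = distance), method = linkage)
  structure(
    list(row_hclust = rh, col_hclust = ch,
         row_order = rh$order, col_order = ch$order,
         z_matrix = z),
    class = "clustergram")
}

#' @export
print.clustergram <- function(x, ...) {
  cat(sprintf("<clustergram> %d rows x %d cols (average linkage, Euclidean)\n",
              nrow(x$z_matrix), ncol(x$z_matrix)))
  invisible(x)
}

#' Export a clustergram dendrogram in Newick format
#'
#' Branch lengths are derived from the UPGMA merge heights, so the tree is
#' ultrametric.
#'
#' @param cg A [clustergram()].
#' @param which `"row"` or `"col"` dendrogram.
#' @param path Optional file to write to; if `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly, if written to `path`).
#' @export
clustergram_newick <- function(cg, which = c("row", "col"), path = NULL) {
  which <- match.arg(which)
  hc <- if (which == "row") cg$row_hclust else cg$col_hclust
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' The two top-level row groups of a clustergram
#'
#' Cuts the row dendrogram at its root, returning the bipartition that the
#' clustered heatmap displays as the two outermost row branches.
#'
#' @param cg A [clustergram()].
#' @return List of two character vectors of row names.
#' @export
top_split <- function(cg) {
  k2 <- stats::cutree(cg$row_hclust, k = 2)
  split(names(k2), k2)
}

#' Seeded k-means clustering
#'
#' Lloyd's algorithm with Euclidean distance; the best of `n_init` random
#' restarts by within-cluster sum of squares is kept. All randomness comes
#' from `seed`, so results are bit-for-bit reproducible.
#'
#' @param z Numeric matrix (rows = observations), typically standardized.
#' @param k Number of clusters, `1 <= k <= nrow(z)`.
#' @param n_init Number of random restarts (default 10).
#' @param seed Integer seed.
#' @return List with `cluster` (assignments), `centers`, `wcss`
#'   (total within-cluster sum of squares) and `k`.
#' @export
kmeans_cluster <- function(z, k = 3, n_init = 10, seed = 1) {
  if (k < 1) stop("`k` must be >= 1")
  if (k > nrow(z)) stop("`k` cannot exceed the number of rows")
  km <- withr::with_seed(seed, {
    stats::kmeans(z, centers = k, nstart = n_init,
                  algorithm = "Lloyd", iter.max = 100)
  })
  list(cluster = km$cluster, centers = km$centers,
       wcss = km$tot.withinss, k = k)
}

#' Cluster phenotypes from a feature table
#'
#' Convenience front-end reproducing the morphology analysis: aggregates the
#' feature table (per-condition metric means by default, or per-image rows),
#' z-scores it, builds the two-dimensional clustergram and runs seeded
#' k-means.
#'
#' @param features Feature table (`data.frame` with `Condition` and the
#'   metric columns of [feature_metrics()]).
#' @param by `"condition"` (cluster per-condition means, default) or
#'   `"image"` (cluster individual image records).
#' @param k Number of k-means classes (default 3: two drug classes plus the
#'   control-like phenotype).
#' @param n_init,seed Passed to [kmeans_cluster()].
#' @return List with `z` (standardized matrix), `clustergram`, `kmeans`,
#'   and `labels` (the Condition label of each clustered row).
#' @export
cluster_phenotypes <- function(features, by = c("condition", "image"),
                               k = 3, n_init = 10, seed = 1) {
  by <- match.arg(by)
  stopifnot("Condition" %in% names(features))
  if (by == "condition") {
    cols <- intersect(feature_metrics(), names(features))
    keep <- features$NObjects > 0 & stats::complete.cases(features[, cols])
    agg <- stats::aggregate(features[keep, cols], by = list(Condition = features$Condition[keep]), FUN = mean)
    m <- as.matrix(agg[, cols])
    rownames(m) <- agg$Condition
    labels <- agg$Condition
  } else {
    m <- .feature_matrix(features)
    labels <- features$Condition[attr(m, "kept_rows")]
  }
  z <- standardize(m)
  cg <- clustergram(z)
  km <- kmeans_cluster(z, k = min(k, nrow(z)), n_init = n_init, seed = seed)
  list(z = z, clustergram = cg, kmeans = km, labels = labels)
}
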