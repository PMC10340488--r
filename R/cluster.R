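# Cluster-separability analysis of classifier logits: project 3-class
# logits onto the first two principal components, then compare inter-class
# centroid distances against intra-class spread via the Dist/SD ratio.

#' Project 3-class logits onto two principal components
#'
#' Centers the `(L1, L2, L3)` logits and projects them onto the top two
#' principal axes (sample covariance, divisor n - 1). Component signs are
#' fixed by making each axis's largest-magnitude loading positive, so plots
#' and downstream summaries are reproducible.
#'
#' @param logits data frame or matrix with columns `L1`, `L2`, `L3` (a
#'   `label` column, if present, is carried through).
#' @return A data frame with columns `PC1`, `PC2` (and `label` if supplied),
#'   with attributes `rotation` and `sdev` from the underlying PCA.
#' @export
project_logits <- function(logits) {
  labs <- NULL
  if (is.data.frame(logits) && "label" %in% names(logits)) {
    labs <- logits$label
    logits <- logits[, c("L1", "L2", "L3")]
  }
  x <- as.matrix(logits)
  if (!is.numeric(x) || ncol(x) != 3)
    stop("logits must have exactly 3 numeric columns", call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (all(apply(x, 2, stats::var) < .Machine$double.eps))
    stop("degenerate covariance: all samples identical", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(x, 2, pc$center) %*% rot
  out <- data.frame(PC1 = scores[, 1], PC2 = scores[, 2])
  if (!is.null(labs)) out$label <- labs
  attr(out, "rotation") <- rot
  attr(out, "sdev") <- pc$sdev
  out
}

#' Summarize class clusters in PCA space
#'
#' Computes per-class centroids (mean PC1/PC2), the three pairwise Euclidean
#' centroid distances and their total, the per-class spread
#' `sd_c = sqrt(sd(PC1)^2 + sd(PC2)^2)` (sample SD, n - 1), the total spread
#' `sd_total = sqrt(sum(sd_c^2))`, and the 3:1-weighted separability ratio
#' `3 * dist_total / sd_total`.
#'
#' @param points data frame with columns `PC1`, `PC2` (e.g. from
#'   [project_logits()]).
#' @param labels class label per row (1, 2, 3); defaults to `points$label`.
#' @return An object of class `cluster_summary`.
#' @export
#' @examples
#' lg <- make_logits(logit_sim_params(seed = 2))
#' summarize_clusters(project_logits(lg))
summarize_clusters <- function(points, labels = points$label) {
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  if (!all(c("PC1", "PC2") %in% names(points)))
    stop("points must have PC1 and PC2 columns", call. = FALSE)
  labels <- as.integer(factor(labels, levels = sort(unique(labels))))
  classes <- sort(unique(labels))
  if (length(classes) != 3)
    stop("exactly 3 classes are required", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2))
    stop("insufficient data: every class needs at least 2 points",
         call. = FALSE)
  xy <- as.matrix(points[, c("PC1", "PC2")])
  centroids <- t(vapply(classes, function(k) colMeans(xy[labels == k, , drop = FALSE]),
                        numeric(2)))
  rownames(centroids) <- paste0("L", classes)
  d <- function(a, b) sqrt(sum((centroids[a, ] - centroids[b, ])^2))
  pairwise <- c("d12" = d(1, 2), "d23" = d(2, 3), "d13" = d(1, 3))
  sd_per <- vapply(classes, function(k) {
    sub <- xy[labels == k, , drop = FALSE]
    sqrt(stats::sd(sub[, 1])^2 + stats::sd(sub[, 2])^2)
  }, numeric(1))
  names(sd_per) <- paste0("L", classes)
  dist_total <- sum(pairwise)
  sd_total <- sqrt(sum(sd_per^2))
  ratio <- if (sd_total > 0) 3 * dist_total / sd_total else NA_real_
  structure(list(centroids = centroids, pairwise_dists = pairwise,
                 dist_total = dist_total, sd_per_cluster = sd_per,
                 sd_total = sd_total, ratio = ratio, n = nrow(xy)),
            class = "cluster_summary")
}

#' Separability ratio of a cluster summary
#'
#' The 3:1-weighted ratio of total inter-centroid distance to total
#' intra-class standard deviation, `3 * dist_total / sd_total`. Larger values
#' indicate better-separated, tighter class clusters in logit space.
#'
#' @param summary a `cluster_summary`.
#' @return A positive number.
#' @export
dist_sd_ratio <- function(summary) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (!is.finite(summary$sd_total) || summary$sd_total <= 0)
    stop("zero intra-class spread: ratio undefined", call. = FALSE)
  3 * summary$dist_total / summary$sd_total
}

#' Full logit-cluster analysis
#'
#' Convenience wrapper: PCA projection followed by the cluster summary.
#'
#' @param logits data frame with `L1`, `L2`, `L3`, `label` columns, or a path
#'   to such a CSV file.
#' @return A `cluster_summary`.
#' @export
cluster_analysis <- function(logits) {
  if (is.character(logits)) logits <- utils::read.csv(logits)
  pts <- project_logits(logits)
  summarize_clusters(pts)
}

#' @export
print.cluster_summary <- function(x, digits = 2, ...) {
  cat("Logit cluster separability (PCA space)\n")
  cat(sprintf("  pairwise centroid distances: %s (total %.*f)\n",
              paste(sprintf("%.*f", digits, x$pairwise_dists), collapse = ", "),
              digits, x$dist_total))
  cat(sprintf("  per-cluster SD: %s (total %.*f)\n",
              paste(sprintf("%.*f", digits, x$sd_per_cluster), collapse = ", "),
              digits, x$sd_total))
  cat(sprintf("  Dist/SD ratio (3:1 weighted): %.*f\n", digits, x$ratio))
  invisible(x)
}

#' @export
as.data.frame.cluster_summary <- function(x, ...) {
  data.frame(dist_12 = x$pairwise_dists[["d12"]],
             dist_23 = x$pairwise_dists[["d23"]],
             dist_13 = x$pairwise_dists[["d13"]],
             dist_total = x$dist_total,
             sd_1 = x$sd_per_cluster[[1]], sd_2 = x$sd_per_cluster[[2]],
             sd_3 = x$sd_per_cluster[[3]], sd_total = x$sd_total,
             ratio = x$ratio)
}

#' Scatter plot of projected logit clusters
#'
#' @param x a data frame from [project_logits()] with a `label` column.
#' @param ... passed to [plot()].
#' @export
plot_logit_clusters <- function(x, ...) {
  stopifnot(all(c("PC1", "PC2", "label") %in% names(x)))
  cols <- c("#1b9e77", "#d95f02", "#7570b3")
  plot(x$PC1, x$PC2, col = cols[as.integer(factor(x$label))], pch = 19,
       xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = levels(factor(x$label)), col = cols,
                   pch = 19, title = "class")
  invisible(x)
}
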