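#' Assign bipartite TE classes from mixture clusters
#'
#' Converts cluster memberships of the TE x sample siRNA matrix into the
#' bipartite class labels. TEs whose maximum replicate-mean RPM across all
#' samples falls below the detection threshold (2 RPM by default) are labeled
#' `depleted`. Each remaining cluster is labeled `A` or `B` by the sign of
#' the difference between the Pearson correlations of the cluster's mean
#' profile (over detected members) with two fixed stage templates: a
#' late/post-embryonic peak (A) and a mid-embryogenesis peak collapsing at
#' maturity (B). All detected members inherit their cluster's label. Clusters
#' correlating equally with both templates (difference below `1e-6`, or an
#' undefined correlation) are reported as `unclassified`, never silently
#' assigned.
#'
#' @param clusters integer cluster ids per row of `X`, or a `gmm_vev` model
#'   (its hard classification is used).
#' @param X TE x sample matrix of replicate-mean 24-nt RPM with stage labels
#'   as column names and te_id rownames.
#' @param threshold_rpm detection threshold in RPM.
#' @param templates 2 x ncol(X) matrix with rows `A` and `B`; defaults to the
#'   generator's stage templates restricted to `colnames(X)`.
#' @return data.frame with columns te_id, cluster, class
#'   (`A`/`B`/`depleted`/`unclassified`).
#' @export
assign_bipartite_classes <- function(clusters, X, threshold_rpm = 2,
                                     templates = NULL) {
  if (inherits(clusters, "gmm_vev")) clusters <- clusters$classification
  X <- as.matrix(X)
  stopifnot(length(clusters) == nrow(X))
  if (is.null(templates))
    templates <- sirna_templates(colnames(X))[c("A", "B"), , drop = FALSE]
  stopifnot(all(c("A", "B") %in% rownames(templates)),
            ncol(templates) == ncol(X))

  depleted <- apply(X, 1L, max) < threshold_rpm
  cluster_label <- character(0)
  for (cl in sort(unique(clusters))) {
    members <- clusters == cl & !depleted
    if (!any(members)) { cluster_label[as.character(cl)] <- "unclassified"; next }
    prof <- colMeans(X[members, , drop = FALSE])
    r_a <- suppressWarnings(stats::cor(prof, templates["A", ]))
    r_b <- suppressWarnings(stats::cor(prof, templates["B", ]))
    if (is.na(r_a) || is.na(r_b) || abs(r_a - r_b) < 1e-6) {
      cluster_label[as.character(cl)] <- "unclassified"
    } else {
      cluster_label[as.character(cl)] <- if (r_a > r_b) "A" else "B"
    }
  }
  class <- cluster_label[as.character(clusters)]
  class[depleted] <- "depleted"
  data.frame(te_id = rownames(X), cluster = clusters, class = unname(class),
             stringsAsFactors = FALSE)
}

#' Partition TEs by length
#'
#' Applies the fixed length cutoffs separating short (<= 723 bp), medium
#' (724-2114 bp) and long (> 2114 bp) TEs.
#'
#' @param x TE lengths in bp, or an annotation data.frame with start/end
#'   (0-based half-open; lengths are `end - start`).
#' @return factor with levels `short`, `medium`, `long`.
#' @export
length_partition <- function(x) {
  if (is.data.frame(x)) x <- x$end - x$start
  stopifnot(all(x >= 1))
  cut(x, breaks = c(0, 723, 2114, Inf),
      labels = c("short", "medium", "long"))
}

#' Principal component analysis of the siRNA matrix
#'
#' Thin wrapper over [stats::prcomp()] with its defaults (columns centered,
#' not scaled). A zero-variance input yields a flagged degenerate result
#' rather than an error.
#'
#' @param X numeric matrix (observations x variables), >= 2 rows and columns.
#' @return list with `scores`, `loadings`, `variance_explained` (sums to 1),
#'   `sdev` and logical `degenerate`.
#' @export
te_pca <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L, ncol(X) >= 2L)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  degenerate <- !isTRUE(tot > 0)
  ve <- if (degenerate) rep(NA_real_, length(p$sdev)) else p$sdev^2 / tot
  list(scores = p$x, loadings = p$rotation, variance_explained = ve,
       sdev = p$sdev, degenerate = degenerate)
}

#' Complete-linkage clustering of samples
#'
#' Euclidean distances between the sample columns of the siRNA matrix,
#' clustered with complete linkage.
#'
#' @param X TE x sample matrix (>= 2 columns).
#' @return an [stats::hclust] object over the samples.
#' @export
sample_hclust <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2L)
  stats::hclust(stats::dist(t(X), method = "euclidean"), method = "complete")
}

#' Percentages of a count vector
#'
#' @param counts named counts.
#' @param total denominator; defaults to `sum(counts)`.
#' @return percentages on the 0-100 scale.
#' @export
class_proportions <- function(counts, total = sum(counts)) {
  stopifnot(total > 0)
  100 * counts / total
}
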