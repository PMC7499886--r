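#' Group regions by profile shape with restarted k-means
#'
#' Clusters the rows of a scale-regions profile matrix (e.g. nucleosome
#' occupancy over long heterochromatic TEs) into `k` groups with k-means,
#' keeping the best of `n_restarts` seeded starts by within-cluster sum of
#' squares. Groups are renumbered by decreasing mean signal so that group 1
#' always denotes the highest occupancy. Rows with all-zero signal should be
#' removed beforehand.
#'
#' @param matrix a `profile_matrix` or plain numeric matrix (regions x bins).
#' @param k number of groups (default 3).
#' @param n_restarts number of random starts.
#' @param seed integer seed.
#' @return list of class `profile_groups`: `group` (named integer per
#'   region), `centers` (k x bins, in renumbered order), `sizes`, and
#'   `tot_withinss`.
#' @export
kmeans_profiles <- function(matrix, k = 3L, n_restarts = 10L, seed = 1L) {
  m <- unclass(matrix)
  attr(m, "geometry") <- NULL
  if (k > nrow(m)) stop("k exceeds the number of regions")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = k, iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart")
  ord <- order(rowMeans(best$centers), decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  group <- stats::setNames(relabel[best$cluster], rownames(m))
  structure(list(group = group,
                 centers = best$centers[ord, , drop = FALSE],
                 sizes = as.integer(table(factor(group, levels = seq_len(k)))),
                 tot_withinss = best$tot.withinss),
            class = "profile_groups")
}

#' Length-normalized heterochromatic vs euchromatic siRNA enrichment
#'
#' The per-bp siRNA density of heterochromatic (class B) TEs divided by the
#' per-bp density of euchromatic (class A) TEs:
#' `(sum RPM_B / sum bp_B) / (sum RPM_A / sum bp_A)`. The ratio is 1 when the
#' per-bp densities are equal and is invariant under uniform rescaling of all
#' RPM values.
#'
#' @param quant named RPM vector per te_id (one sample).
#' @param labels data.frame with te_id and class columns (A/B labels used).
#' @param annotation TE annotation (te_id, start, end) supplying lengths.
#' @return list of class `enrichment_result`: `ratio` (`NA` with a flag when
#'   the euchromatic density is zero), per-class RPM sums and bp totals.
#' @export
enrichment_het_vs_eu <- function(quant, labels, annotation) {
  len <- stats::setNames(annotation$end - annotation$start, annotation$te_id)
  ids_b <- labels$te_id[labels$class == "B"]
  ids_a <- labels$te_id[labels$class == "A"]
  if (!length(ids_a) || !length(ids_b))
    stop("both classes must be non-empty")
  bp_a <- sum(len[ids_a]); bp_b <- sum(len[ids_b])
  stopifnot(bp_a > 0, bp_b > 0)
  rpm_a <- sum(quant[ids_a]); rpm_b <- sum(quant[ids_b])
  dens_a <- rpm_a / bp_a; dens_b <- rpm_b / bp_b
  ratio <- if (dens_a > 0) dens_b / dens_a else NA_real_
  structure(list(ratio = ratio, undefined = !(dens_a > 0),
                 rpm_het = rpm_b, rpm_eu = rpm_a,
                 bp_het = bp_b, bp_eu = bp_a),
            class = "enrichment_result")
}

#' TE family enrichment among DMR-overlapping TEs
#'
#' For each family, the observed fraction among DMR-overlapping TEs over the
#' family's expected genomic fraction (log2 O/E), with a two-sided Fisher's
#' exact test on the 2x2 membership-by-overlap table.
#'
#' @param dmrs DMR intervals (chrom, start, end; 0-based half-open).
#' @param annotation TE annotation with chrom, start, end, te_id, family.
#' @return data.frame: family, n_family, n_overlap, observed, expected,
#'   log2_oe (`NA` sentinel when no family member overlaps), p_value.
#' @export
family_enrichment <- function(dmrs, annotation) {
  gr_te <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(start = annotation$start + 1L,
                                                   end = annotation$end))
  overl <- rep(FALSE, nrow(annotation))
  if (nrow(dmrs)) {
    gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(start = dmrs$start + 1L,
                                                    end = dmrs$end))
    overl <- GenomicRanges::countOverlaps(gr_te, gr_d) > 0
  }
  n_all <- nrow(annotation); n_over <- sum(overl)
  fams <- sort(unique(annotation$family))
  res <- lapply(fams, function(f) {
    in_f <- annotation$family == f
    o <- sum(in_f & overl)
    observed <- if (n_over > 0) o / n_over else NA_real_
    expected <- sum(in_f) / n_all
    l2 <- if (!is.na(observed) && observed > 0) log2(observed / expected)
          else NA_real_
    p <- stats::fisher.test(matrix(c(o, sum(in_f) - o,
                                     n_over - o,
                                     n_all - sum(in_f) - (n_over - o)),
                                   2L, 2L))$p.value
    data.frame(family = f, n_family = sum(in_f), n_overlap = o,
               observed = observed, expected = expected, log2_oe = l2,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Percentile summary of TEs ranked by mutant siRNA level
#'
#' Ranks TEs by their 24-nt siRNA level in a mutant (e.g. *h1*), splits them
#' into `n_bins` equal-count bins (sizes differing by at most one; ties
#' broken by stable te_id order) and summarizes each bin: class composition
#' and the mean of any per-TE covariates supplied (methylation differences,
#' chromatin-mark enrichments).
#'
#' @param quant_mutant named RPM vector per te_id.
#' @param labels data.frame with te_id and class.
#' @param covariates named list of per-TE numeric vectors (named by te_id).
#' @param n_bins number of percentile bins (default 100).
#' @return data.frame, one row per bin (ascending siRNA level): bin, n,
#'   mean_rpm, `frac_<class>` columns, and `mean_<covariate>` columns.
#' @export
percentile_rank_overlay <- function(quant_mutant, labels, covariates = list(),
                                    n_bins = 100L) {
  ids <- names(quant_mutant)
  stopifnot(!is.null(ids), n_bins >= 1L, length(ids) >= n_bins)
  ord <- ids[order(quant_mutant, ids)]
  bin <- rep(seq_len(n_bins), times = diff(floor(seq(0, length(ids), length.out = n_bins + 1L))))
  cls <- stats::setNames(labels$class, labels$te_id)[ord]
  classes <- sort(unique(labels$class))
  out <- data.frame(bin = seq_len(n_bins),
                    n = as.integer(table(bin)),
                    mean_rpm = as.numeric(tapply(quant_mutant[ord], bin, mean)))
  for (cl in classes)
    out[[paste0("frac_", cl)]] <- as.numeric(tapply(cls == cl, bin, mean))
  for (nm in names(covariates))
    out[[paste0("mean_", nm)]] <-
      as.numeric(tapply(covariates[[nm]][ord], bin, mean))
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (`n + m <= 12`) the p-value is
#' computed by exact enumeration of all arrangements of the pooled values
#' (valid under ties); larger samples use the normal approximation with tie
#' correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `U` (statistic for `a`) and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= 12L) {
    # exact null distribution of U by enumeration of which pooled ranks go to a
    combos <- utils::combn(n + m, n)
    Us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    mu <- n * m / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p_value = min(1, p))
}

#' Z-scores of a per-stage series
#'
#' @param values numeric vector (>= 2 values).
#' @return list with `z` (`(x - mean)/sd`; all zero for a constant series)
#'   and logical `constant` flag.
#' @export
zscore_series <- function(values) {
  stopifnot(length(values) >= 2L)
  s <- stats::sd(values)
  if (!isTRUE(s > 0))
    return(list(z = rep(0, length(values)), constant = TRUE))
  list(z = (values - mean(values)) / s, constant = FALSE)
}

#' Pairwise Pearson correlations between two matrices
#'
#' Correlates every row of `X` with every row of `Y` across matched sample
#' columns (e.g. TE-derived 24-nt siRNA class means against biogenesis-factor
#' transcript levels).
#'
#' @param X,Y numeric matrices with identical column count.
#' @return matrix of Pearson r, rows of `X` x rows of `Y`; rows with zero
#'   variance give `NA`.
#' @export
pearson_matrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  suppressWarnings(stats::cor(t(X), t(Y), method = "pearson"))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 for identical partitions, ~0 at
#'   chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
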