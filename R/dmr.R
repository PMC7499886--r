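# RMS goodness-of-fit statistic for a 2 x S methylation table.
# mc_mat: sims x S matrix (or 1 x S), cov: length-S coverage vector.
# statistic = sqrt(mean over the 2S cells of ((O - E)/N)^2) with E the
# homogeneity expectation (pooled proportion x margins); the methylated and
# unmethylated cells contribute identical squared deviations.
rms_stat <- function(mc_mat, cov) {
  N <- sum(cov)
  S <- length(cov)
  p_hat <- rowSums(mc_mat) / N
  dev <- mc_mat - outer(p_hat, cov)
  sqrt(rowSums(dev^2) / (S * N^2))
}

#' Root-mean-square test for differential methylation at one site
#'
#' Tests homogeneity of methylation proportions across samples at a single
#' cytosine with the root-mean-square goodness-of-fit statistic and a
#' Monte-Carlo null: tables are resampled with each sample's coverage fixed
#' and methylated counts drawn binomially at the pooled proportion. The
#' p-value uses the add-one correction `(b + 1) / (n_sim + 1)` where `b`
#' counts resampled statistics at least as extreme as the observed one.
#'
#' @param mc methylated read counts, one per sample (>= 2 samples).
#' @param cov total read counts per sample, all positive.
#' @param n_sim number of Monte-Carlo resamples.
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with `statistic` and `p_value`.
#' @export
rms_test <- function(mc, cov, n_sim = 3000L, seed = 1L) {
  stopifnot(length(mc) == length(cov), length(cov) >= 2L,
            all(cov > 0), all(mc >= 0), all(mc <= cov))
  # canonical sample order makes the result invariant to input permutation
  ord <- order(cov, mc)
  mc <- mc[ord]; cov <- cov[ord]
  obs <- rms_stat(matrix(mc, 1L), cov)
  if (obs == 0) return(list(statistic = 0, p_value = 1))
  set.seed(seed)
  p_hat <- sum(mc) / sum(cov)
  S <- length(cov)
  sims <- matrix(stats::rbinom(n_sim * S, size = rep(cov, each = n_sim),
                               prob = p_hat), n_sim, S)
  b <- sum(rms_stat(sims, cov) >= obs - 1e-12)
  list(statistic = obs, p_value = (b + 1) / (n_sim + 1))
}

#' Align per-sample methylomes into a site comparison
#'
#' Restricts each sample's cytosine table to one context and intersects the
#' sites covered in every sample, yielding aligned count matrices for DMS
#' testing (replicates are expected to be pooled upstream).
#'
#' @param site_tables named list (one element per sample) of cytosine tables
#'   as returned by [simulate_methylome()] or [read_allc()].
#' @param context methylation context to test (default CHH).
#' @return list of class `site_comparison`: `sites` (chrom, pos, strand,
#'   context, subcontext), matrices `mc` and `cov` (sites x samples), and
#'   `samples`.
#' @export
build_comparison <- function(site_tables, context = "CHH") {
  stopifnot(length(site_tables) >= 2L, !is.null(names(site_tables)))
  tabs <- lapply(site_tables, function(t)
    t[t$context %in% context, , drop = FALSE])
  keys <- lapply(tabs, function(t) paste(t$chrom, t$pos, t$strand))
  common <- Reduce(intersect, keys)
  first <- tabs[[1L]][match(common, keys[[1L]]), , drop = FALSE]
  mc <- vapply(seq_along(tabs), function(i)
    tabs[[i]]$mc[match(common, keys[[i]])], numeric(length(common)))
  cov <- vapply(seq_along(tabs), function(i)
    tabs[[i]]$cov[match(common, keys[[i]])], numeric(length(common)))
  mc <- matrix(mc, ncol = length(tabs),
               dimnames = list(NULL, names(site_tables)))
  cov <- matrix(cov, ncol = length(tabs),
                dimnames = list(NULL, names(site_tables)))
  structure(list(sites = first[, c("chrom", "pos", "strand", "context",
                                   "subcontext")],
                 mc = mc, cov = cov, samples = names(site_tables)),
            class = "site_comparison")
}

#' Call differentially methylated sites
#'
#' Applies the per-sample coverage filter (4 reads by default, 3 for
#' preglobular-tagged samples), computes Monte-Carlo RMS p-values for every
#' retained site, adjusts them by Benjamini-Hochberg and flags sites with
#' q-value at or below the FDR. The Monte-Carlo loop is batched with an
#' early exit: once a site's 99% confidence interval for the p-value lies
#' entirely above the FDR boundary the site stops sampling (it can never be
#' called at that FDR, so downstream results are unaffected).
#'
#' Sites whose statistic is extreme enough that even `n_sim` resamples
#' produce no exceedance escalate in larger batches up to `n_sim_max`
#' resamples: at genome scale the BH threshold sits far below `1/n_sim`, so
#' without escalation a Monte-Carlo p-value at its floor could never be
#' ranked finely enough to be called.
#'
#' @param comparison a [build_comparison()] result.
#' @param fdr false discovery rate for the BH cut (default 0.01).
#' @param min_cov named per-sample minimum coverage, a scalar, or `NULL` for
#'   the default (4, and 3 for samples named `"pg"`).
#' @param n_sim baseline Monte-Carlo resamples per site.
#' @param n_sim_max resample ceiling for sites still unresolved at `n_sim`.
#' @param seed integer seed.
#' @return data.frame of the significant sites (chrom, pos, strand,
#'   statistic, p_value, q_value), with the full tested table in attribute
#'   `tested`.
#' @export
call_dms <- function(comparison, fdr = 0.01, min_cov = NULL, n_sim = 3000L,
                     n_sim_max = 40000L, seed = 1L) {
  stopifnot(inherits(comparison, "site_comparison"))
  samples <- comparison$samples
  if (is.null(min_cov))
    min_cov <- stats::setNames(ifelse(samples == "pg", 3L, 4L), samples)
  if (length(min_cov) == 1L && is.null(names(min_cov)))
    min_cov <- stats::setNames(rep(min_cov, length(samples)), samples)
  keep <- rowSums(sweep(comparison$cov, 2L, min_cov[samples], `>=`)) ==
    length(samples)
  sites <- comparison$sites[keep, , drop = FALSE]
  mc <- comparison$mc[keep, , drop = FALSE]
  cov <- comparison$cov[keep, , drop = FALSE]
  n <- nrow(mc)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), statistic = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!n) { attr(empty, "tested") <- empty; return(empty) }

  S <- ncol(mc)
  N <- rowSums(cov)
  p_hat <- rowSums(mc) / N
  obs <- sqrt(rowSums((mc - p_hat * cov)^2) / (S * N^2))

  set.seed(seed)
  b <- integer(n); done <- integer(n)
  active <- which(obs > 0)
  n_sim_max <- max(n_sim, n_sim_max)
  batches <- c(100L, 400L, 500L, 1000L,
               rep(4000L, ceiling(max(0, n_sim_max - 2000L) / 4000L)))
  batches <- batches[cumsum(batches) <= n_sim_max - 1L + 4000L]
  excess <- sum(batches) - n_sim_max
  if (excess > 0L) batches[length(batches)] <- batches[length(batches)] - excess
  for (B in batches) {
    if (!length(active) || B <= 0L) break
    na <- length(active)
    stat2 <- matrix(0, na, B)
    tot_mc <- matrix(0, na, B)
    sims <- vector("list", S)
    for (s in seq_len(S)) {
      sims[[s]] <- matrix(stats::rbinom(na * B, size = cov[active, s],
                                        prob = p_hat[active]), na, B)
      tot_mc <- tot_mc + sims[[s]]
    }
    p_sim <- tot_mc / N[active]
    for (s in seq_len(S))
      stat2 <- stat2 + (sims[[s]] - p_sim * cov[active, s])^2
    stat_sim <- sqrt(stat2 / (S * N[active]^2))
    b[active] <- b[active] + rowSums(stat_sim >= obs[active] - 1e-12)
    done[active] <- done[active] + B
    p_est <- (b[active] + 1) / (done[active] + 1)
    lower <- p_est - 2.576 * sqrt(p_est * (1 - p_est) / done[active])
    # stop sampling once the p-value cannot reach the FDR boundary, once it
    # is estimated from enough exceedances, or at the baseline budget for
    # sites that are clearly unremarkable
    keep <- lower <= fdr & b[active] < 20L &
      !(done[active] >= n_sim & b[active] >= 5L)
    active <- active[keep]
  }
  p <- ifelse(obs == 0, 1, (b + 1) / (pmax(done, 1L) + 1))
  q <- stats::p.adjust(p, method = "BH")
  tested <- data.frame(chrom = sites$chrom, pos = sites$pos,
                       strand = sites$strand, statistic = obs,
                       p_value = p, q_value = q, stringsAsFactors = FALSE)
  out <- tested[tested$q_value <= fdr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

#' Collapse DMSs into regions
#'
#' Chains differentially methylated sites by transitive single linkage:
#' consecutive sites on a chromosome no more than `max_gap` bp apart join one
#' region. Region intervals span the first to last member site, converted to
#' 0-based half-open coordinates.
#'
#' @param dms data.frame with chrom and pos (1-based) columns.
#' @param max_gap maximum chaining distance in bp (default 100).
#' @return data.frame: chrom, start, end, n_dms.
#' @export
collapse_dmrs <- function(dms, max_gap = 100L) {
  if (!nrow(dms))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dms = integer(),
                      stringsAsFactors = FALSE))
  dms <- dms[order(dms$chrom, dms$pos), , drop = FALSE]
  out <- lapply(split(dms$pos, dms$chrom), function(pos) {
    pos <- unique(sort(pos))
    grp <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    data.frame(start = as.integer(tapply(pos, grp, min) - 1L),
               end = as.integer(tapply(pos, grp, max)),
               n_dms = as.integer(tapply(pos, grp, length)))
  })
  res <- do.call(rbind, Map(function(ch, d) cbind(chrom = ch, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

#' Filter candidate DMRs by DMS count and effect size
#'
#' Keeps regions with at least `min_dms` member sites and a maximum pairwise
#' weighted-methylation difference across the compared samples of at least
#' `min_diff_pp` percentage points. Weighted methylation is recomputed per
#' region from all sites of the comparison lying inside it.
#'
#' @param regions output of [collapse_dmrs()].
#' @param comparison the [build_comparison()] the DMSs came from.
#' @param min_dms minimum number of DMSs (default 4).
#' @param min_diff_pp minimum methylation difference in percentage points
#'   (default 20).
#' @return the retained regions with per-sample weighted methylation columns
#'   (`meth_<sample>`) and `max_difference` (percentage points).
#' @export
filter_dmrs <- function(regions, comparison, min_dms = 4L, min_diff_pp = 20) {
  if (!nrow(regions)) {
    for (s in comparison$samples) regions[[paste0("meth_", s)]] <- numeric(0)
    regions$max_difference <- numeric(0)
    return(regions)
  }
  sgr <- GenomicRanges::GRanges(comparison$sites$chrom,
                                IRanges::IRanges(start = comparison$sites$pos,
                                                 width = 1L))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(start = regions$start + 1L,
                                                 end = regions$end))
  hits <- GenomicRanges::findOverlaps(sgr, rgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rates <- matrix(NA_real_, nrow(regions), length(comparison$samples),
                  dimnames = list(NULL, comparison$samples))
  for (s in comparison$samples) {
    mcs <- rowsum(comparison$mc[qh, s], sh)
    covs <- rowsum(comparison$cov[qh, s], sh)
    idx <- as.integer(rownames(mcs))
    rates[idx, s] <- ifelse(covs[, 1L] > 0, mcs[, 1L] / covs[, 1L], NA_real_)
  }
  max_diff <- 100 * apply(rates, 1L, function(r)
    if (all(is.na(r))) NA_real_ else diff(range(r, na.rm = TRUE)))
  keep <- regions$n_dms >= min_dms & !is.na(max_diff) &
    max_diff >= min_diff_pp
  out <- regions[keep, , drop = FALSE]
  for (s in comparison$samples) out[[paste0("meth_", s)]] <- rates[keep, s]
  out$max_difference <- max_diff[keep]
  rownames(out) <- NULL
  out
}

#' All pairwise stage comparisons
#'
#' @param stages stage labels.
#' @return data.frame with columns `a` and `b`, one row per unordered pair
#'   (C(n, 2) rows; 10 for the five embryonic stages).
#' @export
stage_pairs <- function(stages) {
  cmb <- utils::combn(stages, 2L)
  data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
}

#' Merge DMR sets from pairwise comparisons
#'
#' Takes the union of the intervals called in each pairwise comparison and
#' merges overlapping or bookended intervals (bedtools-merge semantics).
#'
#' @param dmr_sets list of DMR data.frames (chrom, start, end).
#' @return data.frame of merged intervals, sorted.
#' @export
merge_pairwise_dmrs <- function(dmr_sets) {
  all <- do.call(rbind, lapply(dmr_sets, function(d)
    d[, c("chrom", "start", "end"), drop = FALSE]))
  if (is.null(all) || !nrow(all))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all$chrom, IRanges::IRanges(start = all$start + 1L, end = all$end)))
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' One pairwise DMR calling pipeline
#'
#' Convenience wrapper chaining [build_comparison()], [call_dms()],
#' [collapse_dmrs()] and [filter_dmrs()] for one pair of pooled methylomes.
#'
#' @param site_tables named list of two (or more) cytosine tables.
#' @param context context to test (CHH).
#' @param fdr,min_cov,n_sim,n_sim_max,seed passed to [call_dms()].
#' @param max_gap passed to [collapse_dmrs()].
#' @param min_dms,min_diff_pp passed to [filter_dmrs()].
#' @return filtered DMR data.frame; the DMS table is kept in attribute
#'   `dms`.
#' @export
call_dmrs <- function(site_tables, context = "CHH", fdr = 0.01,
                      min_cov = NULL, n_sim = 3000L, n_sim_max = 40000L,
                      seed = 1L, max_gap = 100L, min_dms = 4L,
                      min_diff_pp = 20) {
  cmp <- build_comparison(site_tables, context = context)
  dms <- call_dms(cmp, fdr = fdr, min_cov = min_cov, n_sim = n_sim,
                  n_sim_max = n_sim_max, seed = seed)
  dmrs <- filter_dmrs(collapse_dmrs(dms, max_gap = max_gap), cmp,
                      min_dms = min_dms, min_diff_pp = min_diff_pp)
  attr(dmrs, "dms") <- dms
  dmrs
}

#' Precision and recall of called DMRs against planted truth
#'
#' @param called DMR data.frame (chrom, start, end).
#' @param truth planted intervals (chrom, start, end).
#' @return list with `precision` (fraction of called DMRs overlapping a
#'   planted interval), `recall` (fraction of planted intervals recovered),
#'   and the underlying counts.
#' @export
dmr_recovery_stats <- function(called, truth) {
  if (!nrow(called) || !nrow(truth)) {
    return(list(precision = if (nrow(called)) 0 else NA_real_,
                recall = if (nrow(truth)) 0 else NA_real_,
                n_called = nrow(called), n_truth = nrow(truth)))
  }
  cgr <- GenomicRanges::GRanges(called$chrom,
                                IRanges::IRanges(start = called$start + 1L,
                                                 end = called$end))
  tgr <- GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(start = truth$start + 1L,
                                                 end = truth$end))
  hits <- GenomicRanges::findOverlaps(cgr, tgr)
  list(precision = length(unique(S4Vectors::queryHits(hits))) / nrow(called),
       recall = length(unique(S4Vectors::subjectHits(hits))) / nrow(truth),
       n_called = nrow(called), n_truth = nrow(truth))
}
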