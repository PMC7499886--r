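# all cytosine positions (both strands) of one sequence, with contexts
cytosine_sites_of <- function(sequence) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos_p <- which(bases == "C")
  pos_m <- which(bases == "G")   # C on the minus strand
  pos <- c(pos_p, pos_m)
  strand <- rep(c("+", "-"), c(length(pos_p), length(pos_m)))
  ctx <- classify_context(sequence, pos, strand)
  keep <- !is.na(ctx$context)
  data.frame(pos = pos[keep], strand = strand[keep],
             context = ctx$context[keep], subcontext = ctx$subcontext[keep],
             trinuc = ctx$trinuc[keep], stringsAsFactors = FALSE)
}

#' Simulate a pooled per-stage methylome
#'
#' Emits binomially sampled per-cytosine counts for every cytosine of the
#' genome (both strands) plus the unmethylated control contig. Site-level
#' true methylation is the per-context baseline, except for CHH cytosines
#' inside planted DMR intervals, which follow the stage ramp recorded in the
#' ground truth (hypomethylated at preglobular, progressively methylated to
#' maturity). Bisulfite non-conversion adds a uniform false-methylation rate.
#' Replicates are pooled, as they are upstream of DMS testing: one methylome
#' per stage at `n_replicates` times the per-replicate depth
#' `coverage_per_cytosine`.
#'
#' @param genome a [generate_genome()] result.
#' @param stage stage label.
#' @param config a [sim_config()]; defaults to the genome's own.
#' @return data.frame of cytosine sites: chrom, pos (1-based), strand,
#'   context, subcontext, mc, cov. Sites with zero sampled coverage are
#'   omitted (allc convention). `coverage_per_cytosine = 0` yields an empty
#'   table.
#' @export
simulate_methylome <- function(genome, stage, config = genome$config) {
  validate_sim_config(config)
  if (!stage %in% config$stages) stop("unknown stage label: ", stage)
  set.seed(derive_seed(config$seed, "meth", stage))
  base <- config$meth_baseline
  dmr <- genome$truth$dmr_truth
  lvl_col <- paste0("chh_", stage)

  out <- vector("list", length(genome$sequences))
  names(out) <- names(genome$sequences)
  for (ch in names(genome$sequences)) {
    sites <- cytosine_sites_of(genome$sequences[[ch]])
    if (!nrow(sites)) { out[[ch]] <- NULL; next }
    if (ch == "ctrl") {
      p_true <- rep(0, nrow(sites))
    } else {
      p_true <- unname(base[sites$context])
      d <- dmr[dmr$chrom == ch, , drop = FALSE]
      if (nrow(d)) {
        hit <- IRanges::findOverlaps(
          IRanges::IRanges(start = sites$pos, width = 1L),
          IRanges::IRanges(start = d$start + 1L, end = d$end))
        qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
        in_chh <- sites$context[qh] == "CHH"
        p_true[qh[in_chh]] <- d[[lvl_col]][sh[in_chh]]
      }
    }
    p_obs <- p_true + (1 - p_true) * config$conversion_error
    cov <- stats::rpois(nrow(sites),
                        config$coverage_per_cytosine * config$n_replicates)
    keep <- cov > 0
    if (!any(keep)) { out[[ch]] <- NULL; next }
    mc <- stats::rbinom(sum(keep), cov[keep], p_obs[keep])
    out[[ch]] <- data.frame(chrom = ch, pos = sites$pos[keep],
                            strand = sites$strand[keep],
                            context = sites$context[keep],
                            subcontext = sites$subcontext[keep],
                            trinuc = sites$trinuc[keep],
                            mc = mc, cov = cov[keep],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      subcontext = character(), trinuc = character(),
                      mc = integer(), cov = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
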