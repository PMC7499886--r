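#' Classify cytosine sequence context
#'
#' Derives the methylation context of a cytosine from its strand-oriented
#' trinucleotide: CG when the next base is G, CHG when the base after next is
#' G (and the next is not), otherwise CHH. CHH sites are sub-classified as
#' CWA when the trinucleotide is C-(A|T)-A (the CMT2-preferred subcontext) and
#' non-CWA otherwise. Minus-strand cytosines are classified from their own
#' strand's 5'->3' triplet (reverse complement of the template).
#'
#' Sites whose triplet runs off the 3' end of the sequence on their strand are
#' returned as `NA` context and should be skipped.
#'
#' @param sequence a single chromosome sequence (character scalar).
#' @param pos 1-based position vector of the cytosine on `sequence`.
#' @param strand `"+"` or `"-"`, recycled.
#' @return data.frame with columns `context` (`CG`/`CHG`/`CHH`/`NA`),
#'   `subcontext` (`CWA`/`nonCWA` for CHH, `n/a` otherwise) and `trinuc`
#'   (the strand-oriented trinucleotide, allc convention).
#' @export
classify_context <- function(sequence, pos, strand = "+") {
  n <- length(pos)
  strand <- rep_len(strand, n)
  len <- nchar(sequence)
  b1 <- rep(NA_character_, n)
  b2 <- rep(NA_character_, n); b3 <- rep(NA_character_, n)
  plus <- strand == "+"
  ok_p <- plus & pos + 2L <= len
  if (any(ok_p)) {
    b1[ok_p] <- substring(sequence, pos[ok_p], pos[ok_p])
    b2[ok_p] <- substring(sequence, pos[ok_p] + 1L, pos[ok_p] + 1L)
    b3[ok_p] <- substring(sequence, pos[ok_p] + 2L, pos[ok_p] + 2L)
  }
  ok_m <- !plus & pos - 2L >= 1L
  comp <- function(x) chartr("ACGT", "TGCA", x)
  if (any(ok_m)) {
    b1[ok_m] <- comp(substring(sequence, pos[ok_m], pos[ok_m]))
    b2[ok_m] <- comp(substring(sequence, pos[ok_m] - 1L, pos[ok_m] - 1L))
    b3[ok_m] <- comp(substring(sequence, pos[ok_m] - 2L, pos[ok_m] - 2L))
  }
  out <- context_from_bases(b2, b3)
  out$trinuc <- ifelse(is.na(b2), NA_character_, paste0(b1, b2, b3))
  out
}

# context logic shared by sequence- and trinucleotide-based classification
context_from_bases <- function(b2, b3) {
  n <- length(b2)
  context <- rep(NA_character_, n)
  defined <- !is.na(b2)
  context[defined & b2 == "G"] <- "CG"
  context[defined & b2 != "G" & b3 == "G"] <- "CHG"
  context[defined & b2 != "G" & b3 != "G"] <- "CHH"
  subcontext <- rep("n/a", n)
  subcontext[is.na(context)] <- NA_character_
  is_chh <- !is.na(context) & context == "CHH"
  subcontext[is_chh] <- ifelse(b2[is_chh] %in% c("A", "T") & b3[is_chh] == "A",
                               "CWA", "nonCWA")
  data.frame(context = context, subcontext = subcontext,
             stringsAsFactors = FALSE)
}

#' Classify allc trinucleotide strings
#'
#' @param trinuc character vector of strand-oriented trinucleotides
#'   (e.g. `"CAA"`).
#' @return data.frame with `context` and `subcontext` as in
#'   [classify_context()].
#' @export
trinuc_context <- function(trinuc) {
  context_from_bases(substring(trinuc, 2L, 2L), substring(trinuc, 3L, 3L))
}

#' Weighted methylation level of a region
#'
#' Coverage-weighted methylation: the sum of methylated read counts divided by
#' the sum of total read counts over the qualifying sites -- not a mean of
#' per-site ratios. This makes the rate invariant to arbitrary splitting or
#' pooling of replicate count tables.
#'
#' @param sites data.frame of cytosine sites (chrom, pos, strand, context,
#'   subcontext, mc, cov).
#' @param region optional `c(start, end)` 0-based half-open interval (with
#'   `chrom`) restricting the sites; `NULL` uses all sites.
#' @param chrom chromosome of `region`.
#' @param context restrict to one of `"CG"`, `"CHG"`, `"CHH"`, or `NULL`.
#' @param subcontext for CHH, `"CWA"`, `"nonCWA"`, or `NULL` for both.
#' @return the rate in `[0, 1]`, or `NA_real_` when no qualifying site has
#'   coverage (an explicit "no data" result, never 0).
#' @export
weighted_methylation <- function(sites, region = NULL, chrom = NULL,
                                 context = NULL, subcontext = NULL) {
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(context)) keep <- keep & sites$context %in% context
  if (!is.null(subcontext)) keep <- keep & sites$subcontext %in% subcontext
  if (!is.null(region)) {
    stopifnot(!is.null(chrom), length(region) == 2L)
    keep <- keep & sites$chrom == chrom &
      sites$pos - 1L >= region[1] & sites$pos - 1L < region[2]
  }
  tot <- sum(sites$cov[keep])
  if (!isTRUE(tot > 0)) return(NA_real_)
  sum(sites$mc[keep]) / tot
}

#' Bisulfite conversion rate from an unmethylated control
#'
#' @param control_sites sites from an unmethylated reference (e.g. the `ctrl`
#'   contig emitted by [simulate_methylome()], standing in for the chloroplast
#'   or Lambda spike-in).
#' @return conversion rate as a percentage, `100 * (1 - sum(mc)/sum(cov))`.
#' @export
conversion_rate <- function(control_sites) {
  tot <- sum(control_sites$cov)
  if (!isTRUE(tot > 0)) stop("control sites have zero total coverage")
  100 * (1 - sum(control_sites$mc) / tot)
}
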