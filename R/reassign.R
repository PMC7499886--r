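#' Rich-get-richer reassignment of multi-mapping reads
#'
#' Fractionally assigns each multi-mapping read across its candidate loci by
#' iterating a preferential ("rich-get-richer") update: a candidate's weight
#' is proportional to the total currently assigned read mass -- uniquely
#' mapping reads plus the fractional mass of other multimappers -- within a
#' window spanning the candidate footprint extended by `window` bp on each
#' side. Weights are renormalized per read after every update, so total read
#' mass is conserved exactly at all times. Uniquely mapping reads keep weight
#' 1 and anchor the fixed point.
#'
#' If every candidate of a read sees zero coverage, the read's weights fall
#' back to uniform.
#'
#' @param alignments long-format alignment table (one row per candidate
#'   locus): read_id, length, count, chrom, start (0-based), n_cand,
#'   cand_idx, plus any other columns.
#' @param max_iter maximum number of fixed-point iterations.
#' @param tol convergence threshold on the maximum absolute per-candidate
#'   weight change.
#' @param window bp added to each side of the candidate footprint when
#'   summing local coverage.
#' @return the input table with a `weight` column; each read's weights are in
#'   `[0, 1]` and sum to 1.
#' @export
reassign_multimappers <- function(alignments, max_iter = 100L, tol = 1e-6,
                                  window = 25L) {
  need <- c("read_id", "length", "count", "chrom", "start", "n_cand")
  stopifnot(all(need %in% names(alignments)))
  if (any(alignments$n_cand < 1L))
    stop("alignment record with empty candidate list")
  n_per_read <- table(alignments$read_id)
  if (!all(as.integer(n_per_read) ==
           alignments$n_cand[match(names(n_per_read), alignments$read_id)]))
    stop("n_cand inconsistent with candidate rows")
  if (!nrow(alignments)) {
    alignments$weight <- numeric(0)
    return(alignments)
  }

  # global coordinates with inter-chromosome padding so windows never bleed
  chroms <- unique(alignments$chrom)
  pad <- max(alignments$length) + window + 1L
  span <- vapply(chroms, function(ch)
    max(alignments$start[alignments$chrom == ch] + alignments$length[alignments$chrom == ch]),
    numeric(1))
  offset <- stats::setNames(cumsum(c(0, utils::head(span + pad, -1))), chroms)
  gpos <- as.integer(offset[alignments$chrom] + alignments$start + 1L)
  G <- max(gpos) + pad

  is_mm <- alignments$n_cand > 1L
  w <- ifelse(is_mm, 1 / alignments$n_cand, 1)
  mass <- alignments$count * w

  # fixed unique-read mass at start positions
  u_vec <- numeric(G)
  if (any(!is_mm)) {
    m <- rowsum(mass[!is_mm], gpos[!is_mm])
    u_vec[as.integer(rownames(m))] <- m[, 1L]
  }
  if (!any(is_mm)) {
    alignments$weight <- w
    return(alignments)
  }

  mm <- which(is_mm)
  mm_pos <- gpos[mm]
  lo <- pmax(1L, mm_pos - as.integer(window))
  hi <- pmin(G, mm_pos + alignments$length[mm] - 1L + as.integer(window))
  # per-read grouping of multimapper candidate rows
  read_f <- match(alignments$read_id[mm], unique(alignments$read_id[mm]))
  cnt <- alignments$count[mm]

  for (iter in seq_len(max_iter)) {
    vec <- u_vec
    m <- rowsum(cnt * w[mm], mm_pos)
    idx <- as.integer(rownames(m))
    vec[idx] <- vec[idx] + m[, 1L]
    cs <- c(0, cumsum(vec))
    score <- cs[hi + 1L] - cs[lo]
    tot <- rowsum(score, read_f)[read_f, 1L]
    new_w <- ifelse(tot > 0, score / tot, 1 / alignments$n_cand[mm])
    delta <- max(abs(new_w - w[mm]))
    w[mm] <- new_w
    if (delta < tol) break
  }
  alignments$weight <- w
  alignments
}

#' Normalize assigned reads to RPM
#'
#' Converts fractionally assigned alignments into reads-per-million units:
#' each candidate contributes `count * weight * 1e6 / total_genome_matching`
#' at its alignment start position.
#'
#' @param weighted output of [reassign_multimappers()].
#' @param total_genome_matching total genome-matching read count of the
#'   library (all lengths 18-30 nt), the RPM denominator.
#' @return an object of class `sirna_track`: a table of normalized read
#'   masses (chrom, start, length, strand, rpm) plus the total.
#' @export
normalize_rpm <- function(weighted, total_genome_matching) {
  if (!isTRUE(total_genome_matching > 0))
    stop("total_genome_matching must be positive")
  stopifnot("weight" %in% names(weighted))
  reads <- data.frame(chrom = weighted$chrom,
                      start = weighted$start,
                      length = weighted$length,
                      strand = weighted$strand,
                      rpm = weighted$count * weighted$weight * 1e6 /
                        total_genome_matching,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads,
                 total_genome_matching = total_genome_matching),
            class = "sirna_track")
}

#' @export
print.sirna_track <- function(x, ...) {
  cat("sirna_track:", nrow(x$reads), "assigned candidates,",
      format(x$total_genome_matching, big.mark = ","),
      "genome-matching reads\n")
  invisible(x)
}

#' Per-TE siRNA quantification
#'
#' Sums the normalized read mass whose alignment start lies within each TE
#' interval (0-based half-open), restricted to a read-length class: `c(24,
#' 24)` for mature 24-nt siRNAs, `c(25, 30)` for precursor-length reads. A
#' read starting inside two overlapping TEs counts for both.
#'
#' @param track a `sirna_track` from [normalize_rpm()].
#' @param annotation TE annotation data.frame (chrom, start, end, te_id).
#' @param size_range inclusive read-length bounds within 18-30 nt.
#' @return named numeric vector of RPM per `te_id` (zero where no reads).
#' @export
quantify_te <- function(track, annotation, size_range = c(24, 24)) {
  stopifnot(inherits(track, "sirna_track"))
  if (size_range[1] > size_range[2]) stop("inverted size range")
  if (size_range[1] < 18 || size_range[2] > 30)
    stop("size range must lie within [18, 30]")
  out <- stats::setNames(numeric(nrow(annotation)), annotation$te_id)
  r <- track$reads
  r <- r[r$length >= size_range[1] & r$length <= size_range[2], , drop = FALSE]
  if (!nrow(r) || !nrow(annotation)) return(out)
  # disjoint chromosome sets are a legitimate zero-overlap case
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(start = r$start + 1L, width = 1L)),
    GenomicRanges::GRanges(annotation$chrom,
                           IRanges::IRanges(start = annotation$start + 1L,
                                            end = annotation$end))))
  if (length(hits)) {
    sums <- rowsum(r$rpm[S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits))
    out[as.integer(rownames(sums))] <- sums[, 1L]
  }
  out
}

#' First-base composition of reads of a given length
#'
#' Count-weighted nucleotide fractions at the 5' base of all reads of the
#' requested length (each read counted once, regardless of how many candidate
#' loci it reports).
#'
#' @param alignments long-format alignment table.
#' @param length read length in nt (18-30).
#' @return named fractions over A, C, G, T summing to 1, or an empty numeric
#'   vector when no read of that length exists.
#' @export
first_base_composition <- function(alignments, length = 24L) {
  if (length < 18 || length > 30) stop("length must lie within [18, 30]")
  first <- alignments[alignments$cand_idx == 1L & alignments$length == length, ,
                      drop = FALSE]
  if (!nrow(first)) return(stats::setNames(numeric(0), character(0)))
  tab <- rowsum(as.numeric(first$count), factor(first$first_base,
                                                levels = c("A", "C", "G", "T")))
  frac <- tab[, 1L] / sum(tab[, 1L])
  stats::setNames(frac, rownames(tab))
}
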