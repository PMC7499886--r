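# Read-length distributions (18-30 nt). TE-derived small RNAs are strongly
# 24-nt modal; the non-TE background is broader with minor 21/24-nt peaks.
TE_LEN_PROBS <- stats::setNames(
  c(0.01, 0.01, 0.02, 0.03, 0.05, 0.08, 0.60, 0.08, 0.04, 0.03, 0.02, 0.02, 0.01),
  18:30)
BG_LEN_PROBS <- stats::setNames(
  c(0.05, 0.05, 0.06, 0.20, 0.08, 0.07, 0.15, 0.06, 0.06, 0.06, 0.06, 0.05, 0.05),
  18:30)

sample_first_base <- function(lengths) {
  # adenosine is the dominant first base of 24-nt small RNAs
  n <- length(lengths)
  fb <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is24 <- lengths == 24L
  fb[is24] <- sample(c("A", "C", "G", "T"), sum(is24), replace = TRUE,
                     prob = c(0.55, 0.13, 0.12, 0.20))
  fb
}

# sample n start positions uniformly from the complement of TE intervals
sample_background_starts <- function(n, ann, config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  gaps <- do.call(rbind, lapply(chroms, function(ch) {
    occ <- ann[ann$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = occ$start + 1L, end = occ$end)
    g <- IRanges::gaps(IRanges::reduce(ir), start = 1L,
                       end = config$chrom_length)
    if (!length(g)) return(NULL)
    data.frame(chrom = ch, start0 = IRanges::start(g) - 1L,
               width = IRanges::width(g))
  }))
  if (is.null(gaps) || !nrow(gaps)) stop("no TE-free sequence to place background reads")
  idx <- sample.int(nrow(gaps), n, replace = TRUE, prob = gaps$width)
  off <- floor(stats::runif(n) * gaps$width[idx])
  data.frame(chrom = gaps$chrom[idx], start = gaps$start0[idx] + as.integer(off))
}

#' Simulate one stage- and replicate-specific small RNA library
#'
#' Draws per-TE 24-nt-modal read counts from a negative binomial whose mean
#' follows the class-specific stage template (scaled by TE length), fills the
#' remainder of the library with non-TE background reads so that the library
#' totals exactly `reads_per_library` genome-matching reads, and equips a
#' configured fraction of TE reads with multiple candidate loci drawn from
#' other TEs of the same family (the true origin is recorded in the returned
#' ground truth).
#'
#' @param genome a [generate_genome()] result.
#' @param stage stage label, one of `config$stages`.
#' @param replicate replicate index (1-based).
#' @param config a [sim_config()]; defaults to the genome's own.
#' @return a list of class `sirna_library`: `alignments` is a long-format
#'   data.frame with one row per candidate locus (columns read_id, length,
#'   first_base, count, chrom, start, strand, cand_idx, n_cand; start is
#'   0-based) and `origin` maps each read to its true locus and source TE
#'   (`NA` TE for background reads).
#' @export
simulate_sirna_reads <- function(genome, stage, replicate = 1L,
                                 config = genome$config) {
  validate_sim_config(config)
  if (!stage %in% config$stages)
    stop("unknown stage label: ", stage)
  set.seed(derive_seed(config$seed, "sirna", stage, replicate))
  ann <- genome$annotation
  tmpl <- sirna_templates(config$stages)

  # per-TE expected counts and NB draws
  if (nrow(ann)) {
    mu <- tmpl[ann$class, stage] * (ann$end - ann$start) / 1000
    counts <- stats::rnbinom(nrow(ann), mu = mu, size = 1 / config$nb_dispersion)
  } else counts <- integer()
  total_te <- sum(counts)
  if (total_te > config$reads_per_library)
    stop("simulated TE reads (", total_te, ") exceed reads_per_library; ",
         "increase reads_per_library or lower template amplitudes")
  n_bg <- config$reads_per_library - total_te

  # TE-derived reads
  te_idx <- rep(seq_len(nrow(ann)), counts)
  n_te <- length(te_idx)
  te_len <- sample(as.integer(names(TE_LEN_PROBS)), n_te, replace = TRUE,
                   prob = TE_LEN_PROBS)
  te_width <- (ann$end - ann$start)[te_idx]
  te_len <- pmin(te_len, te_width)
  te_start <- ann$start[te_idx] +
    as.integer(floor(stats::runif(n_te) * (te_width - te_len + 1)))
  te_chrom <- ann$chrom[te_idx]
  te_strand <- sample(c("+", "-"), n_te, replace = TRUE)

  # background reads (outside TEs)
  bg <- if (n_bg > 0) sample_background_starts(n_bg, ann, config) else
    data.frame(chrom = character(), start = integer())
  bg_len <- sample(as.integer(names(BG_LEN_PROBS)), n_bg, replace = TRUE,
                   prob = BG_LEN_PROBS)
  bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)

  n_reads <- n_te + n_bg
  read_id <- sprintf("%s_r%d_%07d", stage, replicate, seq_len(n_reads))
  lens <- c(te_len, bg_len)
  origin <- data.frame(
    read_id = read_id,
    te_id = c(ann$te_id[te_idx], rep(NA_character_, n_bg)),
    chrom = c(te_chrom, bg$chrom),
    start = c(te_start, bg$start),
    stringsAsFactors = FALSE)

  # multimapping: a fraction of TE reads reports decoy loci from same-family TEs
  is_mm <- c(stats::runif(n_te) < config$frac_multimapping, rep(FALSE, n_bg))
  # candidate decoys come from same-family, same-class TEs: the simulated
  # "repeat family" whose copies have near-identical flanks
  fam_of <- paste(ann$family, ann$class)[te_idx]
  fam_tab <- split(seq_len(nrow(ann)), paste(ann$family, ann$class))
  n_decoy <- config$multimap_family_size - 1L

  cand <- data.frame(row = seq_len(n_reads),
                     chrom = origin$chrom, start = origin$start,
                     strand = c(te_strand, bg_strand),
                     stringsAsFactors = FALSE)
  extra <- vector("list", 1L)
  if (any(is_mm)) {
    mm_rows <- which(is_mm)
    ex_row <- integer(0); ex_chrom <- character(0)
    ex_start <- integer(0); ex_strand <- character(0)
    for (r in mm_rows) {
      pool <- setdiff(fam_tab[[fam_of[r]]], te_idx[r])
      pool <- pool[(ann$end - ann$start)[pool] >= lens[r]]
      if (!length(pool)) next
      dec <- sample(rep(pool, length.out = max(length(pool), n_decoy)), n_decoy)
      w <- (ann$end - ann$start)[dec] - lens[r]
      s <- ann$start[dec] + as.integer(floor(stats::runif(n_decoy) * (w + 1)))
      ex_row <- c(ex_row, rep(r, n_decoy))
      ex_chrom <- c(ex_chrom, ann$chrom[dec])
      ex_start <- c(ex_start, s)
      ex_strand <- c(ex_strand, sample(c("+", "-"), n_decoy, replace = TRUE))
    }
    extra[[1]] <- data.frame(row = ex_row, chrom = ex_chrom, start = ex_start,
                             strand = ex_strand, stringsAsFactors = FALSE)
  }
  cand <- rbind(cand, extra[[1]])
  cand <- cand[order(cand$row), , drop = FALSE]

  n_cand_per_read <- tabulate(cand$row, nbins = n_reads)
  alignments <- data.frame(
    read_id = read_id[cand$row],
    length = lens[cand$row],
    first_base = sample_first_base(lens)[cand$row],
    count = 1L,
    chrom = cand$chrom,
    start = cand$start,
    strand = cand$strand,
    n_cand = n_cand_per_read[cand$row],
    stringsAsFactors = FALSE)
  alignments$cand_idx <- sequence(rle(cand$row)$lengths)
  rownames(alignments) <- NULL

  structure(list(alignments = alignments, origin = origin,
                 stage = stage, replicate = as.integer(replicate)),
            class = "sirna_library")
}
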