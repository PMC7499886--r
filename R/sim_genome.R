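# Seed streams: each generator draws from a stream derived from the master
# seed plus a label, so generators are independently reproducible and adding a
# stage/replicate never perturbs the others.
derive_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) %% 7919L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

random_sequence <- function(n) {
  # Arabidopsis-like base composition (~36% GC)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
}

#' Generate a miniature annotated genome with known TE classes
#'
#' Places non-overlapping TE intervals of three latent classes on random
#' nucleotide sequences. Class-B (heterochromatic) TEs are drawn longer and
#' concentrated in a pericentromeric window around each chromosome midpoint;
#' class-A and siRNA-depleted TEs are dispersed. The returned ground truth
#' records every TE's latent class, the planted DMR intervals with their
#' per-stage true CHH levels, and the nucleosome archetype of each long
#' class-B TE. An unmethylated control contig (`ctrl`) is emitted alongside
#' the chromosomes for conversion-rate estimation.
#'
#' @param config a [sim_config()].
#' @return a list of class `te_genome` with elements `annotation` (data.frame:
#'   chrom, start, end, te_id, score, strand, family, class; 0-based
#'   half-open), `sequences` (named character, one string per chromosome plus
#'   `ctrl`), `truth` (list: `te_class`, `dmr_truth`, `nucleosome_archetype`),
#'   and `config`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sequences <- stats::setNames(
    c(vapply(chroms, function(ch) random_sequence(config$chrom_length), ""),
      random_sequence(config$control_length)),
    c(chroms, "ctrl"))

  counts <- config$n_te_per_class[c("A", "B", "depleted")]
  n_total <- sum(counts)
  if (n_total == 0L) {
    ann <- data.frame(chrom = character(), start = integer(), end = integer(),
                      te_id = character(), score = integer(),
                      strand = character(), family = character(),
                      class = character(), stringsAsFactors = FALSE)
    truth <- list(te_class = stats::setNames(character(), character()),
                  dmr_truth = empty_dmr_truth(config$stages),
                  nucleosome_archetype = stats::setNames(integer(), character()))
    return(structure(list(annotation = ann, sequences = sequences,
                          truth = truth, config = config),
                     class = "te_genome"))
  }

  cls <- rep(c("A", "B", "depleted"), counts)
  lens <- integer(n_total)
  for (k in c("A", "B", "depleted")) {
    p <- config$length_params[[k]]
    idx <- which(cls == k)
    lens[idx] <- pmax(50L, as.integer(round(
      stats::rlnorm(length(idx), meanlog = log(p[["median"]]),
                    sdlog = p[["sdlog"]]))))
  }
  genome_bp <- config$n_chromosomes * as.numeric(config$chrom_length)
  if (sum(as.numeric(lens)) > genome_bp)
    stop("infeasible packing: total TE length (", sum(as.numeric(lens)),
         " bp) exceeds genome size (", genome_bp, " bp)")

  # sequential rejection placement; class B targets the centromeric window
  mid <- config$chrom_length / 2
  half <- config$centromere_half_width
  occupied <- lapply(chroms, function(ch) IRanges::IRanges())
  names(occupied) <- chroms
  start <- integer(n_total); chrom <- character(n_total)
  ord <- order(-lens)   # place long TEs first so packing succeeds
  for (i in ord) {
    L <- lens[i]
    placed <- FALSE
    for (try in seq_len(2000L)) {
      ch <- sample(chroms, 1L)
      if (cls[i] == "B" && stats::runif(1) < 0.85) {
        lo <- max(0, mid - half); hi <- min(config$chrom_length - L, mid + half - L)
        if (hi < lo) next
        s <- as.integer(floor(stats::runif(1, lo, hi + 1)))
      } else {
        s <- as.integer(floor(stats::runif(1, 0, config$chrom_length - L + 1)))
      }
      cand <- IRanges::IRanges(start = s + 1L, end = s + L)
      if (length(IRanges::findOverlaps(cand, occupied[[ch]])) == 0L) {
        occupied[[ch]] <- c(occupied[[ch]], cand)
        start[i] <- s; chrom[i] <- ch
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible packing: could not place a ", L,
           " bp TE without overlap after 2000 attempts")
  }

  te_id <- sprintf("TE%04d", seq_len(n_total))
  family <- character(n_total)
  for (k in c("A", "B", "depleted")) {
    idx <- which(cls == k)
    pr <- te_family_probs(k)
    family[idx] <- sample(names(pr), length(idx), replace = TRUE, prob = pr)
  }
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  ann <- data.frame(chrom = chrom, start = start, end = start + lens,
                    te_id = te_id, score = 0L, strand = strand,
                    family = family, class = cls, stringsAsFactors = FALSE)
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL

  truth <- list(
    te_class = stats::setNames(ann$class, ann$te_id),
    dmr_truth = plant_dmrs(ann, config),
    nucleosome_archetype = assign_archetypes(ann, config))
  structure(list(annotation = ann, sequences = sequences, truth = truth,
                 config = config), class = "te_genome")
}

empty_dmr_truth <- function(stages) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    te_id = character(), stringsAsFactors = FALSE)
  for (s in stages) out[[paste0("chh_", s)]] <- numeric()
  out
}

plant_dmrs <- function(ann, config) {
  eligible <- ann[ann$class != "depleted" &
                    (ann$end - ann$start) >= config$dmr_length, , drop = FALSE]
  n <- min(config$n_dmr, nrow(eligible))
  if (n == 0L) return(empty_dmr_truth(config$stages))
  pick <- eligible[sample(nrow(eligible), n), , drop = FALSE]
  mid <- floor((pick$start + pick$end) / 2)
  start <- pmax(pick$start, mid - floor(config$dmr_length / 2))
  out <- data.frame(chrom = pick$chrom, start = as.integer(start),
                    end = as.integer(start + config$dmr_length),
                    te_id = pick$te_id, stringsAsFactors = FALSE)
  ramp <- dmr_stage_ramp(config$stages)
  base <- config$meth_baseline[["CHH"]]
  for (s in config$stages)
    out[[paste0("chh_", s)]] <- pmin(1, base + config$dmr_effect * ramp[[s]])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

assign_archetypes <- function(ann, config, long_cutoff = 2114L) {
  long_b <- ann$te_id[ann$class == "B" & (ann$end - ann$start) > long_cutoff]
  if (!length(long_b)) return(stats::setNames(integer(), character()))
  arch <- sample(1:3, length(long_b), replace = TRUE,
                 prob = c(0.567, 0.331, 0.102))
  stats::setNames(arch, long_b)
}
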