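#' Simulation configuration
#'
#' Builds the configuration object consumed by all synthetic-data generators.
#' The defaults define a miniature two-chromosome genome carrying three latent
#' TE populations -- euchromatic "class A" TEs whose 24-nt siRNAs rise sharply
#' at embryo maturation, heterochromatic "class B" TEs with an early-embryonic
#' siRNA burst that collapses at maturity, and siRNA-depleted TEs -- together
#' with stage-ramped CHH hypermethylation planted at known DMR intervals and
#' three nucleosome-occupancy archetypes over long class-B TEs.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param centromere_half_width half-width (bp) of the pericentromeric window
#'   around each chromosome midpoint into which class-B TEs are concentrated.
#' @param n_te_per_class named counts for classes `A`, `B` and `depleted`.
#' @param length_params per-class log-normal length parameters, a named list
#'   of `c(median, sdlog)` in bp. Class B is longer than class A by default,
#'   matching the heterochromatic/euchromatic length asymmetry.
#' @param stages ordered sample labels. Defaults to floral bud (fb),
#'   preglobular (pg), globular (gl), early heart (eh), late heart (lh),
#'   early torpedo (et), late torpedo (lt), bent cotyledon (bc), mature green
#'   (mg) and leaf (lf).
#' @param n_replicates biological replicates per stage.
#' @param reads_per_library total genome-matching reads per simulated library;
#'   every library sums to exactly this count.
#' @param nb_dispersion negative-binomial overdispersion of per-TE counts
#'   (`size = 1/nb_dispersion`).
#' @param multimap_family_size number of candidate loci reported for a
#'   multi-mapping read.
#' @param frac_multimapping proportion of TE-derived reads that report
#'   `multimap_family_size` candidate loci.
#' @param meth_baseline named per-context baseline methylation rates
#'   (`CG`, `CHG`, `CHH`).
#' @param dmr_effect CHH methylation gain (proportion, not percent) planted at
#'   DMR intervals, scaled by the per-stage ramp.
#' @param n_dmr,dmr_length number and width (bp) of planted DMR intervals.
#' @param coverage_per_cytosine mean (Poisson) read depth per cytosine of the
#'   pooled per-stage methylome.
#' @param conversion_error bisulfite non-conversion rate: probability that an
#'   unmethylated cytosine is read as methylated.
#' @param control_length length (bp) of the unmethylated control contig
#'   (chloroplast/Lambda spike-in analogue) used for conversion-rate
#'   estimation.
#' @param te_read_share not used directly; templates are absolute reads/kb.
#' @param seed integer seed; identical configurations (including seed) yield
#'   byte-identical generator output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 500000L,
                       centromere_half_width = 75000L,
                       n_te_per_class = c(A = 120L, B = 120L, depleted = 60L),
                       length_params = list(A = c(median = 500, sdlog = 0.45),
                                            B = c(median = 1800, sdlog = 0.55),
                                            depleted = c(median = 450, sdlog = 0.45)),
                       stages = c("fb", "pg", "gl", "eh", "lh",
                                  "et", "lt", "bc", "mg", "lf"),
                       n_replicates = 3L,
                       reads_per_library = 100000L,
                       nb_dispersion = 0.2,
                       multimap_family_size = 3L,
                       frac_multimapping = 0.3,
                       meth_baseline = c(CG = 0.24, CHG = 0.09, CHH = 0.02),
                       dmr_effect = 0.4,
                       n_dmr = 40L,
                       dmr_length = 200L,
                       coverage_per_cytosine = 20,
                       conversion_error = 0.005,
                       control_length = 10000L,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              centromere_half_width = as.integer(centromere_half_width),
              n_te_per_class = n_te_per_class,
              length_params = length_params,
              stages = stages,
              n_replicates = as.integer(n_replicates),
              reads_per_library = as.integer(reads_per_library),
              nb_dispersion = nb_dispersion,
              multimap_family_size = as.integer(multimap_family_size),
              frac_multimapping = frac_multimapping,
              meth_baseline = meth_baseline,
              dmr_effect = dmr_effect,
              n_dmr = as.integer(n_dmr),
              dmr_length = as.integer(dmr_length),
              coverage_per_cytosine = coverage_per_cytosine,
              conversion_error = conversion_error,
              control_length = as.integer(control_length),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L,
            cfg$chrom_length >= 1L,
            cfg$centromere_half_width >= 1L,
            all(c("A", "B", "depleted") %in% names(cfg$n_te_per_class)),
            all(cfg$n_te_per_class >= 0L),
            all(vapply(cfg$length_params, function(p) all(p > 0), logical(1))),
            length(cfg$stages) >= 2L, !anyDuplicated(cfg$stages),
            cfg$n_replicates >= 1L,
            cfg$reads_per_library >= 1L,
            cfg$nb_dispersion > 0,
            cfg$multimap_family_size >= 2L,
            cfg$frac_multimapping >= 0, cfg$frac_multimapping <= 1,
            all(cfg$meth_baseline >= 0), all(cfg$meth_baseline <= 1),
            cfg$dmr_effect >= 0, cfg$dmr_effect <= 1,
            cfg$n_dmr >= 0L, cfg$dmr_length >= 1L,
            cfg$coverage_per_cytosine >= 0,
            cfg$conversion_error >= 0, cfg$conversion_error < 1,
            cfg$control_length >= 100L,
            is.finite(cfg$seed))
  invisible(cfg)
}

#' Stage templates of expected 24-nt siRNA output
#'
#' Expected 24-nt read yield per kb of TE per library, by latent class and
#' stage. Class A is low in early embryos, rises sharply at the mature green
#' stage and stays high in leaves and floral buds; class B is already high at
#' preglobular, peaks in mid-embryogenesis and collapses at maturity; the
#' depleted class emits essentially nothing. Shapes are fixed; amplitudes are
#' generator conventions (no empirical profile exists to copy).
#'
#' @param stages ordered stage labels (default the ten standard samples).
#' @return a 3 x length(stages) numeric matrix with rows `A`, `B`, `depleted`.
#' @export
sirna_templates <- function(stages = c("fb", "pg", "gl", "eh", "lh",
                                       "et", "lt", "bc", "mg", "lf")) {
  full <- rbind(
    A        = c(fb = 40, pg = 3,  gl = 10, eh = 11, lh = 12,
                 et = 13, lt = 14, bc = 16, mg = 45, lf = 42),
    B        = c(fb = 2,  pg = 45, gl = 55, eh = 65, lh = 75,
                 et = 85, lt = 70, bc = 30, mg = 2.5, lf = 2),
    depleted = c(fb = 0.05, pg = 0.05, gl = 0.05, eh = 0.05, lh = 0.05,
                 et = 0.05, lt = 0.05, bc = 0.05, mg = 0.05, lf = 0.05))
  missing <- setdiff(stages, colnames(full))
  if (length(missing))
    stop("no siRNA template defined for stage(s): ",
         paste(missing, collapse = ", "))
  full[, stages, drop = FALSE]
}

#' Per-stage CHH methylation ramp at planted DMRs
#'
#' Fraction of the full `dmr_effect` realised at each stage: hypomethylated at
#' preglobular, progressively methylated until embryo maturation, and low
#' again in post-embryonic leaves and floral buds.
#'
#' @param stages stage labels.
#' @return named numeric vector in `[0, 1]`.
#' @export
dmr_stage_ramp <- function(stages = c("fb", "pg", "gl", "eh", "lh",
                                      "et", "lt", "bc", "mg", "lf")) {
  full <- c(fb = 0.15, pg = 0, gl = 0.1, eh = 0.25, lh = 0.4,
            et = 0.5, lt = 0.65, bc = 0.75, mg = 1, lf = 0.2)
  missing <- setdiff(stages, names(full))
  if (length(missing))
    stop("no DMR ramp defined for stage(s): ", paste(missing, collapse = ", "))
  full[stages]
}

# TE family labels with class-skewed frequencies: heterochromatic class B is
# dominated by Gypsy/MuDR/En-Spm, euchromatic class A by the remainder.
te_family_probs <- function(class) {
  fam <- c("Gypsy", "Copia", "MuDR", "En-Spm", "LINE", "SINE", "Helitron", "HAT")
  p <- switch(class,
              A        = c(0.05, 0.15, 0.10, 0.05, 0.15, 0.15, 0.20, 0.15),
              B        = c(0.40, 0.15, 0.20, 0.15, 0.05, 0.01, 0.03, 0.01),
              depleted = c(0.10, 0.10, 0.10, 0.10, 0.15, 0.15, 0.20, 0.10))
  stats::setNames(p, fam)
}
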