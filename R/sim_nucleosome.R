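#' Simulate a nucleosome-occupancy track
#'
#' Produces a smooth noisy per-base occupancy signal in which long class-B
#' TEs follow one of three archetypes recorded in the ground truth: archetype
#' 1 has high occupancy over edges and body, archetype 2 has low edges but a
#' high body, and archetype 3 is low throughout. All other TEs sit at an
#' intermediate level and the TE-free background is low.
#'
#' @param genome a [generate_genome()] result.
#' @param config a [sim_config()]; defaults to the genome's own.
#' @param noise_sd standard deviation of the smoothed Gaussian noise added to
#'   the archetype means; `0` gives noiseless archetype profiles.
#' @param edge_width bp treated as "edge" at each end of an archetyped TE
#'   (capped at 20% of TE length).
#' @return a [signal_track()] over the chromosomes (control contig excluded).
#' @export
simulate_nucleosome_signal <- function(genome, config = genome$config,
                                       noise_sd = 0.08, edge_width = 300L) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "nucleosome"))
  arch <- genome$truth$nucleosome_archetype
  ann <- genome$annotation
  chroms <- setdiff(names(genome$sequences), "ctrl")
  levels_body <- c(1.0, 1.0, 0.1)
  levels_edge <- c(1.0, 0.2, 0.1)

  values <- lapply(chroms, function(ch) {
    v <- rep(0.3, config$chrom_length)
    a <- ann[ann$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      s <- a$start[i] + 1L; e <- a$end[i]
      id <- a$te_id[i]
      if (id %in% names(arch)) {
        k <- arch[[id]]
        ew <- min(as.integer(edge_width), as.integer(floor((e - s + 1L) * 0.2)))
        v[s:e] <- levels_body[k]
        if (ew > 0L) {
          v[s:(s + ew - 1L)] <- levels_edge[k]
          v[(e - ew + 1L):e] <- levels_edge[k]
        }
      } else {
        v[s:e] <- 0.5
      }
    }
    if (noise_sd > 0) {
      eps <- stats::rnorm(length(v), 0, noise_sd)
      sm <- stats::filter(eps, rep(1 / 51, 51), sides = 2)
      sm[is.na(sm)] <- 0
      # smoothing shrinks the marginal sd; rescale so noise_sd is as stated
      sdf <- stats::sd(as.numeric(sm))
      if (sdf > 0) sm <- sm * (noise_sd / sdf)
      v <- pmax(0, v + as.numeric(sm))
    }
    v
  })
  names(values) <- chroms
  signal_track(values)
}
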