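# small configurations used across tests; the full default configuration is
# exercised in test-acceptance.R only, to keep the unit tests fast

tiny_config <- function(seed = 1L, ...) {
  args <- list(n_chromosomes = 1L, chrom_length = 60000L,
               centromere_half_width = 12000L,
               n_te_per_class = c(A = 12L, B = 12L, depleted = 6L),
               reads_per_library = 20000L, n_dmr = 6L, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_config <- function(seed = 1L, ...) {
  args <- list(n_chromosomes = 1L, chrom_length = 120000L,
               centromere_half_width = 25000L,
               n_te_per_class = c(A = 25L, B = 25L, depleted = 12L),
               reads_per_library = 40000L, n_dmr = 10L, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# memoised tiny genome + libraries, shared by read-level tests
.fixture_env <- new.env(parent = emptyenv())

tiny_genome <- function() {
  if (is.null(.fixture_env$genome))
    .fixture_env$genome <- generate_genome(tiny_config(seed = 4L))
  .fixture_env$genome
}

# genome rich in long class-B TEs so that all three nucleosome archetypes
# are well represented
nuc_genome <- function() {
  if (is.null(.fixture_env$nuc_genome)) {
    cfg <- sim_config(n_chromosomes = 1L, chrom_length = 300000L,
                      centromere_half_width = 90000L,
                      n_te_per_class = c(A = 15L, B = 40L, depleted = 5L),
                      length_params = list(A = c(median = 500, sdlog = 0.45),
                                           B = c(median = 3200, sdlog = 0.3),
                                           depleted = c(median = 450, sdlog = 0.45)),
                      reads_per_library = 20000L, seed = 14L)
    .fixture_env$nuc_genome <- generate_genome(cfg)
  }
  .fixture_env$nuc_genome
}

tiny_library <- function(stage = "lh") {
  key <- paste0("lib_", stage)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_sirna_reads(tiny_genome(), stage, 1L)
  .fixture_env[[key]]
}

# EM log-likelihood monotonicity, ignoring the steps where a starved
# component was re-seeded (a re-seed may legitimately lower the objective)
loglik_monotone <- function(model, tol = 1e-6) {
  d <- diff(model$loglik_trace)
  skip <- model$reinit_iters - 1L
  d <- d[setdiff(seq_along(d), skip)]
  !length(d) || all(d > -tol * (abs(model$loglik) + 1))
}

# one hand-built read (possibly multi-mapping) in long format; 0-based starts
aln <- function(read_id, starts, chrom = "chr1", length = 24L, count = 1L,
                strand = "+", first_base = "A") {
  data.frame(read_id = read_id, length = length, first_base = first_base,
             count = count, chrom = chrom, start = as.integer(starts),
             strand = strand, n_cand = length(starts),
             cand_idx = seq_along(starts), stringsAsFactors = FALSE)
}
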