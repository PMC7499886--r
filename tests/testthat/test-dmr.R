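# exact version of the Monte-Carlo null: enumerate all count tables with the
# observed coverages under the pooled binomial null and sum the probability
# of statistics at least as extreme
rms_enum_p <- function(mc, cov) {
  p_hat <- sum(mc) / sum(cov)
  obs <- temdyn:::rms_stat(matrix(mc, 1L), cov)
  grid <- expand.grid(lapply(cov, function(c) 0:c))
  probs <- rowSums(vapply(seq_along(cov), function(s)
    dbinom(grid[[s]], cov[s], p_hat, log = TRUE), numeric(nrow(grid))))
  stats <- temdyn:::rms_stat(as.matrix(grid), cov)
  sum(exp(probs)[stats >= obs - 1e-12])
}

test_that("identical proportions give statistic 0 and p = 1", {
  r <- rms_test(c(5, 5), c(10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("sample order does not affect the RMS test", {
  r1 <- rms_test(c(2, 9, 4), c(10, 12, 8), n_sim = 2000L, seed = 3L)
  r2 <- rms_test(c(9, 4, 2), c(12, 8, 10), n_sim = 2000L, seed = 3L)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Monte-Carlo p-values match exhaustive enumeration on small tables", {
  cases <- list(list(mc = c(10, 0), cov = c(10, 10)),
                list(mc = c(8, 2), cov = c(10, 10)),
                list(mc = c(5, 9), cov = c(12, 14)))
  for (cs in cases) {
    exact <- rms_enum_p(cs$mc, cs$cov)
    mc_p <- rms_test(cs$mc, cs$cov, n_sim = 1e5L, seed = 2L)$p_value
    expect_equal(mc_p, exact, tolerance = 0.01)
  }
  # the fully polarized table is decisively significant
  expect_lt(rms_test(c(10, 0), c(10, 10), n_sim = 9999L, seed = 1L)$p_value,
            0.01)
})

test_that("null RMS p-values are conservative (super-uniform) at small counts", {
  set.seed(99)
  n <- 300L
  p <- vapply(seq_len(n), function(i) {
    mc <- rbinom(2L, 8L, 0.2)
    rms_test(mc, c(8L, 8L), n_sim = 400L, seed = i)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(p <= alpha), alpha + 0.03)
})

test_that("coverage filtering precedes testing and respects per-sample rules", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+",
                      context = "CHH", subcontext = "CWA", trinuc = "CAA",
                      stringsAsFactors = FALSE)
  pg <- cbind(sites, mc = c(0L, 0L, 1L), cov = c(3L, 2L, 10L))
  mg <- cbind(sites, mc = c(5L, 5L, 9L), cov = c(5L, 5L, 10L))
  cmp <- build_comparison(list(pg = pg, mg = mg))
  dms <- call_dms(cmp, n_sim = 2000L, seed = 1L)
  tested <- attr(dms, "tested")
  # pos 20 fails the preglobular >= 3 rule; pos 10 passes it (cov 3)
  expect_setequal(tested$pos, c(10L, 30L))
  strict <- call_dms(cmp, min_cov = 4L, n_sim = 500L, seed = 1L)
  expect_equal(attr(strict, "tested")$pos, 30L)
})

test_that("an empty comparison yields an empty DMS table", {
  sites <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      subcontext = character(), trinuc = character(),
                      mc = integer(), cov = integer())
  cmp <- build_comparison(list(pg = sites, mg = sites))
  dms <- call_dms(cmp)
  expect_equal(nrow(dms), 0L)
})

test_that("DMS chaining follows the 100-bp single-linkage rule", {
  dms <- data.frame(chrom = "chr1", pos = c(100L, 150L, 260L))
  r <- collapse_dmrs(dms)
  expect_equal(r$start, c(99L, 259L))
  expect_equal(r$end, c(150L, 260L))
  expect_equal(r$n_dms, c(2L, 1L))

  single <- collapse_dmrs(data.frame(chrom = "chr2", pos = 500L))
  expect_equal(c(single$start, single$end), c(499L, 500L))

  chain <- collapse_dmrs(data.frame(chrom = "chr1", pos = c(0L, 90L, 180L) + 1L))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$n_dms, 3L)
})

test_that("DMR filters discard small or weak regions", {
  pos_a <- seq(1000L, 1100L, by = 20L)   # 6 sites
  pos_b <- seq(5000L, 5040L, by = 20L)   # 3 sites
  sites <- data.frame(chrom = "chr1", pos = c(pos_a, pos_b), strand = "+",
                      context = "CHH", subcontext = "CWA", trinuc = "CAA",
                      stringsAsFactors = FALSE)
  lo <- cbind(sites, mc = 2L, cov = 20L)    # 10%
  hi <- cbind(sites, mc = 7L, cov = 20L)    # 35%
  cmp <- build_comparison(list(s1 = lo, s2 = hi))
  regions <- collapse_dmrs(data.frame(chrom = "chr1", pos = c(pos_a, pos_b)))
  kept <- filter_dmrs(regions, cmp)
  # the 3-DMS region is discarded; the 6-DMS 25-pp region is kept
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_dms, 6L)
  expect_gte(kept$max_difference, 20)

  weak <- cbind(sites, mc = 5L, cov = 20L)  # 25%: 15 pp from lo
  cmp2 <- build_comparison(list(s1 = lo, s2 = weak))
  expect_equal(nrow(filter_dmrs(regions, cmp2)), 0L)
})

test_that("pairwise enumeration and merging follow bedtools semantics", {
  expect_equal(nrow(stage_pairs(c("pg", "eh", "et", "bc", "mg"))), 10L)
  m <- merge_pairwise_dmrs(list(
    data.frame(chrom = "chr1", start = 0L, end = 100L),
    data.frame(chrom = "chr1", start = 50L, end = 150L),
    data.frame(chrom = "chr2", start = 0L, end = 10L)))
  expect_equal(m$start, c(0L, 0L))
  expect_equal(m$end, c(150L, 10L))
  solo <- merge_pairwise_dmrs(list(
    data.frame(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L))))
  expect_equal(nrow(solo), 2L)
})

test_that("reported DMRs satisfy their filter invariants by construction", {
  g <- tiny_genome()
  dmrs <- call_dmrs(list(pg = simulate_methylome(g, "pg"),
                         mg = simulate_methylome(g, "mg")),
                    n_sim = 2000L, n_sim_max = 20000L, seed = 5L)
  if (nrow(dmrs)) {
    expect_true(all(dmrs$n_dms >= 4L))
    expect_true(all(dmrs$max_difference >= 20))
    expect_true(all(dmrs$start < dmrs$end))
  }
  st <- dmr_recovery_stats(dmrs, g$truth$dmr_truth)
  expect_gte(st$recall, 0.5)
})
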