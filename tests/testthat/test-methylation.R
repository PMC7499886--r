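test_that("cytosine contexts follow the trinucleotide definitions", {
  seqs <- list(CAA = c("CHH", "CWA"), CAT = c("CHH", "nonCWA"),
               CTA = c("CHH", "CWA"), CCC = c("CHH", "nonCWA"),
               CAG = c("CHG", "n/a"), CTG = c("CHG", "n/a"),
               CGA = c("CG", "n/a"), CGG = c("CG", "n/a"))
  for (tri in names(seqs)) {
    got <- classify_context(paste0(tri, "AAAA"), 1L, "+")
    expect_equal(c(got$context, got$subcontext), seqs[[tri]],
                 info = tri)
    got2 <- trinuc_context(tri)
    expect_equal(c(got2$context, got2$subcontext), seqs[[tri]], info = tri)
  }
})

test_that("minus-strand cytosines are classified from their own strand", {
  # plus-strand "TTG" at 1..3: the G at position 3 is a minus-strand C whose
  # 5'->3' triplet is the reverse complement "CAA" -> CHH/CWA
  got <- classify_context("TTGAA", 3L, "-")
  expect_equal(got$context, "CHH")
  expect_equal(got$subcontext, "CWA")
  expect_equal(got$trinuc, "CAA")
})

test_that("sites too close to the 3' end are undefined", {
  got <- classify_context("ACGTC", c(5L, 4L), "+")
  expect_true(all(is.na(got$context)))
  gotm <- classify_context("CGTAC", 2L, "-")
  expect_true(is.na(gotm$context))
})

test_that("weighted methylation is coverage-weighted, not a mean of ratios", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                      context = "CHH", subcontext = "CWA",
                      mc = c(2L, 3L), cov = c(4L, 6L))
  expect_equal(weighted_methylation(sites), 0.5)
  sites$mc <- sites$cov
  expect_equal(weighted_methylation(sites), 1.0)
  sites$mc <- 0L
  expect_equal(weighted_methylation(sites), 0.0)
  sites$cov <- 0L
  expect_true(is.na(weighted_methylation(sites)))
})

test_that("pooling replicates equals computing on summed counts", {
  set.seed(8)
  n <- 50L
  rep1 <- data.frame(chrom = "chr1", pos = seq_len(n), strand = "+",
                     context = "CHH", subcontext = "nonCWA",
                     mc = rbinom(n, 10, 0.3), cov = 10L)
  rep2 <- rep1; rep2$cov <- 14L; rep2$mc <- rbinom(n, 14, 0.3)
  pooled <- rep1
  pooled$mc <- rep1$mc + rep2$mc
  pooled$cov <- rep1$cov + rep2$cov
  expect_equal(weighted_methylation(pooled),
               sum(rep1$mc + rep2$mc) / sum(rep1$cov + rep2$cov))
  # splitting arbitrarily leaves the combined rate unchanged
  expect_equal(weighted_methylation(rbind(rep1, rep2)),
               weighted_methylation(pooled))
})

test_that("conversion rate is the unmethylated-control complement", {
  ctrl <- data.frame(chrom = "ctrl", pos = 1:2, strand = "+",
                     context = "CHH", subcontext = "CWA",
                     mc = c(1L, 0L), cov = c(500L, 500L))
  expect_equal(conversion_rate(ctrl), 99.9)
  ctrl$mc <- 0L
  expect_equal(conversion_rate(ctrl), 100)
  expect_equal(conversion_rate(ctrl),
               100 - 100 * weighted_methylation(ctrl))
  ctrl$cov <- 0L
  expect_error(conversion_rate(ctrl), "coverage")
})

test_that("simulated methylomes honour effect and depth settings", {
  g <- tiny_genome()
  m_pg <- simulate_methylome(g, "pg")
  m_mg <- simulate_methylome(g, "mg")
  expect_true(all(m_pg$mc <= m_pg$cov))
  # contexts in the table match reclassification from the sequence
  chr <- m_pg[m_pg$chrom == "chr1", ][1:200, ]
  re <- classify_context(g$sequences[["chr1"]], chr$pos, chr$strand)
  expect_equal(chr$context, re$context)
  expect_equal(chr$subcontext, re$subcontext)

  # planted DMRs gain >= 20 pp weighted CHH from pg to mg
  d <- g$truth$dmr_truth[1L, ]
  r_pg <- weighted_methylation(m_pg, c(d$start, d$end), d$chrom, "CHH")
  r_mg <- weighted_methylation(m_mg, c(d$start, d$end), d$chrom, "CHH")
  expect_gte(r_mg - r_pg, 0.20)

  # no planted effect: genome-wide CHH difference below 1 pp
  cfg0 <- tiny_config(seed = 6L, dmr_effect = 0)
  g0 <- generate_genome(cfg0)
  w0 <- weighted_methylation(simulate_methylome(g0, "pg"), context = "CHH")
  w1 <- weighted_methylation(simulate_methylome(g0, "mg"), context = "CHH")
  expect_lt(abs(w1 - w0), 0.01)

  # zero depth yields an empty site list
  cfgz <- tiny_config(seed = 6L, coverage_per_cytosine = 0)
  gz <- generate_genome(cfgz)
  expect_equal(nrow(simulate_methylome(gz, "pg")), 0L)

  # determinism
  expect_identical(simulate_methylome(g, "pg"), m_pg)
})
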