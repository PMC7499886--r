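archetype_profiles <- function(n_per = 15L, bins = 60L, noise = 0) {
  edge <- 10L
  base <- rbind(rep(1, bins),
                c(rep(0.2, edge), rep(1, bins - 2 * edge), rep(0.2, edge)),
                rep(0.1, bins))
  set.seed(12)
  m <- base[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * bins, 0, noise), 3 * n_per, bins)
  rownames(m) <- paste0("TE", seq_len(3 * n_per))
  list(m = m, truth = rep(1:3, each = n_per))
}

test_that("k-means recovers noiseless archetypes exactly, ordered by occupancy", {
  ap <- archetype_profiles()
  g <- kmeans_profiles(ap$m, k = 3L, seed = 2L)
  expect_equal(unname(g$group), ap$truth)
  expect_true(all(diff(rowMeans(g$centers)) < 0))
  expect_error(kmeans_profiles(ap$m[1:2, ], k = 3L), "regions")
})

test_that("k-means recovery degrades gracefully under noise", {
  ap <- archetype_profiles(noise = 0.15)
  g <- kmeans_profiles(ap$m, k = 3L, seed = 2L)
  expect_gte(adjusted_rand_index(g$group, ap$truth), 0.9)
})

test_that("heterochromatic/euchromatic enrichment follows its definition", {
  ann <- data.frame(chrom = "chr1", start = c(0L, 50000L),
                    end = c(40000L, 90000L), te_id = c("b1", "a1"))
  labels <- data.frame(te_id = c("b1", "a1"), class = c("B", "A"))
  q <- c(b1 = 80, a1 = 40)
  e <- enrichment_het_vs_eu(q, labels, ann)
  expect_equal(e$ratio, 2.0)
  # equal densities give exactly 1; rescaling leaves the ratio unchanged
  expect_equal(enrichment_het_vs_eu(c(b1 = 40, a1 = 40), labels, ann)$ratio, 1)
  expect_equal(enrichment_het_vs_eu(q * 17, labels, ann)$ratio, e$ratio)
  z <- enrichment_het_vs_eu(c(b1 = 10, a1 = 0), labels, ann)
  expect_true(z$undefined && is.na(z$ratio))
})

test_that("preglobular enrichment matches the generator's template expectation", {
  # the length-normalized ratio cancels TE lengths and the 24-nt fraction,
  # so its expectation is the template ratio; at this library size the
  # euchromatic denominator is a few dozen reads, so replicate-averaged
  # ratios are compared on a factor-2 band
  g <- tiny_genome()
  labels <- data.frame(te_id = names(g$truth$te_class),
                       class = unname(g$truth$te_class))
  ratios <- vapply(1:3, function(r) {
    lib <- simulate_sirna_reads(g, "pg", r)
    w <- reassign_multimappers(lib$alignments)
    q <- quantify_te(normalize_rpm(w, sum(w$count[w$cand_idx == 1L])),
                     g$annotation)
    enrichment_het_vs_eu(q, labels, g$annotation)$ratio
  }, numeric(1))
  tmpl <- sirna_templates()
  expected <- tmpl["B", "pg"] / tmpl["A", "pg"]   # length-normalized
  expect_true(all(ratios > 1))
  expect_gt(mean(ratios), expected / 2)
  expect_lt(mean(ratios), expected * 2)
})

test_that("family O/E enrichment reproduces the worked arithmetic", {
  # family f holds 10 of the 20 DMR-overlapping TEs but 25% of all TEs
  ann <- data.frame(chrom = "chr1",
                    start = seq(0L, by = 1000L, length.out = 40L),
                    end = seq(500L, by = 1000L, length.out = 40L),
                    te_id = sprintf("t%02d", 1:40),
                    family = rep(c("f", "g", "h", "i"), each = 10L))
  # DMRs overlap te 1..10 (all f) plus te 11..20 (all g)
  dmrs <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 1000L, length.out = 20L),
                     end = seq(100L, by = 1000L, length.out = 20L))
  fe <- family_enrichment(dmrs, ann)
  f <- fe[fe$family == "f", ]
  expect_equal(f$observed / f$expected, 2)
  expect_equal(f$log2_oe, 1)
  # a family absent from the overlap set gets the sentinel, p still computed
  h <- fe[fe$family == "h", ]
  expect_true(is.na(h$log2_oe))
  expect_true(h$p_value >= 0 && h$p_value <= 1)
})

test_that("Fisher p-values equal hypergeometric tail sums on small tables", {
  # two-sided Fisher = sum of hypergeometric outcomes no more likely than
  # the observed one, enumerated directly
  cases <- list(c(8, 2, 3, 9), c(1, 9, 7, 5), c(4, 4, 4, 4))
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]; c <- cs[3]; d <- cs[4]
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_enum <- sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
    p_fisher <- stats::fisher.test(matrix(cs, 2L))$p.value
    expect_equal(p_fisher, p_enum, tolerance = 1e-9)
  }
})

test_that("an all-TE pseudo-family has O/E exactly 1", {
  ann <- data.frame(chrom = "chr1",
                    start = c(0L, 1000L, 2000L), end = c(500L, 1500L, 2500L),
                    te_id = c("x", "y", "z"), family = "all")
  dmrs <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  fe <- family_enrichment(dmrs, ann)
  expect_equal(fe$observed / fe$expected, 1)
  expect_equal(fe$log2_oe, 0)
})

test_that("percentile bins are equal-count and track class separation", {
  q <- stats::setNames(c(1:40) / 2, sprintf("t%02d", 1:40))
  labels <- data.frame(te_id = names(q),
                       class = rep(c("A", "B"), each = 20L))
  out <- percentile_rank_overlay(q, labels, n_bins = 7L)
  expect_true(all(abs(diff(range(out$n))) <= 1))
  expect_equal(sum(out$n), 40L)
  # perfectly separated classes: top bins pure B, bottom pure A
  expect_equal(out$frac_A[1L], 1)
  expect_equal(out$frac_B[nrow(out)], 1)
  expect_true(all(diff(out$frac_B) >= 0))

  const <- percentile_rank_overlay(stats::setNames(rep(5, 40), names(q)),
                                   labels, n_bins = 7L)
  expect_true(all(abs(diff(range(const$n))) <= 1))
})

test_that("Mann-Whitney matches exact enumeration and the approximate oracle", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(mann_whitney(c(5, 5, 7), c(5, 5, 7))$p_value, 1)
  a <- c(1, 3, 9); b <- c(2, 8, 11, 4)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)

  set.seed(21)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  ours <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("z-score series are centered, scaled and flag constants", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(z$z, c(-1, 0, 1))
  expect_false(z$constant)
  zc <- zscore_series(c(5, 5, 5))
  expect_equal(zc$z, c(0, 0, 0))
  expect_true(zc$constant)
  set.seed(4)
  expect_equal(sum(zscore_series(rnorm(9))$z), 0, tolerance = 1e-9)
})

test_that("Pearson matrices match the covariance-formula oracle", {
  X <- matrix(c(1, 2, 3, 4), 1)
  expect_equal(pearson_matrix(X, 2 * X + 1)[1, 1], 1)
  expect_equal(pearson_matrix(X, -X)[1, 1], -1)
  y <- matrix(c(2, 1, 5, 3), 1)
  r_hand <- sum((X - mean(X)) * (y - mean(y))) /
    sqrt(sum((X - mean(X))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_matrix(X, y)[1, 1], r_hand)
  const <- matrix(1, 1, 4)
  expect_true(is.na(pearson_matrix(const, y)[1, 1]))
})
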