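stage10 <- c("fb", "pg", "gl", "eh", "lh", "et", "lt", "bc", "mg", "lf")

profile_matrix_fixture <- function() {
  tmpl <- sirna_templates(stage10)
  X <- rbind(tmpl["A", ] * 1.1, tmpl["A", ] * 0.9,
             tmpl["B", ] * 1.2, tmpl["B", ] * 0.8,
             rep(0, 10), rep(0.5, 10))
  rownames(X) <- paste0("TE", 1:6)
  X
}

test_that("depleted, A and B labels follow threshold and templates", {
  X <- profile_matrix_fixture()
  clusters <- c(1L, 1L, 2L, 2L, 3L, 3L)
  lab <- assign_bipartite_classes(clusters, X)
  expect_equal(lab$class, c("A", "A", "B", "B", "depleted", "depleted"))

  # threshold semantics: infinite threshold depletes everything
  lab_inf <- assign_bipartite_classes(clusters, X, threshold_rpm = Inf)
  expect_true(all(lab_inf$class == "depleted"))
})

test_that("ambiguous cluster profiles are reported as unclassified", {
  X <- matrix(5, nrow = 2, ncol = 10,
              dimnames = list(c("t1", "t2"), stage10))
  lab <- assign_bipartite_classes(c(1L, 1L), X)
  expect_true(all(lab$class == "unclassified"))
})

test_that("length partition applies the printed boundaries inclusively", {
  lens <- c(1, 723, 724, 2114, 2115, 9000)
  part <- length_partition(lens)
  expect_equal(as.character(part),
               c("short", "short", "medium", "medium", "long", "long"))
  ann <- data.frame(start = c(0, 100), end = c(723, 2900))
  expect_equal(as.character(length_partition(ann)), c("short", "long"))
  expect_equal(sum(table(part)), length(lens))
})

test_that("PCA matches prcomp conventions and a hand eigen-oracle", {
  # perfectly collinear data: PC1 explains everything
  X <- cbind(1:10, 2 * (1:10) + 1)
  p <- te_pca(X)
  expect_equal(p$variance_explained[1L], 1.0, tolerance = 1e-12)

  # four symmetric points: 50/50 split
  Y <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(unname(te_pca(Y)$variance_explained), c(0.5, 0.5))

  # 3 x 2 hand matrix: loadings equal the eigenvectors of the centered
  # covariance computed by hand
  Z <- rbind(c(1, 2), c(3, 3), c(5, 7))
  e <- eigen(stats::cov(Z))
  p2 <- te_pca(Z)
  for (j in 1:2)
    expect_equal(abs(sum(p2$loadings[, j] * e$vectors[, j])), 1,
                 tolerance = 1e-9)
  expect_equal(unname(p2$sdev^2), e$values, tolerance = 1e-12)

  Xc <- matrix(3, 4, 3)
  expect_true(te_pca(Xc)$degenerate)
})

test_that("sample clustering is complete linkage with monotone heights", {
  # 1-D samples at 0, 1, 10: merges at heights 1 then 10
  X <- matrix(c(0, 1, 10), nrow = 1,
              dimnames = list("te1", c("s1", "s2", "s3")))
  X <- rbind(X, X * 0)  # two TEs, distances driven by row 1
  h <- sample_hclust(X)
  expect_equal(h$height, c(1, 10))

  # duplicated sample merges first at height 0
  Y <- matrix(rnorm(20), 5, 4)
  Y <- cbind(Y, Y[, 2L])
  hy <- sample_hclust(Y)
  expect_equal(min(hy$height), 0)
  expect_true(all(diff(hy$height) >= -1e-12))
})

test_that("class proportions reproduce percentage arithmetic", {
  p <- class_proportions(c(A = 25, B = 25, C = 50))
  expect_equal(unname(p), c(25, 25, 50))
  expect_equal(sum(p), 100)
})
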