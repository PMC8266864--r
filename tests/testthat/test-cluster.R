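test_that("PCA matches an eigendecomposition oracle and reconstructs exactly", {
  set.seed(61)
  m <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  pc <- pca_expression(m, n_components = 5)

  # oracle: eigendecomposition of the sample covariance of centered samples
  xc <- t(m - rowMeans(m))
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  expect_equal(pc$sdev^2, ev$values[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    expect_equal(abs(pc$loadings[, k]), abs(ev$vectors[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # scores are centered and variance fractions are sorted and bounded
  expect_equal(colMeans(pc$scores), rep(0, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pc$explained_variance_fraction), 1 + 1e-12)

  # full-rank reconstruction of the centered matrix
  rec <- pc$scores %*% t(pc$loadings)
  expect_equal(rec, xc, tolerance = 1e-8, ignore_attr = TRUE)

  # sign convention: each loading's largest-|entry| is positive
  expect_true(all(apply(pc$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("PCA handles degenerate geometry", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  pc <- pca_expression(m, 2)
  expect_equal(pc$scores["s1", 1], pc$scores["s2", 1], tolerance = 1e-10)
  # collinear samples: one component explains everything
  expect_equal(pc$explained_variance_fraction[1], 1, tolerance = 1e-10)
  expect_error(pca_expression(m, 10), "n_components")
})

test_that("average-linkage clustering agrees with an O(n^3) UPGMA oracle", {
  # two close points and one far: the close pair merges first
  x <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  hc <- hierarchical_cluster(t(x), axis = "samples")
  expect_equal(hc$height[1L], 1)
  expect_setequal(hc$labels[-hc$merge[1L, ]], c("a", "b"))

  set.seed(62)
  for (i in 1:10) {
    y <- matrix(rnorm(12 * 4), nrow = 12)
    rownames(y) <- paste0("i", 1:12)
    hc2 <- hierarchical_cluster(t(y), axis = "samples")
    expect_equal(sort(hc2$height), upgma_heights(y), tolerance = 1e-10)
    expect_equal(length(hc2$height), 11L)
  }

  # monotone heights on a broad random sweep
  for (i in 1:100) {
    n <- sample(3:15, 1)
    y <- matrix(rnorm(n * 3), nrow = n)
    hc3 <- stats::hclust(stats::dist(y), method = "average")
    expect_true(all(diff(hc3$height) >= -1e-12))
  }

  expect_error(hierarchical_cluster(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("tree cutting yields exactly k clusters and recovers planted groups", {
  set.seed(63)
  x <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(20, 8), ncol = 2))
  rownames(x) <- paste0("s", 1:20)
  hc <- hierarchical_cluster(t(x), axis = "samples")
  cl <- cut_tree(hc, 2)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])

  expect_equal(length(unique(cut_tree(hc, 1))), 1L)
  expect_equal(length(unique(cut_tree(hc, 20))), 20L)
  expect_error(cut_tree(hc, 0), "k must be")
  expect_error(cut_tree(hc, 21), "k must be")
  for (k in c(2, 5, 9, 13)) {
    expect_equal(length(unique(cut_tree(hc, k))), k)
  }
})

test_that("dendrograms export to parseable Newick", {
  set.seed(64)
  x <- matrix(rnorm(18), nrow = 6, dimnames = list(paste0("g", 1:6), NULL))
  hc <- hierarchical_cluster(x, axis = "genes")
  nwk <- export_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("g", 1:6))

  f <- withr::local_tempfile(fileext = ".nwk")
  export_newick(hc, f)
  expect_setequal(ape::read.tree(f)$tip.label, paste0("g", 1:6))
})

test_that("row standardization uses the population-SD convention", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g1", c("a", "b", "c")))
  z <- row_standardize(m)
  expect_equal(unname(z[1, ]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  zs <- row_standardize(m, sd_type = "sample")
  expect_equal(unname(zs[1, ]), c(-1, 0, 1))

  expect_warning(zz <- row_standardize(rbind(m, g2 = c(5, 5, 5))), "zero-variance")
  expect_equal(unname(zz["g2", ]), c(0, 0, 0))

  set.seed(65)
  mm <- matrix(rnorm(50), nrow = 5)
  z2 <- row_standardize(mm)
  expect_equal(rowMeans(z2), rep(0, 5), tolerance = 1e-12)
  expect_equal(rowSums(z2^2) / ncol(mm), rep(1, 5), tolerance = 1e-12)
})
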