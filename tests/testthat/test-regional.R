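toy_map <- function() {
  lab <- array(0L, c(2, 6, 6))
  lab[1, 1:3, ] <- 1L
  lab[2, 4:6, ] <- 2L
  region_label_map(lab, c("1" = "AL", "2" = "MB"))
}

test_that("region means are size-normalized sums matching the voxel oracle", {
  map <- toy_map()
  const <- array(3, c(2, 6, 6))
  expect_equal(unname(region_means(const, map)), c(3, 3))

  doubled <- const
  doubled[map$labels == 2L] <- 6
  expect_equal(unname(region_means(doubled, map)), c(3, 6))

  set.seed(5)
  v <- array(runif(2 * 6 * 6, 0, 50), c(2, 6, 6))
  got <- region_means(v, map)
  for (id in c(1L, 2L)) {
    nm <- map$region_names[[as.character(id)]]
    expect_equal(got[[nm]], mean(v[map$labels == id]))
  }
  # additivity
  w <- array(runif(2 * 6 * 6), c(2, 6, 6))
  expect_equal(region_means(v + w, map), region_means(v, map) +
                 region_means(w, map), tolerance = 1e-12)
})

test_that("excluded and absent regions are handled explicitly", {
  lab <- array(0L, c(1, 4, 4)); lab[1, 1:2, ] <- 1L
  map <- region_label_map(lab, c("1" = "AL", "2" = "LOP"),
                          excluded = "LOP")
  v <- array(2, c(1, 4, 4))
  got <- region_means(v, map)
  expect_false("LOP" %in% names(got))

  map2 <- region_label_map(lab, c("1" = "AL", "2" = "MB"))
  expect_warning(got2 <- region_means(v, map2), "zero voxels")
  expect_true(is.na(got2[["MB"]]))
})

test_that("gene-mean normalization is exact, idempotent and scale-free", {
  m <- region_expression_matrix(matrix(c(2, 4, 5, 5), 2, 2, byrow = TRUE))
  nm <- normalize_rows(m)
  expect_equal(unname(nm$values[1, ]), c(2 / 3, 4 / 3))
  expect_equal(unname(rowMeans(nm$values)), c(1, 1), tolerance = 1e-9)
  expect_true(nm$normalized)
  expect_equal(normalize_rows(nm)$values, nm$values, tolerance = 1e-12)
  # scaling a gene's raw row by k > 0 leaves its normalized row unchanged
  m2 <- region_expression_matrix(m$values * c(7, 1))
  expect_equal(normalize_rows(m2)$values, nm$values, tolerance = 1e-12)
  expect_error(normalize_rows(region_expression_matrix(
    matrix(0, 2, 2))), "positive mean")
})

test_that("ward-d2 clustering merges identical genes first", {
  vals <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4),
                g3 = c(10, 0, 5, 1))
  ch <- cluster_heatmap(region_expression_matrix(vals), "genes")
  merged_first <- sort(ch$hclust$merge[1, ])
  expect_equal(merged_first, c(-2, -1))
  expect_equal(ch$hclust$height[1], 0)
  expect_match(ch$newick, "g3")
})

test_that("ward-d2 merge heights match the Lance-Williams oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    X <- matrix(rnorm(n * 4), n)
    ch <- cluster_heatmap(region_expression_matrix(X), "genes")
    expect_equal(ch$hclust$height, oracle_ward_d2_heights(X),
                 tolerance = 1e-9)
  }
})

test_that("clustering is invariant to input row order", {
  set.seed(33)
  X <- matrix(rnorm(6 * 5), 6)
  rownames(X) <- paste0("g", 1:6)
  perm <- sample(6)
  c1 <- cluster_heatmap(region_expression_matrix(X), "genes")
  c2 <- cluster_heatmap(region_expression_matrix(X[perm, ]), "genes")
  expect_equal(sort(c1$hclust$height), sort(c2$hclust$height),
               tolerance = 1e-9)
  k1 <- cutree(c1$hclust, 3)
  k2 <- cutree(c2$hclust, 3)[rownames(X)]
  expect_equal(rand_index(unname(k1), unname(k2)), 1)
})

test_that("region clustering uses correlation distance and flags constants", {
  set.seed(8)
  X <- matrix(rnorm(8 * 4), 8)
  m <- region_expression_matrix(X)
  ch <- cluster_heatmap(m, "regions")
  expect_equal(length(ch$order), 4)
  Xc <- X; Xc[, 2] <- 1
  expect_error(cluster_heatmap(region_expression_matrix(Xc), "regions"),
               "constant")
})

test_that("region correlations match the direct Pearson formula", {
  set.seed(13)
  X <- matrix(rnorm(6 * 6), 6)
  m <- region_expression_matrix(X)
  rc <- region_correlation(m)
  expect_equal(dim(rc), c(6, 6))
  expect_equal(unname(diag(rc)), rep(1, 6))
  expect_equal(rc, t(rc))
  expect_true(all(rc >= -1 & rc <= 1))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(rc[i, j], oracle_pearson(X[, i], X[, j]), tolerance = 1e-12)
  }
  # duplicated column -> r = 1; negated column -> r = -1
  Xd <- cbind(X[, 1], X[, 1], -X[, 1])
  rcd <- region_correlation(region_expression_matrix(Xd))
  expect_equal(rcd[1, 2], 1)
  expect_equal(rcd[1, 3], -1)
})

test_that("planted gene blocks are recovered by cutting the gene tree", {
  set.seed(90)
  profiles <- matrix(runif(3 * 25, 1, 10), 3)
  truth <- rep(1:3, each = 4)
  X <- profiles[truth, ] * (1 + matrix(rnorm(12 * 25, sd = 0.1), 12))
  m <- normalize_rows(region_expression_matrix(X))
  ch <- cluster_heatmap(m, "genes")
  got <- cutree(ch$hclust, 3)
  expect_gte(rand_index(unname(got), truth), 0.9)
})
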