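test_that("sphingolipid species are filtered at 0.01 ng/brain", {
  t <- rbind(
    make_lipid_rows("CerPE low", "CerPE", "control", c(0.009, 0.009)),
    make_lipid_rows("CerPE low", "CerPE", "mutant", c(0.01, 0.01)),
    make_lipid_rows("CerPE high", "CerPE", "control", c(0.011, 0.011)),
    make_lipid_rows("CerPE high", "CerPE", "mutant", c(0.02, 0.02)))
  f <- filter_species(lipid_table(t))
  expect_setequal(unique(f$species), "CerPE high")
})

test_that("phospholipids keep the top 99.5% cumulative abundance", {
  ab <- c(90, 9, 0.9, 0.1)
  t <- do.call(rbind, lapply(1:4, function(i) rbind(
    make_lipid_rows(paste0("PC sp", i), "PC", "control", rep(ab[i], 2)),
    make_lipid_rows(paste0("PC sp", i), "PC", "mutant", rep(ab[i], 2)))))
  f <- filter_species(lipid_table(t))
  expect_setequal(unique(f$species), paste0("PC sp", 1:3))
  # everything above threshold -> unchanged
  t2 <- rbind(make_lipid_rows("Cer a", "Cer", "control", c(1, 1)),
              make_lipid_rows("Cer a", "Cer", "mutant", c(2, 2)))
  f2 <- filter_species(lipid_table(t2))
  expect_equal(nrow(f2), nrow(t2))
})

test_that("fold change is the mean of per-replicate ratios", {
  t <- rbind(make_lipid_rows("Cer a", "Cer", "control", c(2, 2)),
             make_lipid_rows("Cer a", "Cer", "mutant", c(3, 3)))
  fc <- fold_change(lipid_table(t))
  expect_equal(fc$fold_change, 1.5)
  # mean-of-ratios vs ratio-of-means differ on asymmetric replicates
  t2 <- rbind(make_lipid_rows("Cer a", "Cer", "control", c(1, 3)),
              make_lipid_rows("Cer a", "Cer", "mutant", c(1, 3)))
  mor <- fold_change(lipid_table(t2))$fold_change
  rom <- fold_change(lipid_table(t2), summary = "ratio_of_means")$fold_change
  expect_equal(mor, 1)
  expect_equal(rom, 1)
  # scale equivariance: multiplying all abundances by k leaves FC unchanged
  t3 <- t; t3$ng_per_brain <- t3$ng_per_brain * 37
  expect_equal(fold_change(lipid_table(t3))$fold_change, 1.5)
  # zero control mean errors
  t4 <- rbind(make_lipid_rows("Cer a", "Cer", "control", c(0, 0)),
              make_lipid_rows("Cer a", "Cer", "mutant", c(1, 1)))
  expect_error(fold_change(lipid_table(t4)), "zero control mean")
})

test_that("a planted threefold effect is recovered from noisy replicates", {
  base <- simulate_lipid_table(c(Cer = 5), 4, cv = 0, seed = 44L)
  target <- base$species[1]
  lt <- simulate_lipid_table(c(Cer = 5), 4, cv = 0.1, seed = 44L,
                             genotype_effects = setNames(3.0, target))
  fc <- fold_change(lt)
  got <- fc$fold_change[fc$species == target]
  expect_gte(got, 2.5); expect_lte(got, 3.5)
})

test_that("headgroup PCA matches a direct eigendecomposition", {
  set.seed(50)
  lt <- simulate_lipid_table(c(CerPE = 5), 2, cv = 0.3, seed = 50L)
  p <- headgroup_pca(lt, "CerPE")
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-12)

  # oracle on the same z-scored matrix (4 samples x 5 species)
  m <- tapply(lt$ng_per_brain, list(paste(lt$genotype, lt$replicate, sep = "_"),
                                    lt$species), mean)
  z <- scale(m)
  cv <- crossprod(z) / (nrow(z) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  want_scores <- z %*% ev$vectors
  informative <- which(p$variance_fractions > 1e-8)
  for (j in informative) {
    expect_equal(abs(p$scores[, j]), abs(want_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: the largest-magnitude loading is positive
    i <- which.max(abs(p$loadings[, j]))
    expect_gte(p$loadings[i, j], 0)
  }
  expect_equal(p$variance_fractions,
               (ev$values / sum(ev$values))[seq_along(p$variance_fractions)],
               tolerance = 1e-9)
})

test_that("a noiseless two-cluster design loads entirely on PC1", {
  t <- do.call(rbind, lapply(1:4, function(i) rbind(
    make_lipid_rows(paste0("PS sp", i), "PS", "control", rep(10, 3)),
    make_lipid_rows(paste0("PS sp", i), "PS", "mutant", rep(10 + i, 3)))))
  p <- suppressWarnings(headgroup_pca(lipid_table(t), "PS"))
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-9)
  sc <- p$scores[, 1]
  geno <- p$samples$genotype
  expect_true(max(sc[geno == "control"]) < min(sc[geno == "mutant"]) ||
                min(sc[geno == "control"]) > max(sc[geno == "mutant"]))
})

test_that("PCA scores are invariant to species column order", {
  lt <- simulate_lipid_table(c(PI = 6), 3, cv = 0.2, seed = 61L)
  p1 <- headgroup_pca(lt, "PI")
  p2 <- headgroup_pca(lt[rev(seq_len(nrow(lt))), ], "PI")
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(p1$variance_fractions, p2$variance_fractions,
               tolerance = 1e-12)
})

test_that("volcano applies the BH-corrected P and fold-change rule", {
  base <- simulate_lipid_table(c(CerPE = 10), 4, cv = 0, seed = 70L)
  target <- base$species[2]
  lt <- simulate_lipid_table(c(CerPE = 10), 4, cv = 0.05, seed = 70L,
                             genotype_effects = setNames(4.0, target))
  v <- volcano(lt)
  expect_s3_class(v, "volcano_table")
  expect_true(v$significant[v$species == target])
  expect_true(all(v$p_adj >= v$p_raw))
  expect_equal(v$p_adj, oracle_bh(v$p_raw), tolerance = 1e-12)
  # a strong fold change with an insignificant p is not flagged
  expect_true(all(v$significant == (v$p_adj < 0.05 & abs(v$log2_fc) >
                                      log2(1.5))))
})

test_that("degenerate zero-variance species give p = 1 under equal means", {
  t <- rbind(make_lipid_rows("Cer a", "Cer", "control", c(2, 2)),
             make_lipid_rows("Cer a", "Cer", "mutant", c(2, 2)),
             make_lipid_rows("Cer b", "Cer", "control", c(1, 1.2)),
             make_lipid_rows("Cer b", "Cer", "mutant", c(1.1, 1.4)))
  v <- volcano(lipid_table(t))
  expect_equal(v$p_raw[v$species == "Cer a"], 1)
  expect_false(v$significant[v$species == "Cer a"])
})

test_that("welch and log-abundance variants agree with stats::t.test", {
  set.seed(81)
  x <- abs(rnorm(4, 10, 3)); y <- abs(rnorm(4, 14, 1))
  t <- rbind(make_lipid_rows("PC sp", "PC", "control", x),
             make_lipid_rows("PC sp", "PC", "mutant", y))
  v_eq <- volcano(lipid_table(t))
  v_w <- volcano(lipid_table(t), welch = TRUE)
  v_log <- volcano(lipid_table(t), log_abundance = TRUE)
  expect_equal(v_eq$p_raw, t.test(y, x, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(v_w$p_raw, t.test(y, x)$p.value, tolerance = 1e-12)
  expect_equal(v_log$p_raw, t.test(log(y), log(x), var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("lipid tables are validated", {
  bad <- make_lipid_rows("X", "NotAHeadgroup", "control", c(1, 2))
  expect_error(lipid_table(bad), "headgroup")
  dup <- rbind(make_lipid_rows("Cer a", "Cer", "control", c(1, 2)),
               make_lipid_rows("Cer a", "Cer", "control", c(1, 2)))
  expect_error(lipid_table(dup), "unique")
})
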