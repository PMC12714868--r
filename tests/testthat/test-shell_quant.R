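disc_slice <- function(ny, nx, centers, radius, value = 200) {
  s <- matrix(0, ny, nx)
  for (ct in centers) {
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      if ((y - ct[1])^2 + (x - ct[2])^2 <= radius^2) s[y, x] <- value
    }
  }
  s
}

as_vol <- function(slice) array(slice, dim = c(1, nrow(slice), ncol(slice)))

test_that("contrast normalization matches the percentile-clip contract", {
  set.seed(7)
  v <- array(runif(1000, 10, 250), dim = c(10, 10, 10))
  # fraction 0: pure min-max rescale
  out0 <- normalize_contrast(v, 0)
  expect_equal(out0, (v - min(v)) / (max(v) - min(v)), tolerance = 1e-12)
  # 1000 voxels at fraction 0.004: exactly 2 voxels at each tail clipped
  out <- normalize_contrast(v, 0.004)
  expect_equal(sum(out == 0), 2)
  expect_equal(sum(out == 1), 2)
  # monotone: rank order preserved among unclipped voxels
  expect_identical(order(v[out > 0 & out < 1]), order(out[out > 0 & out < 1]))
  # constant image passes through with a warning
  k <- array(5, dim = c(2, 3, 3))
  expect_warning(res <- normalize_contrast(k, 0.0035), "constant")
  expect_identical(res, k)
})

test_that("nucleus masks separate, split and clean objects as specified", {
  cfg <- analysis_config()
  vox <- c(1, 0.5, 0.5)
  # two discs with a clear gap -> two labeled objects
  apart <- as_vol(disc_slice(64, 64, list(c(20, 20), c(20, 48)), 8))
  m1 <- make_nucleus_mask(apart, cfg, vox)
  expect_equal(max(m1$labels), 2)
  # touching discs (0-px gap) -> watershed still yields two objects
  touching <- as_vol(disc_slice(64, 64, list(c(32, 24), c(32, 40)), 8))
  m2 <- make_nucleus_mask(touching, cfg, vox)
  expect_equal(max(m2$labels), 2)
  # a particle smaller than the opening radius is removed, the disc survives
  small <- disc_slice(64, 64, list(c(16, 16)), 8)
  small[50, 50] <- 200  # single-pixel speck
  m3 <- make_nucleus_mask(as_vol(small), cfg, vox)
  expect_equal(max(m3$labels), 1)
  expect_equal(m3$data[1, 50, 50], 0)
  # an all-background slice yields an empty mask, not an error
  vol <- array(0, dim = c(2, 64, 64))
  vol[1, , ] <- disc_slice(64, 64, list(c(30, 30)), 8)
  m4 <- make_nucleus_mask(vol, cfg, vox)
  expect_true(all(m4$data[2, , ] == 0))
  expect_gt(sum(m4$data[1, , ]), 0)
})

test_that("shell masks are annuli disjoint from their nuclei", {
  # empty nucleus -> empty shell
  empty <- mask_stack(array(0, c(2, 8, 8)), "nucleus")
  expect_equal(sum(make_shell_mask(empty)$data), 0)
  # single-pixel nucleus, radius 3: shell count = |disc(3)| - 1
  one <- array(0, c(1, 21, 21)); one[1, 11, 11] <- 1
  sh <- make_shell_mask(mask_stack(one, "nucleus"), 3)
  expect_equal(sum(sh$data), oracle_disc_count(3) - 1)
  # disjointness on random masks
  set.seed(11)
  for (i in 1:5) {
    m <- array(as.numeric(runif(4 * 20 * 20) < 0.1), c(4, 20, 20))
    shl <- make_shell_mask(mask_stack(m, "nucleus"), 2)
    expect_equal(sum(shl$data * m), 0)
    surr <- attr(shl, "surrounding")$data
    expect_equal(shl$data, surr * (1 - m))
  }
})

test_that("shell measurement matches the direct voxel-list oracle", {
  set.seed(3)
  inten <- array(runif(5 * 16 * 16, 0, 100), c(5, 16, 16))
  m <- array(as.numeric(runif(5 * 16 * 16) < 0.3), c(5, 16, 16))
  m[4, , ] <- 0   # an empty slice is recorded with count 0
  ms <- measure_shell(inten, mask_stack(m, "shell"))
  expect_equal(ms$pixel_count[4], 0)
  expect_true(is.na(ms$mean_intensity[4]))
  for (z in c(1, 2, 3, 5)) {
    expect_equal(ms$mean_intensity[z], mean(inten[z, , ][m[z, , ] > 0]))
    expect_equal(ms$pixel_count[z], sum(m[z, , ]))
  }
  # constant field: every nonempty slice mean is the constant
  ms7 <- measure_shell(array(7, c(5, 16, 16)), mask_stack(m, "shell"))
  expect_true(all(ms7$mean_intensity[ms7$pixel_count > 0] == 7))
  # checkerboard 0/10 over a full-slice shell -> mean 5
  cb <- array(0, c(1, 16, 16))
  cb[1, , ] <- outer(1:16, 1:16, function(a, b) 10 * ((a + b) %% 2))
  full <- mask_stack(array(1, c(1, 16, 16)), "shell")
  expect_equal(measure_shell(cb, full)$mean_intensity, 5)
})

test_that("the pixel-weighted mean equals the pooled voxel mean", {
  m <- data.frame(z = 1:2, pixel_count = c(10, 30), mean_intensity = c(2, 4))
  class(m) <- c("shell_measurement", "data.frame")
  expect_equal(weighted_mean(m), 3.5)
  one <- m[1, ]; class(one) <- c("shell_measurement", "data.frame")
  expect_equal(weighted_mean(one), 2)
  empty <- data.frame(z = 1, pixel_count = 0, mean_intensity = NA)
  class(empty) <- c("shell_measurement", "data.frame")
  expect_error(weighted_mean(empty), "empty ROI")

  set.seed(19)
  for (i in 1:10) {
    inten <- array(rnorm(6 * 12 * 12, 50, 20), c(6, 12, 12))
    inten <- pmax(inten, 0)
    mask <- array(as.numeric(runif(6 * 12 * 12) < 0.4), c(6, 12, 12))
    if (sum(mask) == 0) next
    wm <- weighted_mean(measure_shell(inten, mask_stack(mask, "shell")))
    expect_equal(wm, oracle_pooled_mean(inten, mask), tolerance = 1e-12)
  }
})

test_that("shell means are shift-covariant in the measured channel", {
  p <- brain_sim_params(noise_sd = 0, seed = 23L)
  sim <- simulate_brain_stack(p)
  ha <- get_channel(sim$stack, "HA")
  nuc <- make_nucleus_mask(get_channel(sim$stack, "Elav"),
                           voxel_size_um = sim$stack$voxel_size_um)
  sh <- make_shell_mask(nuc)
  m0 <- measure_shell(ha, sh)
  m5 <- measure_shell(ha + 5, sh)
  keep <- m0$pixel_count > 0
  expect_equal(m5$mean_intensity[keep], m0$mean_intensity[keep] + 5,
               tolerance = 1e-12)
  expect_equal(weighted_mean(m5), weighted_mean(m0) + 5, tolerance = 1e-12)
})

test_that("equal shell intensities give a ratio of one", {
  p <- brain_sim_params(shell_intensity_neuron = 200,
                        shell_intensity_glia = 200,
                        background = 10, noise_sd = 0, seed = 41L)
  sim <- simulate_brain_stack(p)
  res <- shell_ratio(sim$stack)
  expect_equal(res$ratio_neuron_to_glia, 1.0, tolerance = 0.05)
})

test_that("a brain without glia yields a flagged undefined ratio", {
  p <- brain_sim_params(neuron_fraction = 1, noise_sd = 0, seed = 6L)
  sim <- simulate_brain_stack(p)
  res <- shell_ratio(sim$stack)
  expect_true(is.na(res$ratio_neuron_to_glia))
  expect_match(paste(res$flags, collapse = " "), "glial")
})
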