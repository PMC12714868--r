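# Independent brute-force oracles used to check the package implementations.
# Each oracle is written directly from the defining formula or enumeration and
# shares no code with the implementation it checks.

# plain mean over all ROI voxels pooled across slices
oracle_pooled_mean <- function(intensity, mask3d) {
  mean(intensity[mask3d > 0])
}

# all-pairs nearest-neighbour matching at an inclusive radius
oracle_match <- function(a_um, b_um, radius_um) {
  if (nrow(a_um) == 0 || nrow(b_um) == 0) {
    return(data.frame(index_a = integer(), index_b = integer()))
  }
  d2 <- outer(rowSums(a_um^2), rep(1, nrow(b_um))) +
    outer(rep(1, nrow(a_um)), rowSums(b_um^2)) - 2 * a_um %*% t(b_um)
  d <- sqrt(pmax(d2, 0))
  out <- lapply(seq_len(nrow(a_um)), function(i) {
    j <- which.min(d[i, ])
    if (d[i, j] <= radius_um) c(i, j) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(index_a = integer(), index_b = integer()))
  data.frame(index_a = out[, 1], index_b = out[, 2])
}

# Benjamini-Hochberg step-up from the definition: sort ascending, take the
# running minimum of p * m / rank from the largest rank down, cap at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# agglomerative Ward-D2 by direct evaluation of the Lance-Williams recurrence
# on squared distances; returns the merge heights in order
oracle_ward_d2_heights <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      v <- d2[active[ii], active[jj]]
      if (v < bestv) { bestv <- v; best <- c(ii, jj) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights[step] <- sqrt(bestv)
    ni <- size[i]; nj <- size[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- size[k]
      d2new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                  nk * d2[i, j]) / (ni + nj + nk)
      d2[i, k] <- d2new; d2[k, i] <- d2new
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- (same_a == same_b)
  (sum(agree) - n) / (n * (n - 1))
}

# number of integer offsets inside a rasterized disc of the given pixel
# radius, using the rank-filter convention (pixel centers within r + 0.5 of
# the origin) that ImageJ's Maximum/Minimum filters and EBImage brushes share
oracle_disc_count <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  sum(g$dx^2 + g$dy^2 <= (r + 0.5)^2)
}

# direct Pearson product-moment formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# pooled-variance two-sample t-test from the formulas
oracle_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# one-sample two-tailed t-test against a constant
oracle_t_one_sample <- function(x, mu) {
  t <- (mean(x) - mu) / (sd(x) / sqrt(length(x)))
  2 * pt(-abs(t), length(x) - 1)
}

# render isotropic Gaussian blobs at given (z,y,x) um positions into a volume
render_spot_volume <- function(coords_um, shape_zyx, voxel_size_um,
                               amplitude = 200, sigma_um = 1) {
  vol <- array(0, dim = shape_zyx)
  ax <- lapply(1:3, function(i) {
    (seq_len(shape_zyx[i]) - 0.5) * voxel_size_um[i]
  })
  for (i in seq_len(nrow(coords_um))) {
    gz <- exp(-(ax[[1]] - coords_um[i, 1])^2 / (2 * sigma_um^2))
    gy <- exp(-(ax[[2]] - coords_um[i, 2])^2 / (2 * sigma_um^2))
    gx <- exp(-(ax[[3]] - coords_um[i, 3])^2 / (2 * sigma_um^2))
    vol <- vol + amplitude * outer(outer(gz, gy), gx)
  }
  vol
}

# minimal lipid table builder for hand-specified abundances
make_lipid_rows <- function(species, headgroup, genotype, values) {
  data.frame(species = species, headgroup = headgroup, genotype = genotype,
             replicate = seq_along(values), ng_per_brain = values)
}
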