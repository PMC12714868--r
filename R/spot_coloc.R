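# Nuclear-spot colocalization: detection of point sources, proximity matching
# at a physical distance threshold (2 um by default, boundary inclusive), and
# the neuron/glia enrichment statistic against the 89.56% neuronal baseline.

#' Point set in physical coordinates
#'
#' @param coords_um numeric matrix with one (z, y, x) row per spot, in um.
#' @param channel channel name (nonempty).
#' @return An object of class \code{spot_set}.
#' @export
spot_set <- function(coords_um, channel) {
  coords_um <- as.matrix(coords_um)
  if (length(coords_um) == 0) coords_um <- matrix(numeric(), 0, 3)
  if (ncol(coords_um) != 3L) stop("coords_um must have 3 columns (z, y, x)")
  if (any(!is.finite(coords_um))) stop("coordinates must be finite")
  if (!is.character(channel) || length(channel) != 1L || !nzchar(channel)) {
    stop("channel must be a nonempty string")
  }
  colnames(coords_um) <- c("z", "y", "x")
  structure(list(coords_um = coords_um, channel = channel),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set channel=%s> %d spot(s)\n", x$channel,
              nrow(x$coords_um)))
  invisible(x)
}

#' Detect point sources in a 3D channel
#'
#' Band-pass filters the volume slice-wise (difference of in-plane Gaussians,
#' sigma and 2 sigma), finds 3D local maxima over the 26-neighbourhood, keeps
#' maxima whose original intensity reaches \code{min_intensity}, then enforces
#' a minimum pairwise separation greedily in decreasing intensity order.
#' Coordinates are voxel centers in um.
#'
#' @param channel 3D (z, y, x) intensity array.
#' @param voxel_size_um (z, y, x) voxel size in um.
#' @param min_intensity minimum raw intensity at an accepted maximum (a.u.).
#' @param min_separation_um minimum distance between accepted spots (um).
#' @param sigma_px in-plane sigma of the band-pass filter (pixels).
#' @param channel_name name recorded in the returned spot set.
#' @return A \code{\link{spot_set}}.
#' @export
detect_spots <- function(channel, voxel_size_um, min_intensity,
                         min_separation_um, sigma_px = 2,
                         channel_name = "spots") {
  stopifnot(is.array(channel), length(dim(channel)) == 3L,
            min_separation_um > 0)
  d <- dim(channel)
  filt <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    s <- channel[z, , ]
    lo <- EBImage::gblur(s, sigma = sigma_px)
    hi <- EBImage::gblur(s, sigma = 2 * sigma_px)
    filt[z, , ] <- EBImage::imageData(lo) - EBImage::imageData(hi)
  }
  is_max <- array(TRUE, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    shifted <- array(-Inf, dim = d)
    src_z <- seq_len(d[1]) + dz; src_y <- seq_len(d[2]) + dy
    src_x <- seq_len(d[3]) + dx
    ok_z <- src_z >= 1 & src_z <= d[1]
    ok_y <- src_y >= 1 & src_y <= d[2]
    ok_x <- src_x >= 1 & src_x <= d[3]
    shifted[ok_z, ok_y, ok_x] <-
      filt[src_z[ok_z], src_y[ok_y], src_x[ok_x]]
    is_max <- is_max & (filt >= shifted)
  }
  cand <- which(is_max & channel >= min_intensity & filt > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(spot_set(matrix(numeric(), 0, 3), channel_name))
  inten <- channel[cand]
  ord <- order(inten, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  coords <- sweep(cand - 0.5, 2, voxel_size_um, "*")
  keep <- logical(nrow(coords))
  acc <- matrix(numeric(), 0, 3)
  for (i in seq_len(nrow(coords))) {
    if (nrow(acc) == 0 ||
        min(sqrt(colSums((t(acc) - coords[i, ])^2))) >= min_separation_um) {
      keep[i] <- TRUE
      acc <- rbind(acc, coords[i, ])
    }
  }
  spot_set(coords[keep, , drop = FALSE], channel_name)
}

# grid-bucket nearest-neighbour search; cell size = radius so only the 27
# neighbouring cells can hold a point within the threshold
nearest_within <- function(a, b, radius_um) {
  na <- nrow(a); nb <- nrow(b)
  idx <- rep(NA_integer_, na); dst <- rep(NA_real_, na)
  if (na == 0 || nb == 0) return(list(index = idx, dist = dst))
  cell <- radius_um
  key <- function(m) floor(sweep(m, 2, rep(cell, 3), "/"))
  kb <- key(b)
  buckets <- split(seq_len(nb), paste(kb[, 1], kb[, 2], kb[, 3]))
  ka <- key(a)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(na)) {
    best <- NA_integer_; bestd <- Inf
    for (o in seq_len(nrow(offs))) {
      k <- ka[i, ] + offs[o, ]
      hits <- buckets[[paste(k[1], k[2], k[3])]]
      if (is.null(hits)) next
      dd <- sqrt(colSums((t(b[hits, , drop = FALSE]) - a[i, ])^2))
      j <- which.min(dd)
      if (dd[j] < bestd) { bestd <- dd[j]; best <- hits[j] }
    }
    if (is.finite(bestd) && bestd <= radius_um) {
      idx[i] <- best; dst[i] <- bestd
    }
  }
  list(index = idx, dist = dst)
}

#' Match spots across channels at a distance threshold
#'
#' Pairs each spot of \code{a} with its nearest spot of \code{b} at Euclidean
#' (physical, um) distance at or below \code{radius_um}; the boundary is
#' inclusive ("within 2 um" includes exactly 2 um). Spots of \code{a} with no
#' \code{b} spot in range are unpaired and omitted from the result.
#'
#' @param a,b \code{\link{spot_set}} objects.
#' @param radius_um matching radius in um (> 0).
#' @return data.frame(index_a, index_b, dist_um), one row per paired a-spot.
#' @export
match_spots <- function(a, b, radius_um = 2) {
  stopifnot(inherits(a, "spot_set"), inherits(b, "spot_set"), radius_um > 0)
  nn <- nearest_within(a$coords_um, b$coords_um, radius_um)
  paired <- which(!is.na(nn$index))
  data.frame(index_a = paired, index_b = nn$index[paired],
             dist_um = nn$dist[paired])
}

#' Neuron/glia enrichment of reporter spots
#'
#' Matches mCherry reporter spots to Elav (neuronal) and Repo (glial) nuclear
#' spots at the configured radius. Labeled spots are those matched to either
#' marker; a spot within range of both goes to the nearer marker, with exact
#' ties resolved toward Elav (the tie count is reported). Percentages are
#' computed over labeled spots only, so pct_elav + pct_repo = 100. When at
#' least two replicate percentages are supplied, a two-tailed one-sample
#' t-test compares them to the baseline percentage (89.56 by default — the
#' Elav share of all labeled nuclei across 182 brains); a two-sample mode
#' tests against explicit baseline replicates instead. Classification is
#' "neuronal" when the replicate mean exceeds the baseline with p < 0.05,
#' "glial" when below it with p < 0.05, otherwise "none".
#'
#' @param mcherry,elav,repo \code{\link{spot_set}} objects.
#' @param replicate_pcts optional numeric vector of per-replicate pct_elav
#'   values used for the test (NULL: no test, classification "none").
#' @param config an \code{\link{analysis_config}}.
#' @param baseline_pcts optional baseline replicate percentages; when given,
#'   a two-sample equal-variance t-test is used instead of the one-sample
#'   test against the constant baseline.
#' @return An \code{enrichment_result} with pct_elav, pct_repo, n_labeled,
#'   baseline_pct, p_value, classification, tie count and flags.
#' @export
enrichment <- function(mcherry, elav, repo, replicate_pcts = NULL,
                       config = analysis_config(), baseline_pcts = NULL) {
  r <- config$coloc_radius_um
  nn_e <- nearest_within(mcherry$coords_um, elav$coords_um, r)
  nn_r <- nearest_within(mcherry$coords_um, repo$coords_um, r)
  has_e <- !is.na(nn_e$index); has_r <- !is.na(nn_r$index)
  to_elav <- has_e & (!has_r | nn_e$dist <= nn_r$dist)   # ties go to Elav
  to_repo <- has_r & !to_elav
  ties <- sum(has_e & has_r & nn_e$dist == nn_r$dist)
  n_lab <- sum(to_elav) + sum(to_repo)
  if (n_lab == 0) stop("no labeled spots: nothing colocalizes with a marker")
  pct_elav <- 100 * sum(to_elav) / n_lab
  baseline <- config$elav_baseline_pct

  p_value <- NA_real_
  classification <- "none"
  flags <- character()
  if (!is.null(replicate_pcts)) {
    if (length(replicate_pcts) < 2) {
      stop("at least 2 replicate percentages are required for a p-value")
    }
    if (stats::sd(replicate_pcts) == 0 && is.null(baseline_pcts)) {
      flags <- c(flags, "zero variance across replicates: p undefined")
    } else {
      tt <- if (is.null(baseline_pcts)) {
        stats::t.test(replicate_pcts, mu = baseline)
      } else {
        stats::t.test(replicate_pcts, baseline_pcts, var.equal = TRUE)
      }
      p_value <- unname(tt$p.value)
      m <- mean(replicate_pcts)
      if (p_value < 0.05) {
        classification <- if (m > baseline) "neuronal" else "glial"
      }
    }
  }
  structure(list(pct_elav = pct_elav, pct_repo = 100 - pct_elav,
                 n_labeled = n_lab, baseline_pct = baseline,
                 p_value = p_value, classification = classification,
                 n_dual_ties = ties, flags = flags),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  cat(sprintf("  %% Elav-colocalized: %.2f (baseline %.2f)\n",
              x$pct_elav, x$baseline_pct))
  cat(sprintf("  %% Repo-colocalized: %.2f\n", x$pct_repo))
  cat(sprintf("  labeled spots: %d (dual-match ties: %d)\n",
              x$n_labeled, x$n_dual_ties))
  cat(sprintf("  p = %s, classification: %s\n", format(x$p_value),
              x$classification))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Apply an exclusion mask to a spot set
#'
#' Removes spots falling inside excluded territory (e.g. the optic lobes)
#' before matching. The mask is a 3D binary array on the voxel grid; spots in
#' voxels where the mask is 1 are dropped.
#'
#' @param spots a \code{\link{spot_set}}.
#' @param exclusion 3D binary array (1 = excluded).
#' @param voxel_size_um (z, y, x) voxel size in um.
#' @return The filtered \code{spot_set}.
#' @export
exclude_spots <- function(spots, exclusion, voxel_size_um) {
  stopifnot(inherits(spots, "spot_set"), is.array(exclusion),
            length(dim(exclusion)) == 3L)
  if (nrow(spots$coords_um) == 0) return(spots)
  idx <- sweep(spots$coords_um, 2, voxel_size_um, "/")
  idx <- pmin(pmax(ceiling(idx), 1), matrix(rep(dim(exclusion),
              each = nrow(idx)), ncol = 3))
  drop <- exclusion[idx] > 0
  spot_set(spots$coords_um[!drop, , drop = FALSE], spots$channel)
}
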