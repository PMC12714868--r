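# Perinuclear (anti-HA) intensity quantification: nucleus masks from the
# nuclear-marker channels, a 3-px "surrounding" dilation, the shell ROI as
# surrounding minus nucleus, per-slice measurement and the pixel-weighted mean
# across slices. All morphology is 2D per slice, matching the slice-wise
# batch processing the measurements are defined by.

#' Binary mask stack
#'
#' @param data 3D array of 0/1 values aligned to one image channel.
#' @param kind one of "nucleus", "surrounding", "shell".
#' @param labels optional 3D integer array of per-slice object labels.
#' @return An object of class \code{mask_stack}.
#' @export
mask_stack <- function(data, kind = c("nucleus", "surrounding", "shell"),
                       labels = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("mask data must be a 3D (z, y, x) array")
  }
  if (!all(data %in% c(0, 1))) stop("mask values must be 0/1")
  structure(list(data = data, kind = kind, labels = labels),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("<mask_stack kind=%s> %s voxels on (%.2f%%)\n", x$kind,
              format(sum(x$data)), 100 * mean(x$data)))
  invisible(x)
}

#' Contrast normalization with tail saturation
#'
#' Linearly rescales a volume to [0, 1] so that \code{saturation_fraction} of
#' all voxels (split equally between the low and high tails) lie at or beyond
#' the clip points, mirroring an "enhance contrast with N\% saturated pixels"
#' step computed on the whole stack histogram. Monotone in input intensity;
#' with fraction 0 it is a pure min-max rescale.
#'
#' @param channel 3D (or 2D) numeric array.
#' @param saturation_fraction fraction in [0, 1).
#' @return Array of the same shape with values in [0, 1]. A constant input is
#'   returned unchanged with a warning (no dynamic range to stretch).
#' @export
normalize_contrast <- function(channel, saturation_fraction = 0.0035) {
  stopifnot(saturation_fraction >= 0, saturation_fraction < 1)
  v <- as.vector(channel)
  if (max(v) == min(v)) {
    warning("constant image: contrast normalization skipped")
    return(channel)
  }
  n <- length(v)
  k <- round(n * saturation_fraction / 2)
  if (k >= 1) {
    s <- sort(v, partial = c(k, n - k + 1L))
    lo <- s[k]; hi <- s[n - k + 1L]
  } else {
    lo <- min(v); hi <- max(v)
  }
  if (hi <= lo) {  # heavily tied histogram: fall back to min-max
    lo <- min(v); hi <- max(v)
  }
  out <- (channel - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# radius in um -> in-plane pixels, rounded half-up, at least 1
um_to_px <- function(radius_um, pixel_um) max(1L, as.integer(floor(radius_um / pixel_um + 0.5)))

disc_kernel <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

# zero pixels sitting on a boundary between two different nonzero labels,
# mimicking the one-pixel separation lines a binary watershed draws
split_label_boundaries <- function(lab) {
  if (max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  bnd <- matrix(FALSE, nr, nc)
  differs <- function(a, b) a > 0 & b > 0 & a != b
  bnd[-nr, ] <- bnd[-nr, ] | differs(lab[-nr, ], lab[-1, ])
  bnd[-1, ]  <- bnd[-1, ]  | differs(lab[-1, ], lab[-nr, ])
  bnd[, -nc] <- bnd[, -nc] | differs(lab[, -nc], lab[, -1])
  bnd[, -1]  <- bnd[, -1]  | differs(lab[, -1], lab[, -nc])
  lab[bnd] <- 0L
  lab
}

#' Nucleus mask from a nuclear-marker channel
#'
#' Per z-slice: Otsu threshold of the contrast-normalized slice (foreground =
#' above threshold), distance-transform watershed to split touching nuclei
#' (with one-pixel separation lines between objects), then a morphological
#' opening with an in-plane disc of radius \code{open_radius_um} (converted to
#' pixels, rounded half-up, minimum 1 px) to remove small particles.
#' Zero-variance slices yield empty masks.
#'
#' @param channel 3D (z, y, x) intensity array.
#' @param config an \code{\link{analysis_config}}.
#' @param voxel_size_um (z, y, x) voxel size in um.
#' @param normalize apply \code{\link{normalize_contrast}} to the whole stack
#'   first (default TRUE).
#' @return A \code{mask_stack} of kind "nucleus" carrying per-slice object
#'   labels in \code{$labels}.
#' @export
make_nucleus_mask <- function(channel, config = analysis_config(),
                              voxel_size_um = c(1, 0.5, 0.5),
                              normalize = TRUE) {
  stopifnot(is.array(channel), length(dim(channel)) == 3L)
  sq_log("make_nucleus_mask", config, channel)
  norm <- if (normalize) {
    suppressWarnings(normalize_contrast(channel, config$saturation_fraction))
  } else channel
  rng <- range(norm)
  if (rng[1] == rng[2]) {   # constant channel: nothing to segment
    return(mask_stack(array(0, dim = dim(channel)), "nucleus",
                      labels = array(0L, dim = dim(channel))))
  }
  # whole-stack Otsu as a floor for the per-slice thresholds: a slice holding
  # no nuclei, only background noise, must yield an empty mask instead of a
  # threshold that bisects the noise
  global_th <- EBImage::otsu(matrix(as.vector(norm), ncol = 1), range = rng)
  nz <- dim(channel)[1]
  open_px <- um_to_px(config$open_radius_um, voxel_size_um[3])
  kern <- disc_kernel(open_px)
  mask <- array(0, dim = dim(channel))
  labels <- array(0L, dim = dim(channel))
  for (z in seq_len(nz)) {
    s <- norm[z, , ]
    if (max(s) == min(s)) next
    th <- max(EBImage::otsu(s, range = rng), global_th)
    bin <- (s > th) * 1
    if (!any(bin > 0)) next
    lab <- EBImage::watershed(EBImage::distmap(bin), tolerance = 1, ext = 1)
    lab <- split_label_boundaries(EBImage::imageData(lab))
    bin <- (lab > 0) * 1
    opened <- EBImage::opening(bin, kern)
    opened <- (EBImage::imageData(opened) > 0) * 1
    mask[z, , ] <- opened
    labels[z, , ] <- EBImage::imageData(EBImage::bwlabel(opened))
  }
  mask_stack(mask, "nucleus", labels = labels)
}

#' Perinuclear shell mask
#'
#' Dilates the nucleus mask slice-wise by an in-plane disc of
#' \code{dilate_radius_px} pixels (the "surrounding" mask) and subtracts the
#' nucleus, leaving the annular shell where perinuclear signal is measured.
#' The shell is disjoint from the nucleus by construction.
#'
#' @param nucleus a \code{mask_stack} of kind "nucleus".
#' @param dilate_radius_px dilation radius in pixels (default 3).
#' @return A \code{mask_stack} of kind "shell"; the intermediate surrounding
#'   mask is attached as attribute \code{"surrounding"}.
#' @export
make_shell_mask <- function(nucleus, dilate_radius_px = 3) {
  stopifnot(inherits(nucleus, "mask_stack"))
  kern <- disc_kernel(dilate_radius_px)
  d <- dim(nucleus$data)
  surrounding <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    s <- nucleus$data[z, , ]
    if (!any(s > 0)) next
    surrounding[z, , ] <- (EBImage::imageData(EBImage::dilate(s, kern)) > 0) * 1
  }
  shell <- surrounding * (1 - nucleus$data)
  out <- mask_stack(shell, "shell")
  attr(out, "surrounding") <- mask_stack(surrounding, "surrounding")
  out
}

#' Per-slice measurement of an intensity channel over a shell ROI
#'
#' For each z-slice records the ROI pixel count and the arithmetic mean
#' intensity over the ROI (NA where the slice ROI is empty).
#'
#' @param intensity 3D (z, y, x) intensity array.
#' @param shell a \code{mask_stack}.
#' @param channel_name recorded label for the measured channel.
#' @return A \code{shell_measurement}: data.frame(z, pixel_count,
#'   mean_intensity) with the channel name as an attribute.
#' @export
measure_shell <- function(intensity, shell, channel_name = "HA") {
  stopifnot(inherits(shell, "mask_stack"),
            identical(dim(intensity), dim(shell$data)))
  nz <- dim(intensity)[1]
  counts <- integer(nz); means <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    m <- shell$data[z, , ] > 0
    counts[z] <- sum(m)
    if (counts[z] > 0) means[z] <- mean(intensity[z, , ][m])
  }
  out <- data.frame(z = seq_len(nz), pixel_count = counts,
                    mean_intensity = means)
  attr(out, "channel_measured") <- channel_name
  class(out) <- c("shell_measurement", "data.frame")
  out
}

#' Pixel-weighted mean intensity across slices
#'
#' Computes sum(pixel_count x slice mean) / sum(pixel_count) over all slices
#' with a nonempty ROI — algebraically identical to the plain mean over all
#' ROI voxels pooled across slices.
#'
#' @param m a \code{shell_measurement}.
#' @return The weighted mean (a.u.).
#' @examples
#' m <- data.frame(z = 1:2, pixel_count = c(10, 30), mean_intensity = c(2, 4))
#' class(m) <- c("shell_measurement", "data.frame")
#' weighted_mean(m)  # 3.5
#' @export
weighted_mean <- function(m) {
  stopifnot(inherits(m, "shell_measurement"))
  keep <- m$pixel_count > 0
  if (!any(keep)) stop("empty ROI: no slice has a positive pixel count")
  sum(m$pixel_count[keep] * m$mean_intensity[keep]) / sum(m$pixel_count[keep])
}

#' Neuron/glia perinuclear intensity ratio
#'
#' Builds nucleus and shell masks independently from the Elav (neuronal) and
#' Repo (glial) channels, measures the HA channel in each shell, and returns
#' the pixel-weighted means and their neuron/glia ratio. With
#' \code{exclusive = TRUE}, voxels inside the other class's surrounding mask
#' are removed from each shell before measurement; the default measures the
#' two shells independently (overlaps counted in both).
#'
#' @param stack an \code{image_stack} with channels named in \code{channels}.
#' @param config an \code{\link{analysis_config}}.
#' @param channels named character vector mapping roles ha/neuron/glia to
#'   channel names.
#' @param exclusive remove cross-class shell overlap before measuring.
#' @return A \code{shell_result}: weighted means per class, their ratio
#'   (NA and flagged when the glial shell is empty), and the per-slice
#'   measurements.
#' @export
shell_ratio <- function(stack, config = analysis_config(),
                        channels = c(ha = "HA", neuron = "Elav",
                                     glia = "Repo"),
                        exclusive = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  sq_log("shell_ratio", config, stack$data)
  ha <- get_channel(stack, channels[["ha"]])
  masks <- lapply(c(channels[["neuron"]], channels[["glia"]]), function(ch) {
    nuc <- make_nucleus_mask(get_channel(stack, ch), config,
                             stack$voxel_size_um)
    make_shell_mask(nuc, config$dilate_radius_px)
  })
  shell_n <- masks[[1]]; shell_g <- masks[[2]]
  if (exclusive) {
    surr_n <- attr(shell_n, "surrounding")$data
    surr_g <- attr(shell_g, "surrounding")$data
    shell_n <- mask_stack(shell_n$data * (1 - surr_g), "shell")
    shell_g <- mask_stack(shell_g$data * (1 - surr_n), "shell")
  }
  m_n <- measure_shell(ha, shell_n, channels[["ha"]])
  m_g <- measure_shell(ha, shell_g, channels[["ha"]])
  flags <- character()
  neuron_mean <- if (any(m_n$pixel_count > 0)) weighted_mean(m_n) else NA_real_
  glia_mean <- if (any(m_g$pixel_count > 0)) weighted_mean(m_g) else NA_real_
  if (is.na(neuron_mean)) flags <- c(flags, "empty neuronal shell")
  ratio <- NA_real_
  if (is.na(glia_mean) || glia_mean <= 0) {
    flags <- c(flags, "ratio undefined: empty or zero glial shell")
  } else if (!is.na(neuron_mean)) {
    ratio <- neuron_mean / glia_mean
  }
  structure(list(neuron_mean = neuron_mean, glia_mean = glia_mean,
                 ratio_neuron_to_glia = ratio, flags = flags,
                 neuron_measurement = m_n, glia_measurement = m_g),
            class = "shell_result")
}

#' @export
print.shell_result <- function(x, ...) {
  cat("<shell_result>\n")
  cat(sprintf("  neuron shell mean: %s\n", format(x$neuron_mean)))
  cat(sprintf("  glia shell mean:   %s\n", format(x$glia_mean)))
  cat(sprintf("  neuron/glia ratio: %s\n", format(x$ratio_neuron_to_glia)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
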