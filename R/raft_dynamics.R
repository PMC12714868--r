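# Lipid-raft biosensor readouts: mean OlyA(w) intensity over the blurred,
# thresholded Elav cortical mask, and the acceptor-photobleaching FRET step
# summary (donor dequenching after the bleach between acquisition points).

#' OlyA(w) mean intensity over the Elav-derived cortical mask
#'
#' Blurs the Elav channel slice-wise with a Gaussian of sigma
#' \code{blur_sigma_px} pixels, thresholds each slice with Otsu, and returns
#' the mean of the biosensor channel over the pooled mask voxels. The result
#' depends on the Elav channel only through the thresholded mask.
#'
#' @param stack an \code{image_stack} containing the biosensor and Elav
#'   channels.
#' @param config an \code{\link{analysis_config}} (supplies blur_sigma_px).
#' @param channels named character vector mapping roles olya/elav to channel
#'   names.
#' @return Mean biosensor intensity over the mask (a.u.).
#' @export
olya_cortex_mean <- function(stack, config = analysis_config(),
                             channels = c(olya = "OlyA", elav = "Elav")) {
  stopifnot(inherits(stack, "image_stack"))
  sq_log("olya_cortex_mean", config, stack$data)
  olya <- get_channel(stack, channels[["olya"]])
  elav <- get_channel(stack, channels[["elav"]])
  d <- dim(elav)
  vals <- numeric(0)
  for (z in seq_len(d[1])) {
    s <- elav[z, , ]
    sm <- EBImage::imageData(EBImage::gblur(s, sigma = config$blur_sigma_px))
    if (max(sm) == min(sm)) next
    th <- EBImage::otsu(sm, range = range(sm))
    m <- sm > th
    if (any(m)) vals <- c(vals, olya[z, , ][m])
  }
  if (length(vals) == 0) stop("empty cortical mask")
  mean(vals)
}

#' Acceptor-photobleaching FRET time series
#'
#' @param times_s strictly increasing acquisition times in seconds (default
#'   spacing 5 s).
#' @param roi_mean mean donor (OlyA) ROI intensity at each time point.
#' @param bleach_after_index 1-based index of the last pre-bleach point; the
#'   acceptor is bleached between this point and the next (default 3).
#' @return An object of class \code{fret_series}.
#' @export
fret_series <- function(times_s, roi_mean, bleach_after_index = 3L) {
  stopifnot(length(times_s) == length(roi_mean),
            all(diff(times_s) > 0),
            bleach_after_index >= 1,
            bleach_after_index < length(roi_mean))
  structure(list(times_s = as.numeric(times_s),
                 roi_mean = as.numeric(roi_mean),
                 bleach_after_index = as.integer(bleach_after_index)),
            class = "fret_series")
}

#' Donor intensity response to acceptor photobleaching
#'
#' Averages the ROI intensity before and after the bleach point and reports
#' the relative change; a positive \code{delta_rel} (donor dequenching) is the
#' FRET signature of molecular proximity between donor and acceptor.
#'
#' @param s a \code{\link{fret_series}}.
#' @return list(pre_mean, post_mean, delta_rel) where
#'   delta_rel = (post_mean - pre_mean) / pre_mean.
#' @examples
#' s <- fret_series(seq(0, 25, 5), c(10, 10, 10, 12, 12, 12))
#' fret_response(s)$delta_rel  # 0.2
#' @export
fret_response <- function(s) {
  stopifnot(inherits(s, "fret_series"))
  b <- s$bleach_after_index
  pre <- mean(s$roi_mean[seq_len(b)])
  post <- mean(s$roi_mean[(b + 1):length(s$roi_mean)])
  if (pre == 0) stop("pre-bleach mean is zero: relative change undefined")
  list(pre_mean = pre, post_mean = post, delta_rel = (post - pre) / pre)
}
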