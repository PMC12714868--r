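#' Multichannel 3D image stack with physical voxel sizes
#'
#' Container for a confocal stack: a 4D non-negative intensity array indexed
#' (channel, z, y, x) plus channel names and the (z, y, x) voxel size in um.
#' The z spacing is typically coarser than the in-plane pixel size (e.g. 1 um
#' sections, 0.5 um pixels); all physical distances in the package respect
#' this anisotropy.
#'
#' @param data 4D numeric array, dimensions (channel, z, y, x), non-negative.
#' @param channel_names character vector, one unique name per channel.
#' @param voxel_size_um numeric triple (z, y, x) of strictly positive um.
#' @return An object of class \code{image_stack}.
#' @examples
#' a <- array(0, dim = c(2, 3, 8, 8))
#' s <- image_stack(a, c("HA", "Elav"), c(1, 0.5, 0.5))
#' dim(s$data)
#' @export
image_stack <- function(data, channel_names, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("data must be a 4D array indexed (channel, z, y, x)")
  }
  if (any(data < 0)) stop("intensities must be non-negative")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[1L]) {
    stop("channel_names length must equal the number of channels")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be a strictly positive (z, y, x) triple")
  }
  structure(list(data = data,
                 channel_names = channel_names,
                 voxel_size_um = voxel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d channel(s) [%s], z=%d, y=%d, x=%d\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel size (z,y,x) um: %s\n",
              paste(format(x$voxel_size_um), collapse = " x ")))
  invisible(x)
}

#' Extract one channel of a stack as a 3D (z, y, x) array
#'
#' @param stack an \code{image_stack}.
#' @param channel channel name.
#' @return 3D numeric array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(channel, stack$channel_names)
  if (is.na(i)) {
    stop("channel not found: ", channel, " (have: ",
         paste(stack$channel_names, collapse = ", "), ")")
  }
  arr <- stack$data[i, , , , drop = FALSE]
  dim(arr) <- dim(stack$data)[2:4]
  arr
}

#' Read a multichannel stack from a multi-page TIFF
#'
#' Pages are interpreted z-major, channel-minor: for each z slice all channels
#' follow in order before the next slice. Integer-valued 8/16-bit data are
#' preserved bit-exactly; 32-bit pages are read as floats.
#'
#' @param path TIFF file with at least one page; the page count must be a
#'   multiple of the channel count.
#' @param channel_names channel names in page order within each slice.
#' @param voxel_size_um (z, y, x) voxel size in um.
#' @return An \code{image_stack}.
#' @export
read_stack <- function(path, channel_names, voxel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # scaled [0,1] reads are rescaled back to raw integer counts for 8/16-bit
  # pages (bit-exact); 32-bit float pages are kept as stored
  pages <- lapply(pages, function(p) {
    bps <- attr(p, "bits.per.sample")
    if (!is.null(bps) && bps %in% c(8L, 16L)) round(p * (2^bps - 1)) else p
  })
  n_chan <- length(channel_names)
  if (length(pages) %% n_chan != 0L) {
    stop(sprintf("page count (%d) is not a multiple of channel count (%d)",
                 length(pages), n_chan))
  }
  nz <- length(pages) %/% n_chan
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  data <- array(0, dim = c(n_chan, nz, ny, nx))
  for (z in seq_len(nz)) {
    for (c in seq_len(n_chan)) {
      data[c, z, , ] <- pages[[(z - 1L) * n_chan + c]]
    }
  }
  image_stack(data, channel_names, voxel_size_um)
}

#' Write a stack to a multi-page TIFF
#'
#' The inverse of \code{\link{read_stack}} (same z-major, channel-minor page
#' order). With \code{bits_per_sample} 8 or 16 the data must be integer-valued
#' within the dtype range and round trip bit-exactly; 32 writes floats, which
#' must already lie in [0, 1] (the TIFF float convention).
#'
#' @param stack an \code{image_stack}.
#' @param path output path.
#' @param bits_per_sample 8, 16 or 32.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!bits_per_sample %in% c(8L, 16L, 32L)) {
    stop("bits_per_sample must be 8, 16 or 32")
  }
  d <- dim(stack$data)
  if (bits_per_sample == 32L) {
    top <- 1
    if (max(stack$data) > 1) stop("32-bit float output requires data in [0, 1]")
  } else {
    top <- 2^bits_per_sample - 1
    if (max(stack$data) > top) {
      stop("intensities exceed the ", bits_per_sample, "-bit range")
    }
    if (any(stack$data != round(stack$data))) {
      stop("integer TIFF output requires integer-valued intensities")
    }
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (z in seq_len(d[2])) {
    for (c in seq_len(d[1])) {
      pages[[k]] <- matrix(stack$data[c, z, , ] / top, nrow = d[3])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}
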