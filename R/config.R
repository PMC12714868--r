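#' Analysis configuration
#'
#' Central registry of the tunable constants used across the quantification
#' stages. Every parameter has the default used throughout the study design:
#' contrast saturation 0.35\% of voxels, morphological opening radius 0.5 um,
#' nucleus-mask dilation 3 px, colocalization radius 2 um, neuronal baseline
#' 89.56\% (fraction of Elav nuclei among all labeled nuclei), Gaussian blur
#' sigma 2 px for the cortical Elav mask, sphingolipid abundance floor
#' 0.01 ng/brain, phospholipid cumulative-abundance coverage 0.995, and the
#' volcano significance rule (BH-adjusted P < 0.05 and fold change beyond
#' 1.5-fold in either direction).
#'
#' @param saturation_fraction fraction of voxels saturated by contrast
#'   normalization, split between the low and high tails; in [0, 1).
#' @param open_radius_um in-plane radius (um) of the morphological opening
#'   that removes small particles from nucleus masks.
#' @param dilate_radius_px in-plane radius (pixels) of the dilation producing
#'   the "surrounding" mask around each nucleus.
#' @param coloc_radius_um distance threshold (um) below or at which two spots
#'   are considered colocalized.
#' @param elav_baseline_pct percentage of neuronal (Elav) nuclei among all
#'   labeled nuclei expected for a gene with no cell-type enrichment.
#' @param blur_sigma_px Gaussian blur sigma (pixels) applied to the Elav
#'   channel before thresholding the cortical region of interest.
#' @param sphingolipid_min_ng minimum mean control abundance (ng/brain) for a
#'   sphingolipid species to be retained.
#' @param phospholipid_top_fraction cumulative control-abundance coverage
#'   defining the retained most-abundant phospholipid species.
#' @param volcano_p adjusted-P threshold of the volcano significance rule.
#' @param volcano_fc fold-change threshold (>= 1) of the volcano rule; a
#'   species passes when its fold change exceeds the threshold in either
#'   direction (FC > volcano_fc or FC < 1/volcano_fc).
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return An object of class \code{analysis_config} (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$coloc_radius_um
#' @export
analysis_config <- function(saturation_fraction = 0.0035,
                            open_radius_um = 0.5,
                            dilate_radius_px = 3,
                            coloc_radius_um = 2.0,
                            elav_baseline_pct = 89.56,
                            blur_sigma_px = 2,
                            sphingolipid_min_ng = 0.01,
                            phospholipid_top_fraction = 0.995,
                            volcano_p = 0.05,
                            volcano_fc = 1.5,
                            rng_seed = 1L) {
  cfg <- list(
    saturation_fraction = saturation_fraction,
    open_radius_um = open_radius_um,
    dilate_radius_px = dilate_radius_px,
    coloc_radius_um = coloc_radius_um,
    elav_baseline_pct = elav_baseline_pct,
    blur_sigma_px = blur_sigma_px,
    sphingolipid_min_ng = sphingolipid_min_ng,
    phospholipid_top_fraction = phospholipid_top_fraction,
    volcano_p = volcano_p,
    volcano_fc = volcano_fc,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(
    "saturation_fraction must be in [0,1)" =
      num1(cfg$saturation_fraction) &&
      cfg$saturation_fraction >= 0 && cfg$saturation_fraction < 1,
    "open_radius_um must be positive" =
      num1(cfg$open_radius_um) && cfg$open_radius_um > 0,
    "dilate_radius_px must be positive" =
      num1(cfg$dilate_radius_px) && cfg$dilate_radius_px > 0,
    "coloc_radius_um must be positive" =
      num1(cfg$coloc_radius_um) && cfg$coloc_radius_um > 0,
    "elav_baseline_pct must be in (0,100)" =
      num1(cfg$elav_baseline_pct) &&
      cfg$elav_baseline_pct > 0 && cfg$elav_baseline_pct < 100,
    "blur_sigma_px must be positive" =
      num1(cfg$blur_sigma_px) && cfg$blur_sigma_px > 0,
    "sphingolipid_min_ng must be positive" =
      num1(cfg$sphingolipid_min_ng) && cfg$sphingolipid_min_ng > 0,
    "phospholipid_top_fraction must be in (0,1]" =
      num1(cfg$phospholipid_top_fraction) &&
      cfg$phospholipid_top_fraction > 0 && cfg$phospholipid_top_fraction <= 1,
    "volcano_p must be in (0,1)" =
      num1(cfg$volcano_p) && cfg$volcano_p > 0 && cfg$volcano_p < 1,
    "volcano_fc must be >= 1" = num1(cfg$volcano_fc) && cfg$volcano_fc >= 1
  )
  invisible(cfg)
}

#' Load an analysis configuration from a JSON file
#'
#' Keys absent from the file take their defaults (see
#' \code{\link{analysis_config}}); unknown keys are an error so that typos
#' cannot silently fall back to defaults.
#'
#' @param path path to a JSON file of scalar key-value pairs, or \code{NULL}
#'   for the all-defaults configuration.
#' @return An \code{analysis_config}.
#' @examples
#' load_config(NULL)$coloc_radius_um  # 2.0
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(analysis_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to a JSON file
#'
#' Round trips with \code{\link{load_config}} field-for-field.
#'
#' @param cfg an \code{analysis_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Opt-in stage logging: emits the stage name, a config snapshot and a content
# checksum so a run can be reconstructed from its log.
sq_log <- function(stage, cfg = NULL, data = NULL) {
  if (!isTRUE(getOption("sphingoquant.verbose", FALSE))) return(invisible())
  msg <- paste0("[sphingoquant] stage=", stage)
  if (!is.null(cfg)) {
    msg <- paste0(msg, " config=",
                  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  }
  if (!is.null(data)) {
    v <- as.numeric(data)
    v <- v[is.finite(v)]
    msg <- paste0(msg, sprintf(" checksum=%.6g n=%d", sum(v), length(v)))
  }
  message(msg)
  invisible()
}
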