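# Per-neuropil expression profiling from a pre-warped intensity volume and an
# integer label map: mean intensity per voxel per region, gene-mean row
# normalization, Ward-D2 clustering of genes and regions, and the region
# correlation matrix. Registration/warping happens upstream; this module's
# contract starts at the warped volume.

#' Region label map
#'
#' @param labels 3D integer array; 0 marks voxels outside every region.
#' @param region_names named character vector or list mapping label id (as
#'   character) to region name; every nonzero label in \code{labels} must be
#'   named.
#' @param excluded character vector of region names excluded from analysis
#'   (e.g. optic-lobe neuropils imaged incompletely).
#' @return An object of class \code{region_label_map}.
#' @export
region_label_map <- function(labels, region_names, excluded = character()) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  region_names <- unlist(region_names)
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  missing <- setdiff(as.character(ids), names(region_names))
  if (length(missing)) {
    stop("unnamed label id(s): ", paste(missing, collapse = ", "))
  }
  if (!all(excluded %in% region_names)) {
    stop("excluded regions must be named regions")
  }
  structure(list(labels = labels, region_names = region_names,
                 excluded = excluded),
            class = "region_label_map")
}

#' Mean intensity per voxel for each region
#'
#' For each non-excluded region: the sum of intensity over the region's voxels
#' divided by the region's voxel count (intensity normalized to region size).
#' Regions present in the name map but absent from the volume are returned as
#' NA with a warning.
#'
#' @param intensity 3D (z, y, x) intensity array, same shape as the label map.
#' @param map a \code{\link{region_label_map}}.
#' @return Named numeric vector of region means (a.u./voxel).
#' @export
region_means <- function(intensity, map) {
  stopifnot(inherits(map, "region_label_map"),
            identical(dim(intensity), dim(map$labels)))
  keep_names <- setdiff(unname(map$region_names), map$excluded)
  lab <- as.vector(map$labels)
  inside <- lab != 0
  sums <- rowsum(as.vector(intensity)[inside], lab[inside])
  counts <- rowsum(rep(1, sum(inside)), lab[inside])
  means_by_id <- setNames(as.vector(sums / counts), rownames(sums))
  out <- rep(NA_real_, length(keep_names))
  names(out) <- keep_names
  for (id in names(map$region_names)) {
    nm <- map$region_names[[id]]
    if (nm %in% keep_names && id %in% names(means_by_id)) {
      out[nm] <- means_by_id[[id]]
    }
  }
  if (anyNA(out)) {
    warning("region(s) with zero voxels: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Genes x regions expression matrix
#'
#' @param values numeric matrix, genes in rows, regions in columns, entries
#'   are mean intensity per voxel.
#' @param normalized whether rows have already been gene-mean normalized.
#' @return An object of class \code{region_expression_matrix}.
#' @export
region_expression_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("region", seq_len(ncol(values)))
  }
  structure(list(values = values, normalized = normalized),
            class = "region_expression_matrix")
}

#' Gene-mean normalization of an expression matrix
#'
#' Divides each gene's row by its mean across regions, so expression levels
#' are comparable across genes of very different absolute reporter intensity;
#' row means become 1. Idempotent.
#'
#' @param m a \code{\link{region_expression_matrix}}.
#' @return The normalized matrix (\code{normalized = TRUE}).
#' @export
normalize_rows <- function(m) {
  stopifnot(inherits(m, "region_expression_matrix"))
  rm <- rowMeans(m$values)
  if (any(rm <= 0)) stop("every gene row must have a positive mean")
  region_expression_matrix(m$values / rm, normalized = TRUE)
}

#' Ward-D2 clustering of genes or regions
#'
#' Agglomerative clustering with the Ward-D2 criterion: on Euclidean distances
#' between gene rows (\code{axis = "genes"}), or on 1 - Pearson correlation
#' distances between region expression profiles (\code{axis = "regions"}).
#' Deterministic given the input.
#'
#' @param m a \code{\link{region_expression_matrix}}.
#' @param axis "genes" or "regions".
#' @return list(hclust = stats::hclust tree, order = leaf order, labels =
#'   leaf labels, newick = Newick string of the dendrogram).
#' @export
cluster_heatmap <- function(m, axis = c("genes", "regions")) {
  stopifnot(inherits(m, "region_expression_matrix"))
  axis <- match.arg(axis)
  if (axis == "genes") {
    if (nrow(m$values) < 2) stop("need >= 2 genes to cluster")
    d <- stats::dist(m$values)
    labs <- rownames(m$values)
  } else {
    if (ncol(m$values) < 2) stop("need >= 2 regions to cluster")
    if (any(apply(m$values, 2, stats::sd) == 0)) {
      stop("constant region profile: correlation distance undefined")
    }
    d <- stats::as.dist(1 - stats::cor(m$values))
    labs <- colnames(m$values)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = hc$order, labels = labs[hc$order],
       newick = newick)
}

#' Pairwise Pearson correlation between region expression profiles
#'
#' Correlates the per-gene expression profiles of every pair of regions;
#' symmetric with unit diagonal, entries in [-1, 1].
#'
#' @param m a \code{\link{region_expression_matrix}} with >= 2 genes.
#' @return regions x regions correlation matrix.
#' @export
region_correlation <- function(m) {
  stopifnot(inherits(m, "region_expression_matrix"))
  if (nrow(m$values) < 2) stop("need >= 2 genes for region correlations")
  if (any(apply(m$values, 2, stats::sd) == 0)) {
    stop("constant region column: correlation undefined")
  }
  stats::cor(m$values)
}

#' Heatmap of a region expression or correlation matrix
#'
#' Thin wrapper over \pkg{pheatmap} (suggested) with Ward-D2 clustering,
#' matching the package's dendrogram functions. Purely presentational.
#'
#' @param m a \code{\link{region_expression_matrix}} or a correlation matrix.
#' @param ... passed to \code{pheatmap::pheatmap}.
#' @return The pheatmap object, invisibly.
#' @export
plot_region_heatmap <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_region_heatmap requires the pheatmap package")
  }
  vals <- if (inherits(m, "region_expression_matrix")) m$values else m
  p <- pheatmap::pheatmap(vals, clustering_method = "ward.D2", silent = TRUE,
                          ...)
  invisible(p)
}
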