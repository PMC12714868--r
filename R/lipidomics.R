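# Brain lipidomics statistics: abundance filters, fold change relative to the
# control genotype, per-headgroup z-scored PCA, and the BH-corrected volcano
# classification (adjusted P < 0.05 and fold change beyond 1.5-fold).

SPHINGO_HEADGROUPS <- c("Cer", "CerPE", "GlcCer")
PHOSPHO_HEADGROUPS <- c("PS", "PI", "PC", "PE")

#' Validate a lipid abundance table
#'
#' @param x data.frame with columns species, headgroup, genotype, replicate,
#'   ng_per_brain. (species, genotype, replicate) must be unique, the
#'   headgroup must be consistent per species and abundances non-negative.
#' @return \code{x} with class \code{c("lipid_table", "data.frame")}.
#' @export
lipid_table <- function(x) {
  need <- c("species", "headgroup", "genotype", "replicate", "ng_per_brain")
  if (!all(need %in% names(x))) {
    stop("lipid table needs columns: ", paste(need, collapse = ", "))
  }
  hg_all <- c(SPHINGO_HEADGROUPS, PHOSPHO_HEADGROUPS)
  if (!all(x$headgroup %in% hg_all)) {
    stop("headgroup must be one of: ", paste(hg_all, collapse = ", "))
  }
  if (any(x$ng_per_brain < 0)) stop("abundances must be >= 0")
  key <- paste(x$species, x$genotype, x$replicate)
  if (anyDuplicated(key)) stop("(species, genotype, replicate) must be unique")
  hg_per_sp <- tapply(x$headgroup, x$species, function(h) length(unique(h)))
  if (any(hg_per_sp > 1)) stop("headgroup must be consistent per species")
  class(x) <- unique(c("lipid_table", class(x)))
  x
}

control_means <- function(t, control_genotype) {
  ctl <- t[t$genotype == control_genotype, ]
  if (nrow(ctl) == 0) stop("control genotype not found: ", control_genotype)
  tapply(ctl$ng_per_brain, ctl$species, mean)
}

#' Abundance filtering of lipid species
#'
#' Sphingolipid species (Cer, CerPE, GlcCer) are kept when their mean control
#' abundance exceeds \code{sphingolipid_min_ng} (0.01 ng/brain by default).
#' Phospholipid species (PS, PI, PC, PE) are kept when they belong to the
#' smallest set of most-abundant species whose cumulative control abundance
#' reaches \code{phospholipid_top_fraction} (99.5\%) of the total phospholipid
#' signal; species tied in abundance with the last retained one are all kept.
#'
#' @param t a \code{\link{lipid_table}}.
#' @param config an \code{\link{analysis_config}}.
#' @param control_genotype genotype defining the reference abundances.
#' @return The filtered \code{lipid_table}.
#' @export
filter_species <- function(t, config = analysis_config(),
                           control_genotype = "control") {
  t <- lipid_table(t)
  sq_log("filter_species", config, t$ng_per_brain)
  cm <- control_means(t, control_genotype)
  hg <- tapply(t$headgroup, t$species, function(h) h[1])[names(cm)]
  keep <- character()

  sph <- names(cm)[hg %in% SPHINGO_HEADGROUPS]
  keep <- c(keep, sph[cm[sph] > config$sphingolipid_min_ng])

  pho <- names(cm)[hg %in% PHOSPHO_HEADGROUPS]
  if (length(pho)) {
    ab <- sort(cm[pho], decreasing = TRUE)
    cum <- cumsum(ab) / sum(ab)
    k <- which(cum >= config$phospholipid_top_fraction)[1]
    cutoff <- ab[k]
    keep <- c(keep, names(ab)[ab >= cutoff])  # ties with the last kept stay
  }
  out <- t[t$species %in% keep, ]
  rownames(out) <- NULL
  lipid_table(out)
}

#' Per-species fold change relative to the control genotype
#'
#' Each test replicate is divided by the mean of the control replicates; the
#' summary fold change per species is the mean of these per-replicate ratios
#' (matching error bars drawn over per-replicate normalized values). The
#' ratio-of-means alternative is available via \code{summary = "ratio_of_means"}.
#'
#' @param t a \code{\link{lipid_table}}.
#' @param control_genotype,test_genotype genotype labels, both present.
#' @param summary "mean_of_ratios" (default) or "ratio_of_means".
#' @return data.frame(species, headgroup, fold_change).
#' @export
fold_change <- function(t, control_genotype = "control",
                        test_genotype = "mutant",
                        summary = c("mean_of_ratios", "ratio_of_means")) {
  t <- lipid_table(t)
  summary <- match.arg(summary)
  cm <- control_means(t, control_genotype)
  if (any(cm == 0)) {
    stop("zero control mean for species: ",
         paste(names(cm)[cm == 0], collapse = ", "))
  }
  tst <- t[t$genotype == test_genotype, ]
  if (nrow(tst) == 0) stop("test genotype not found: ", test_genotype)
  sp <- names(cm)
  fc <- vapply(sp, function(s) {
    x <- tst$ng_per_brain[tst$species == s]
    if (length(x) == 0) return(NA_real_)
    if (summary == "mean_of_ratios") mean(x / cm[[s]]) else mean(x) / cm[[s]]
  }, numeric(1))
  hg <- tapply(t$headgroup, t$species, function(h) h[1])[sp]
  data.frame(species = sp, headgroup = unname(hg), fold_change = unname(fc),
             row.names = NULL)
}

#' Principal component analysis of one headgroup's species profile
#'
#' Builds the samples x species abundance matrix for the headgroup (samples =
#' genotype/replicate combinations), z-scores each species column across
#' samples (zero-variance columns are dropped with a warning), and computes
#' principal components. Component signs are fixed by making each component's
#' largest-magnitude loading positive, so results are reproducible across
#' eigensolvers.
#'
#' @param t a \code{\link{lipid_table}}.
#' @param headgroup one headgroup name.
#' @return list(scores = samples x components matrix,
#'   variance_fractions (sums to 1), loadings, samples = data.frame of
#'   genotype/replicate per score row).
#' @export
headgroup_pca <- function(t, headgroup) {
  t <- lipid_table(t)
  sub <- t[t$headgroup == headgroup, ]
  if (nrow(sub) == 0) stop("no species with headgroup ", headgroup)
  sub$sample <- paste(sub$genotype, sub$replicate, sep = "_")
  m <- tapply(sub$ng_per_brain, list(sub$sample, sub$species), mean)
  if (anyNA(m)) stop("unbalanced table: missing species x sample cells")
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need >= 2 samples and >= 2 species for PCA")
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance species column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 species with variance")
  }
  z <- scale(m, center = TRUE, scale = TRUE)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  vf <- ev / sum(ev)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  meta <- do.call(rbind, strsplit(rownames(m), "_(?=[^_]+$)", perl = TRUE))
  list(scores = pc$x, variance_fractions = vf, loadings = pc$rotation,
       samples = data.frame(sample = rownames(m), genotype = meta[, 1],
                            replicate = meta[, 2]))
}

# vectorized equal-variance (or Welch) two-sample t-test over matrix rows
row_t_test <- function(X, Y, welch = FALSE) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- apply(X, 1, stats::var); vy <- apply(Y, 1, stats::var)
  if (welch) {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    tstat <- (mx - my) / sqrt(se2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- rep(nx + ny - 2, length(mx))
    tstat <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate zero-variance rows: equal means are the null exactly
  zero <- is.na(tstat) | !is.finite(tstat)
  p[zero & mx == my] <- 1
  p[zero & mx != my] <- 0
  tstat[zero] <- ifelse(mx[zero] == my[zero], 0, Inf * sign((mx - my)[zero]))
  list(statistic = tstat, df = df, p_value = p)
}

#' Volcano classification of lipid species
#'
#' Per species: a two-tailed unpaired t-test (equal-variance by default,
#' Welch behind a flag) between control and test abundances,
#' Benjamini-Hochberg adjustment across all tested species, and the
#' significance rule: adjusted P < \code{volcano_p} and fold change beyond
#' \code{volcano_fc}-fold in either direction (|log2 FC| > log2 volcano_fc).
#'
#' @param t a \code{\link{lipid_table}} (typically already filtered).
#' @param control_genotype,test_genotype genotype labels.
#' @param config an \code{\link{analysis_config}}.
#' @param welch use the Welch (unequal variance) t-test.
#' @param log_abundance t-test log-transformed abundances (default: raw
#'   ng/brain).
#' @return data.frame(species, headgroup, log2_fc, p_raw, p_adj, significant),
#'   class \code{volcano_table}.
#' @export
volcano <- function(t, control_genotype = "control",
                    test_genotype = "mutant",
                    config = analysis_config(), welch = FALSE,
                    log_abundance = FALSE) {
  t <- lipid_table(t)
  sq_log("volcano", config, t$ng_per_brain)
  ctl <- t[t$genotype == control_genotype, ]
  tst <- t[t$genotype == test_genotype, ]
  sp <- sort(unique(t$species))
  to_matrix <- function(d) {
    m <- tapply(d$ng_per_brain, list(d$species, d$replicate), mean)
    m[sp, , drop = FALSE]
  }
  X <- to_matrix(tst); Y <- to_matrix(ctl)
  if (anyNA(X) || anyNA(Y)) stop("need >= 2 replicates per genotype per species")
  if (ncol(X) < 2 || ncol(Y) < 2) stop("need >= 2 replicates per genotype")
  tt <- if (log_abundance) row_t_test(log(X), log(Y), welch) else
    row_t_test(X, Y, welch)
  p_adj <- stats::p.adjust(tt$p_value, method = "BH")
  fc <- fold_change(t, control_genotype, test_genotype)
  fc <- fc[match(sp, fc$species), ]
  log2_fc <- log2(fc$fold_change)
  significant <- p_adj < config$volcano_p &
    abs(log2_fc) > log2(config$volcano_fc)
  out <- data.frame(species = sp, headgroup = fc$headgroup,
                    log2_fc = log2_fc, p_raw = tt$p_value, p_adj = p_adj,
                    significant = significant, row.names = NULL)
  class(out) <- c("volcano_table", "data.frame")
  out
}

#' Volcano plot
#'
#' log2 fold change against -log10 adjusted P, significant species
#' highlighted. Base graphics; purely presentational.
#'
#' @param x a \code{volcano_table}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.volcano_table <- function(x, ...) {
  cols <- ifelse(x$significant, "firebrick", "grey50")
  graphics::plot(x$log2_fc, -log10(x$p_adj), pch = 19, col = cols,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ "adjusted P"), ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  graphics::abline(v = c(-log2(1.5), log2(1.5)), lty = 2)
  invisible(x)
}
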