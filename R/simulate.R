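# Seeded ground-truth generators for every quantification stage. All
# generators are pure functions of their arguments (the seed included): the
# RNG state of the caller is saved and restored.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Parameters of the synthetic brain-stack generator
#'
#' Describes a field of non-overlapping ellipsoidal nuclei of two classes
#' (neurons marked by Elav, glia by Repo) at the 89.56:10.44 class ratio
#' observed across adult central brains, each wrapped in a perinuclear shell
#' of class-specific reporter (HA) intensity, plus a nuclear-spot (mCherry)
#' channel. Nucleus radii are jittered per axis by +/-20\%.
#'
#' @param shape_zyx voxel dimensions (z, y, x).
#' @param voxel_size_um (z, y, x) voxel size in um (default 1 x 0.5 x 0.5,
#'   i.e. 1-um optical sections with 0.5-um pixels).
#' @param n_nuclei number of nuclei to place.
#' @param neuron_fraction expected fraction of neuronal nuclei (default
#'   0.8956).
#' @param nucleus_radius_um mean nucleus radius in um.
#' @param shell_thickness_um thickness of the rendered perinuclear shell (um).
#' @param shell_intensity_neuron,shell_intensity_glia HA shell amplitude
#'   (a.u.) around neuronal / glial nuclei.
#' @param nucleus_intensity amplitude (a.u.) of the Elav/Repo nuclear fill.
#'   Nuclear-marker immunostains are high-contrast relative to background and
#'   to reporter noise; the default models a bright stain (SNR ~100 over the
#'   default background).
#' @param spot_coloc_neuron_fraction fraction of mCherry spots placed on
#'   neuronal nuclei (the rest go to glial nuclei).
#' @param n_spots number of mCherry spots (default: one per nucleus up to
#'   the available nuclei of each class).
#' @param background additive background level (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.), clipped at zero.
#' @param min_gap_um minimum gap between nucleus surfaces; the default of
#'   twice the shell thickness keeps neighbouring shells disjoint so that the
#'   neuron/glia intensity ratio is identifiable.
#' @param seed integer seed.
#' @return A validated parameter list of class \code{brain_sim_params}.
#' @export
brain_sim_params <- function(shape_zyx = c(16L, 96L, 96L),
                             voxel_size_um = c(1, 0.5, 0.5),
                             n_nuclei = 25L,
                             neuron_fraction = 0.8956,
                             nucleus_radius_um = 2,
                             shell_thickness_um = 1.5,
                             shell_intensity_neuron = 200,
                             shell_intensity_glia = 100,
                             nucleus_intensity = 1000,
                             spot_coloc_neuron_fraction = 0.8956,
                             n_spots = NULL,
                             background = 10,
                             noise_sd = 0,
                             min_gap_um = 2 * shell_thickness_um,
                             seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    length(p$shape_zyx) == 3L, all(p$shape_zyx >= 4),
    length(p$voxel_size_um) == 3L, all(p$voxel_size_um > 0),
    p$n_nuclei >= 1,
    p$neuron_fraction >= 0, p$neuron_fraction <= 1,
    p$nucleus_radius_um > 0, p$shell_thickness_um > 0,
    p$shell_intensity_neuron >= 0, p$shell_intensity_glia >= 0,
    p$nucleus_intensity > 0,
    p$spot_coloc_neuron_fraction >= 0, p$spot_coloc_neuron_fraction <= 1,
    p$background >= 0, p$noise_sd >= 0, p$min_gap_um >= 0
  )
  class(p) <- "brain_sim_params"
  p
}

# voxel-center coordinates (um) along one axis
axis_um <- function(n, step) (seq_len(n) - 0.5) * step

#' Simulate a 4-channel brain stack with ground truth
#'
#' Renders channels HA (perinuclear shells of class-specific intensity over
#' background), Elav (filled neuronal nuclei), Repo (filled glial nuclei) and
#' mCherry (one Gaussian blob per chosen nucleus), plus clipped additive
#' Gaussian noise. Nuclei are axis-aligned ellipsoids placed by rejection
#' sampling; placement fails with an error if the field cannot accommodate
#' them.
#'
#' @param params a \code{\link{brain_sim_params}}.
#' @return \code{list(stack = image_stack, truth = list(...))}; the truth
#'   carries nucleus centers (um), classes, the true neuron/glia shell
#'   intensity ratio and the spot-to-nucleus assignments.
#' @export
simulate_brain_stack <- function(params) {
  stopifnot(inherits(params, "brain_sim_params"))
  p <- params
  with_seed(p$seed, {
    nz <- p$shape_zyx[1]; ny <- p$shape_zyx[2]; nx <- p$shape_zyx[3]
    vz <- p$voxel_size_um[1]; vy <- p$voxel_size_um[2]; vx <- p$voxel_size_um[3]
    ext <- c(nz * vz, ny * vy, nx * vx)
    r0 <- p$nucleus_radius_um
    t <- p$shell_thickness_um
    margin <- r0 * 1.2 + t

    if (any(ext <= 2 * margin)) stop("field too small for the nucleus size")

    centers <- matrix(NA_real_, 0, 3)
    radii <- matrix(NA_real_, 0, 3)   # per-axis semi-axes (z,y,x), um
    max_tries <- 400L * p$n_nuclei
    tries <- 0L
    while (nrow(centers) < p$n_nuclei && tries < max_tries) {
      tries <- tries + 1L
      c_new <- runif(3, min = margin, max = ext - margin)
      r_new <- r0 * runif(3, 0.8, 1.2)
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt(colSums((t(centers) - c_new)^2))
        # conservative spherical bound: surfaces at least min_gap_um apart
        lim <- apply(radii, 1, max) + max(r_new) + p$min_gap_um
        ok <- all(d > lim)
      }
      if (ok) {
        centers <- rbind(centers, c_new)
        radii <- rbind(radii, r_new)
      }
    }
    if (nrow(centers) < p$n_nuclei) {
      stop("infeasible packing: could not place ", p$n_nuclei,
           " nuclei without overlap")
    }

    n_neuron <- round(p$n_nuclei * p$neuron_fraction)
    cls <- rep("glia", p$n_nuclei)
    cls[sample.int(p$n_nuclei, n_neuron)] <- "neuron"

    zs <- axis_um(nz, vz); ys <- axis_um(ny, vy); xs <- axis_um(nx, vx)
    ha <- array(0, dim = c(nz, ny, nx))
    elav <- array(0, dim = c(nz, ny, nx))
    repo <- array(0, dim = c(nz, ny, nx))
    mch <- array(0, dim = c(nz, ny, nx))

    box_idx <- function(center, reach) {
      list(z = which(abs(zs - center[1]) <= reach),
           y = which(abs(ys - center[2]) <= reach),
           x = which(abs(xs - center[3]) <= reach))
    }

    for (i in seq_len(p$n_nuclei)) {
      ci <- centers[i, ]; ri <- radii[i, ]
      ix <- box_idx(ci, max(ri) + t + max(vz, vy, vx))
      dz <- (zs[ix$z] - ci[1]) / ri[1]
      dy <- (ys[ix$y] - ci[2]) / ri[2]
      dx <- (xs[ix$x] - ci[3]) / ri[3]
      q_n <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")  # nucleus metric
      dz2 <- (zs[ix$z] - ci[1]) / (ri[1] + t)
      dy2 <- (ys[ix$y] - ci[2]) / (ri[2] + t)
      dx2 <- (xs[ix$x] - ci[3]) / (ri[3] + t)
      q_s <- outer(outer(dz2^2, dy2^2, "+"), dx2^2, "+")  # enlarged metric
      inside <- q_n <= 1
      shell <- (q_s <= 1) & !inside
      amp <- if (cls[i] == "neuron") p$shell_intensity_neuron else
        p$shell_intensity_glia
      ha[ix$z, ix$y, ix$x][shell] <- ha[ix$z, ix$y, ix$x][shell] + amp
      if (cls[i] == "neuron") {
        elav[ix$z, ix$y, ix$x][inside] <-
          elav[ix$z, ix$y, ix$x][inside] + p$nucleus_intensity
      } else {
        repo[ix$z, ix$y, ix$x][inside] <-
          repo[ix$z, ix$y, ix$x][inside] + p$nucleus_intensity
      }
    }

    # mCherry blobs on chosen nuclei
    n_spots <- p$n_spots
    idx_n <- which(cls == "neuron"); idx_g <- which(cls == "glia")
    if (is.null(n_spots)) n_spots <- p$n_nuclei
    k_n <- min(round(n_spots * p$spot_coloc_neuron_fraction), length(idx_n))
    k_g <- min(n_spots - k_n, length(idx_g))
    chosen <- c(if (k_n > 0) sample(idx_n, k_n) else integer(),
                if (k_g > 0) sample(idx_g, k_g) else integer())
    # physically isotropic PSF: sigma = 2 in-plane pixels, expressed in um,
    # so the z extent in voxels scales with the axial anisotropy
    sig_xy <- 2 * vx
    sig_z <- sig_xy
    for (i in chosen) {
      ci <- centers[i, ]
      ix <- box_idx(ci, 4 * sig_xy + max(vz, vy, vx))
      gz <- exp(-((zs[ix$z] - ci[1])^2) / (2 * sig_z^2))
      gy <- exp(-((ys[ix$y] - ci[2])^2) / (2 * sig_xy^2))
      gx <- exp(-((xs[ix$x] - ci[3])^2) / (2 * sig_xy^2))
      blob <- outer(outer(gz, gy), gx)
      mch[ix$z, ix$y, ix$x] <- mch[ix$z, ix$y, ix$x] + 150 * blob
    }

    add_noise <- function(a) {
      a <- a + p$background
      if (p$noise_sd > 0) {
        a <- a + array(rnorm(length(a), 0, p$noise_sd), dim = dim(a))
      }
      pmax(a, 0)
    }
    data <- array(0, dim = c(4, nz, ny, nx))
    data[1, , , ] <- add_noise(ha)
    data[2, , , ] <- add_noise(elav)
    data[3, , , ] <- add_noise(repo)
    data[4, , , ] <- add_noise(mch)

    stack <- image_stack(data, c("HA", "Elav", "Repo", "mCherry"),
                         p$voxel_size_um)
    truth <- list(
      nucleus_centers_um = centers,
      nucleus_radii_um = radii,
      nucleus_class = cls,
      true_shell_ratio = p$shell_intensity_neuron / p$shell_intensity_glia,
      spot_assignments = chosen,
      region_means = NULL
    )
    list(stack = stack, truth = truth)
  })
}

#' Simulate marker and reporter spot sets with planted colocalization
#'
#' Places Elav and Repo marker spots uniformly in a box (markers mutually
#' separated by at least 2.5 x the colocalization radius), then plants mCherry
#' spots in three strata: within 0.9 x radius of an Elav spot, within 0.9 x
#' radius of a Repo spot, or farther than 1.5 x radius from every marker, in
#' the requested fractions. The construction margins guarantee that a
#' threshold matcher at \code{radius_um} recovers the planted assignment
#' exactly.
#'
#' @param n_mcherry number of mCherry spots.
#' @param frac_near_elav,frac_near_repo planted colocalization fractions;
#'   their sum must be <= 1.
#' @param radius_um colocalization radius (default 2 um).
#' @param box_um (z, y, x) extent of the field in um.
#' @param n_elav,n_repo numbers of marker spots (defaults keep the 89.56:10.44
#'   nucleus-class ratio over 200 nuclei).
#' @param seed integer seed.
#' @return \code{list(mcherry, elav, repo, truth)}; the spot sets are
#'   \code{\link{spot_set}} objects and \code{truth$assignments} is a
#'   data.frame with the planted marker channel ("Elav", "Repo" or NA) and
#'   marker index per mCherry spot.
#' @export
simulate_spot_sets <- function(n_mcherry, frac_near_elav, frac_near_repo,
                               radius_um = 2, box_um = c(40, 120, 120),
                               n_elav = 179L, n_repo = 21L, seed = 1L) {
  stopifnot(frac_near_elav >= 0, frac_near_repo >= 0,
            frac_near_elav + frac_near_repo <= 1,
            radius_um > 0, all(box_um > 0))
  with_seed(seed, {
    min_sep <- 2.5 * radius_um
    n_marker <- n_elav + n_repo
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < n_marker && tries < 500L * n_marker) {
      tries <- tries + 1L
      cand <- runif(3) * box_um
      if (nrow(pts) == 0 ||
          min(sqrt(colSums((t(pts) - cand)^2))) > min_sep) {
        pts <- rbind(pts, cand)
      }
    }
    if (nrow(pts) < n_marker) {
      stop("infeasible geometry: box too small for the marker count")
    }
    elav_pts <- pts[seq_len(n_elav), , drop = FALSE]
    repo_pts <- pts[n_elav + seq_len(n_repo), , drop = FALSE]

    k_e <- round(n_mcherry * frac_near_elav)
    k_r <- round(n_mcherry * frac_near_repo)
    k_0 <- n_mcherry - k_e - k_r
    place_near <- function(anchor) {
      repeat {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        d <- radius_um * 0.9 * runif(1)^(1 / 3)
        cand <- anchor + u * d
        if (all(cand >= 0 & cand <= box_um)) return(cand)
      }
    }
    mc <- matrix(NA_real_, n_mcherry, 3)
    assign_ch <- rep(NA_character_, n_mcherry)
    assign_ix <- rep(NA_integer_, n_mcherry)
    row <- 1L
    for (j in seq_len(k_e)) {
      i <- sample.int(n_elav, 1L)
      mc[row, ] <- place_near(elav_pts[i, ])
      assign_ch[row] <- "Elav"; assign_ix[row] <- i
      row <- row + 1L
    }
    for (j in seq_len(k_r)) {
      i <- sample.int(n_repo, 1L)
      mc[row, ] <- place_near(repo_pts[i, ])
      assign_ch[row] <- "Repo"; assign_ix[row] <- i
      row <- row + 1L
    }
    all_markers <- rbind(elav_pts, repo_pts)
    for (j in seq_len(k_0)) {
      repeat {
        cand <- runif(3) * box_um
        d <- sqrt(colSums((t(all_markers) - cand)^2))
        if (min(d) > 1.5 * radius_um) break
      }
      mc[row, ] <- cand
      row <- row + 1L
    }
    list(
      mcherry = spot_set(mc, "mCherry"),
      elav = spot_set(elav_pts, "Elav"),
      repo = spot_set(repo_pts, "Repo"),
      truth = list(assignments = data.frame(channel = assign_ch,
                                            index = assign_ix))
    )
  })
}

#' Simulate a lipid abundance table with planted genotype effects
#'
#' Control replicate abundances are log-normal around per-species baselines
#' with the requested coefficient of variation (the log-normal is
#' mean-corrected so the expectation equals the baseline; cv = 0 gives the
#' baseline exactly). Mutant abundances are scaled by the planted fold change
#' per species.
#'
#' @param n_species_per_headgroup named integer vector over the headgroups
#'   {Cer, CerPE, GlcCer, PS, PI, PC, PE} (subset allowed).
#' @param n_replicates replicates per genotype (>= 2).
#' @param genotype_effects named numeric vector, species name to fold change
#'   (> 0); species not named get fold change 1.
#' @param cv coefficient of variation of the replicate noise.
#' @param seed integer seed.
#' @param control_genotype,test_genotype genotype labels.
#' @param baselines optional named numeric vector of per-species baseline
#'   abundances (ng/brain); by default drawn log-uniformly in [0.05, 50].
#' @return A \code{data.frame} with columns species, headgroup, genotype,
#'   replicate, ng_per_brain (a \code{lipid_table}).
#' @export
simulate_lipid_table <- function(n_species_per_headgroup,
                                 n_replicates = 4L,
                                 genotype_effects = numeric(),
                                 cv = 0.1,
                                 seed = 1L,
                                 control_genotype = "control",
                                 test_genotype = "mutant",
                                 baselines = NULL) {
  stopifnot(n_replicates >= 2, all(genotype_effects > 0), cv >= 0)
  hg_all <- c("Cer", "CerPE", "GlcCer", "PS", "PI", "PC", "PE")
  stopifnot(all(names(n_species_per_headgroup) %in% hg_all))
  with_seed(seed, {
    species <- character(); headgroup <- character()
    for (hg in names(n_species_per_headgroup)) {
      k <- n_species_per_headgroup[[hg]]
      chains <- sprintf("d%d:%d/%d:0", sample(c(14L, 16L, 18L), k, TRUE),
                        sample(0:2, k, TRUE), sample(c(18L, 20L, 22L), k, TRUE))
      species <- c(species, paste(hg, chains, sprintf("#%02d", seq_len(k))))
      headgroup <- c(headgroup, rep(hg, k))
    }
    n_sp <- length(species)
    if (is.null(baselines)) {
      baselines <- exp(runif(n_sp, log(0.05), log(50)))
      names(baselines) <- species
    } else {
      stopifnot(all(species %in% names(baselines)))
      baselines <- baselines[species]
    }
    fc <- rep(1, n_sp); names(fc) <- species
    known <- intersect(names(genotype_effects), species)
    fc[known] <- genotype_effects[known]

    sigma <- sqrt(log(1 + cv^2))
    # mean-corrected log-normal noise: E[exp(N(log mu - s^2/2, s))] = mu
    draw <- function(mu) {
      m <- matrix(rep(mu, each = n_replicates), nrow = n_replicates)
      if (cv == 0) return(m)
      m * exp(matrix(rnorm(n_replicates * length(mu), -sigma^2 / 2, sigma),
                     nrow = n_replicates))
    }
    ctl <- draw(baselines)
    tst <- draw(baselines * fc)
    tab <- data.frame(
      species = rep(rep(species, each = n_replicates), 2L),
      headgroup = rep(rep(headgroup, each = n_replicates), 2L),
      genotype = rep(c(control_genotype, test_genotype),
                     each = n_sp * n_replicates),
      replicate = rep(seq_len(n_replicates), 2L * n_sp),
      ng_per_brain = c(as.vector(ctl), as.vector(tst)))
    lipid_table(tab)
  })
}

#' Simulate an acceptor-photobleaching FRET time series
#'
#' A step change in donor intensity at the bleach point (between acquisition
#' points \code{n_pre} and \code{n_pre + 1}) plus Gaussian noise, at the
#' default 5-second frame interval.
#'
#' @param pre_level mean donor intensity before the bleach (a.u.).
#' @param delta_rel relative intensity step after the bleach (0.15 = +15\%).
#' @param n_pre,n_post numbers of pre- and post-bleach points.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param dt_s frame interval in seconds.
#' @param seed integer seed.
#' @return A \code{\link{fret_series}}.
#' @export
simulate_fret_series <- function(pre_level = 100, delta_rel = 0.15,
                                 n_pre = 3L, n_post = 3L, noise_sd = 0,
                                 dt_s = 5, seed = 1L) {
  stopifnot(pre_level > 0, n_pre >= 1, n_post >= 1, noise_sd >= 0, dt_s > 0)
  with_seed(seed, {
    n <- n_pre + n_post
    mu <- c(rep(pre_level, n_pre), rep(pre_level * (1 + delta_rel), n_post))
    y <- mu + rnorm(n, 0, noise_sd)
    fret_series(times_s = seq_len(n) * dt_s - dt_s, roi_mean = y,
                bleach_after_index = n_pre)
  })
}
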