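---
title: "Quantification methods for sphingolipid reporter profiling in the fly brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for sphingolipid reporter profiling in the fly brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingoquant)
```

# Scope

`sphingoquant` implements the quantification stages used to profile a
collection of endogenous sphingolipid-pathway reporters in the adult
*Drosophila* brain:

1. **Perinuclear shell quantification** — how much HA-tagged enzyme sits
   around neuronal (Elav+) versus glial (Repo+) nuclei.
2. **Nuclear spot colocalization** — which cell type a gene's nls-mCherry
   reporter labels, tested against the brain-wide neuronal baseline.
3. **Regional expression profiling** — per-neuropil reporter intensity,
   gene-mean normalization, Ward-D2 clustering and region correlations.
4. **Raft/biosensor readouts** — OlyA^w cortical intensity over an
   Elav-derived mask, and the acceptor-photobleaching FRET step.
5. **Lipidomics statistics** — abundance filters, fold change, per-headgroup
   z-scored PCA, and a BH-corrected volcano classification.
6. **Shared statistics** — unpaired t-tests, one-way ANOVA with Dunnett and
   Tukey adjustments, Pearson correlation, and the behavioral scalar metrics
   (olfactory performance index, climbing ratio).

Image registration, deconvolution and mass-spectrometry acquisition happen
upstream of this package: the regional module consumes a pre-warped intensity
volume plus an integer neuropil label map, and the lipidomics module consumes
ng/brain abundance tables.

Every stage has a seeded synthetic generator with explicit ground truth, so
accuracy is tested by parameter recovery rather than against opaque fixtures.

# Perinuclear shell quantification

The nuclear-marker channel (Elav or Repo) is contrast-normalized on the whole
stack so that 0.35% of voxels saturate (split between the low and high
tails), then each z-slice is thresholded with Otsu, touching nuclei are split
by a distance-transform watershed, and small particles are removed with a
morphological opening of radius 0.5 µm (converted to in-plane pixels, rounded
half-up, minimum 1 px). Dilating the nucleus mask by a 3-pixel disc and
subtracting the nucleus yields the perinuclear shell ROI. Per slice the ROI
pixel count and mean HA intensity are recorded, and the brain-level summary
is the pixel-weighted mean

$$\frac{\sum_z \text{pixels}_z \times \text{mean}_z}{\sum_z \text{pixels}_z},$$

which is algebraically the plain mean over all ROI voxels pooled across
slices (an identity the test suite checks to 1e-9 on random stacks). The
neuron/glia ratio is the weighted mean over Elav-derived shells divided by
that over Repo-derived shells.

Numerical choices worth knowing:

* All morphology is 2D per slice; physical distances respect anisotropic
  voxel sizes (defaults: 1 µm sections, 0.5 µm pixels). Pixel-unit parameters
  (the 3-px dilation, the blur sigma) are applied in-plane.
* Otsu is computed per slice, with the whole-stack Otsu threshold as a floor.
  Without the floor, a slice containing no nuclei — only background noise —
  gets a threshold that bisects the noise; with it, such slices yield empty
  masks, which is the intended degenerate behaviour.
* The watershed seeds come from distance-transform maxima; one-pixel
  separation lines are drawn between adjacent labels, mirroring what a binary
  watershed in common image-analysis tools produces.
* Elav- and Repo-derived shells are measured independently by default;
  voxels falling in both are counted in both. An `exclusive = TRUE` mode
  removes cross-class overlap first.
* Discs are rasterized with the rank-filter convention (pixel centers within
  r + 0.5 of the origin), matching the Maximum/Minimum filters of standard
  tools.

# Spot colocalization and enrichment

Spots are matched across channels by nearest neighbour at a physical
threshold of 2 µm, **boundary inclusive** ("within 2 µm" includes exactly
2 µm; inclusivity makes the brute-force oracle unambiguous). Reporter spots
matched to both an Elav and a Repo spot are assigned to the nearer marker;
exact ties go to Elav and are counted in the result. Percentages are computed
over labeled spots only, so `pct_elav + pct_repo = 100`.

The enrichment test compares per-replicate `pct_elav` values to the 89.56%
baseline — the share of Elav nuclei among all labeled nuclei observed across
182 brains — using a two-tailed one-sample t-test by default. The underlying
wording ("comparing the means between the percentage …") is ambiguous between
a one-sample test against a constant and a two-sample test against baseline
replicates, so both are provided; the one-sample form is the default because
the baseline is used as a single constant. A gene is called neuronal when the
replicate mean exceeds the baseline at p < 0.05, glial when below, otherwise
unclassified. Zero-variance replicate sets are flagged rather than tested.

An optic-lobe-style exclusion is available as a binary mask applied to spot
sets before matching (`exclude_spots`).

# Regional expression

`region_means` divides the summed intensity of each non-excluded neuropil by
its voxel count (intensity normalized to region size). `normalize_rows`
divides each gene's row by its mean across neuropils so genes of very
different absolute reporter brightness become comparable; row means become 1
and the operation is idempotent. Gene-axis clustering uses Ward-D2 on
Euclidean distances; region-axis clustering uses 1 − Pearson correlation
between region profiles, both via `stats::hclust(method = "ward.D2")`, with
the merge heights verified in the tests against a direct Lance–Williams
recurrence. The exclusion set (optic-lobe neuropils LOP, MED, OG, incomplete
in imaging) is configurable, not hard-coded; hemisphere merging is the label
map author's responsibility, leaving 25 analyzed neuropils in the reference
setup.

# Biosensor and FRET readouts

`olya_cortex_mean` blurs the Elav channel slice-wise (Gaussian, sigma 2 px),
thresholds with Otsu, and averages the biosensor channel over the pooled mask
— so the result depends on the Elav channel only through the mask.
`fret_response` summarizes an acceptor-photobleaching series (5-s frames,
bleach between points 3 and 4 by default) as pre-bleach mean, post-bleach
mean and their relative difference; a positive step is the donor-dequenching
signature. No FRET-efficiency model is fitted: that would require acceptor
cross-talk terms the imaging protocol does not provide. The series is assumed
to contain only pre- and post-bleach frames.

# Lipidomics

Sphingolipid species (Cer, CerPE, GlcCer) are kept when the mean control
abundance exceeds 0.01 ng/brain. The "top 99.5% of phospholipids" filter is
interpreted as cumulative-abundance coverage: species are ranked by mean
control abundance and the smallest prefix reaching 99.5% of the total is
kept, with ties kept — this reading is deterministic, unlike a per-species
percentile. Fold change is the mean of per-replicate test/control-mean
ratios (matching error bars drawn over per-replicate normalized values); the
ratio-of-means alternative is a flag. The volcano applies equal-variance
two-tailed t-tests per species on raw ng/brain (Welch and log-abundance
variants behind flags), Benjamini–Hochberg adjustment across species, and
flags species with adjusted P < 0.05 and fold change beyond 1.5-fold in
either direction. PCA z-scores species columns within one headgroup and fixes
component signs by making each component's largest-magnitude loading
positive, so scores are reproducible across eigensolvers.

# Shared statistics

Dunnett's many-to-one adjusted p-values are computed from the joint
multivariate-t null via `mvtnorm::pmvt` (Genz–Bretz quadrature, absolute
tolerance 1e-5, locally seeded; agreement with `multcomp` is checked to three
decimals in the tests). Tukey's all-pairs p-values use the studentized range
distribution (`stats::ptukey`). Both reduce to the unadjusted t-test with two
groups, and both are calibrated by seeded null simulations (familywise error
0.05 ± 0.01) in the acceptance tests.

The olfactory performance index is implemented exactly as defined —
(CS+ − CS−)/total — even though learned avoidance then yields negative
values; a `convention = "avoidance"` flag flips the sign, and neither
convention is applied silently. The climbing ratio averages trials 2–6,
excluding the first (habituation) trial.

# Synthetic data: what it emulates, and what it does not

`simulate_brain_stack` renders non-overlapping axis-aligned ellipsoidal
nuclei (radii jittered ±20% per axis) of two classes at the observed
89.56:10.44 neuron:glia ratio, perinuclear shells of class-specific HA
intensity, filled Elav/Repo nuclei, and Gaussian-blob reporter spots, over a
constant background with additive Gaussian noise clipped at zero — the
simplest noise model that exercises Otsu robustness without committing to a
detector model. Defaults: 1 × 0.5 × 0.5 µm voxels, 2 µm nuclei, 1.5 µm
shells, background 10 a.u., marker amplitude 1000 a.u. (nuclear-marker
immunostains are high-contrast; a dim marker would conflate marker SNR with
shell-recovery accuracy). Nuclei are placed with an inter-surface gap of
twice the shell thickness so neighbouring shells stay disjoint — the
neuron/glia ratio is only identifiable when annuli do not mix classes.

`simulate_spot_sets` plants reporter spots within 0.9 × radius of a chosen
marker or farther than 1.5 × radius from all markers, with markers mutually
separated by 2.5 × radius; these margins guarantee that the 2-µm matcher
recovers the planted assignment exactly, which is what makes the recovery
tests sharp. `simulate_lipid_table` draws mean-corrected log-normal replicate
noise at a chosen coefficient of variation with planted per-species fold
changes. `simulate_fret_series` renders a step change plus Gaussian noise.

What the generators deliberately do **not** model: optical point-spread
anisotropy beyond a fixed isotropic sigma, depth-dependent attenuation,
chromatic offsets, deconvolution artifacts, touching-nucleus clumps beyond
pairwise contact, autofluorescence structure, or lipid species correlation
across headgroups. Passing recovery tests therefore demonstrates correctness
of the quantification logic under controlled conditions, not robustness to
every artifact of real confocal data.

# Problem sizes in the test and acceptance runs

The shipped tests recover shell ratios on 16 × 96 × 96 stacks with 25 nuclei
(20 seeded brains across true ratios 0.5–4 at 10% noise), match up to 500
spots per instance against brute force, classify planted enrichment at
20/50/95/99% over 100 seeded runs of 5 × 500-spot replicates, and calibrate
the t, Dunnett and Tukey null rates with 5,000–10,000 simulations each.
These sizes give stable Monte-Carlo estimates (binomial standard errors well
inside the asserted bands) while keeping a full run to a few minutes on one
core.

# Known limitations

* The nucleus-mask pipeline inherits Otsu's weakness under extreme
  foreground/background imbalance; the whole-stack floor mitigates
  noise-only slices but a channel whose true foreground is far below ~1% of
  voxels at low SNR will still threshold unreliably.
* 3D morphology is intentionally absent: masks are slice-wise by design, so
  shells are not closed caps above and below a nucleus.
* `detect_spots` is a band-pass local-maximum detector with greedy
  separation; it does not fit sub-voxel centers and will merge sources
  closer than the separation parameter.
* Trajectory linking for time-lapse puncta is out of scope; only per-frame
  counts via `detect_spots` are supported.
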