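# sphingoquant

Quantification pipelines for profiling sphingolipid-pathway gene reporters in
the adult *Drosophila* brain. The package is aimed at imaging labs that tag
endogenous enzymes (HA knock-ins with a GAL4 reporter) and need reproducible,
scriptable versions of the measurements usually assembled by hand from
ImageJ/Imaris sessions and spreadsheets:

* **Perinuclear shell intensity** — how much tagged protein surrounds
  neuronal (Elav+) versus glial (Repo+) nuclei. Nucleus masks are built per
  z-slice (contrast normalization saturating 0.35% of voxels, Otsu threshold,
  distance-transform watershed, 0.5 µm opening), dilated by 3 px, and the
  shell ROI = dilated − nucleus. The brain-level summary is the
  pixel-weighted mean across slices,
  `Σ(pixels_z × mean_z) / Σ(pixels_z)`,
  identical to the pooled mean over all ROI voxels, and the readout is the
  neuron/glia ratio of weighted means.
* **Nuclear spot colocalization** — nls-mCherry reporter spots are assigned
  to neurons or glia by nearest-marker matching within 2 µm (inclusive), and
  per-replicate Elav percentages are tested against the 89.56% neuronal
  baseline (the Elav share of all labeled nuclei across 182 brains) to call
  a gene neuronal, glial, or unenriched.
* **Regional expression** — mean reporter intensity per voxel for each of 25
  neuropils from a pre-warped volume and a label map, gene-mean row
  normalization, Ward-D2 clustering of genes and regions, and region-region
  Pearson correlation.
* **Biosensor readouts** — OlyA^w (CerPE sensor) cortical intensity over a
  blurred-and-thresholded Elav mask, and acceptor-photobleaching FRET step
  summaries from 5-s interval series.
* **Lipidomics statistics** — abundance filters (sphingolipids
  > 0.01 ng/brain; phospholipids covering the top 99.5% of cumulative
  abundance), fold change versus control, per-headgroup z-scored PCA, and a
  Benjamini–Hochberg volcano (significant at adjusted P < 0.05 and fold
  change beyond 1.5-fold).
* **Shared statistics** — unpaired t-tests, one-way ANOVA with Dunnett
  (multivariate-t) and Tukey (studentized-range) adjustments, Pearson
  correlation, the olfactory performance index and the climbing ratio.

Every stage ships with a seeded synthetic generator carrying explicit ground
truth (nucleus positions and classes, planted colocalization assignments,
planted lipid fold changes), so the pipeline's accuracy is verified by
parameter recovery. See the methods vignette
(`vignettes/quantification-methods.Rmd`) for the models, parameter defaults
and design decisions.

## Worked example

Simulate a brain whose neuronal shells are twice as bright as glial shells
(400 vs 200 a.u. over background 10, 10% noise), then recover the ratio:

```r
library(sphingoquant)

p <- brain_sim_params(shell_intensity_neuron = 400,
                      shell_intensity_glia  = 200,
                      noise_sd = 20, seed = 42)
sim <- simulate_brain_stack(p)
sim$stack
#> <image_stack> 4 channel(s) [HA, Elav, Repo, mCherry], z=16, y=96, x=96
#>   voxel size (z,y,x) um: 1.0 x 0.5 x 0.5

shell_ratio(sim$stack)
#> <shell_result>
#>   neuron shell mean: 400.478
#>   glia shell mean:   206.9336
#>   neuron/glia ratio: 1.935297
```

The recovered ratio 1.94 sits within 4% of the planted 2.0 (the measured
shell includes the additive background, so the attainable value is
410/210 ≈ 1.95, not 2.0 exactly).

Colocalization of a neuron-enriched reporter (85% of spots planted on Elav
nuclei, 5% on Repo, the rest unlabeled), with three replicate percentages
tested against the neuronal baseline:

```r
ss <- simulate_spot_sets(1000, frac_near_elav = 0.85,
                         frac_near_repo = 0.05, seed = 42)
enrichment(ss$mcherry, ss$elav, ss$repo,
           replicate_pcts = c(94.7, 94.1, 95.2))
#> <enrichment_result>
#>   % Elav-colocalized: 94.44 (baseline 89.56)
#>   % Repo-colocalized: 5.56
#>   labeled spots: 900 (dual-match ties: 0)
#>   p = 0.003854846, classification: neuronal
```

94.44% of labeled spots sit on neuronal nuclei — above the 89.56% expected
for an unenriched gene — and the replicate test calls the gene neuronal at
p ≈ 0.004.

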