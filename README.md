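# smcoloc

Quantitative analysis of two-colour 3D single-molecule localization
microscopy (smFISH/STORM) data for bacterial small-RNA biology, plus the
statistics of MS2-affinity-purification RNA sequencing (MAPS) pull-downs.

The package is written for researchers who image a small regulatory RNA
(sRNA) together with a candidate target mRNA in single cells and want to
turn raw blink localizations into biology: RNA copy numbers per cell, the
fraction of mRNA bound by the sRNA, and an apparent dissociation constant
that can be compared across genetic backgrounds (e.g. wild type versus an
RNA-chaperone deletion). A companion module scores MAPS pull-down
sequencing for enriched transcripts.

## What it computes

Starting from localization tables (x, y, z in nm, frame, channel):

1. **Clustering** — density-based cluster analysis with the Eps/Npt rule
   (defaults Eps = 25 nm, Npt = 2): a localization is a core point iff at
   least Npt localizations (itself included) lie within Eps; clusters are
   connected components of core points plus their border points.
2. **Registration** — the chromatic shift between the two dye channels is
   the component-wise median displacement of mutual-nearest-neighbour
   cluster pairs in dual-labelled marker cells.
3. **Copy numbers** — cells expressing basal RNA levels calibrate a
   negative-binomial model NB(r, p) of localizations per single molecule;
   the k-fold convolution (equal to NB(k·r, p) in closed form) gives a
   reference matrix P(n | k), inverted per cluster by maximum likelihood;
   a deletion-strain control sets the nonspecific background subtracted
   per cell.
4. **Colocalization** — the percentage of mRNA clusters whose centroid
   lies within a distance cutoff (default 50 nm, the axial resolution) of
   any sRNA cluster, with a complete-spatial-randomness (CSR) Monte-Carlo
   baseline whose unbounded closed form is `1 − exp(−λ·(4/3)π d³)`.
5. **Affinity** — single-site mass action: with S sRNA copies, M mRNA
   copies, bound fraction f and cell volume V,

       K_D = (S − f·M)(1 − f) / (f·V)

   and the ratio of K_D between two conditions converts to an affinity
   fold-change as its reciprocal (a ratio of 0.40 is a 2.5-fold gain).
6. **MAPS enrichment** — FPKM normalization, the zero-dispersion exact
   conditional test (counts scaled to a common library and pooled; the
   group total is binomial given the pooled total), Benjamini–Hochberg
   q-values, and flags at 2x (volcano threshold, q < 0.05) and >4x
   (efficient recovery).

Synthetic-scene and synthetic-count generators provide ground truth for
every stage, so the full pipeline is testable without any imaging data.

## Worked example

```r
library(smcoloc)

# a synthetic two-channel scene: 200 rod-shaped cells, ~30 sRNA and
# ~20 mRNA copies per cell, 40% of the mRNA bound, marker cells included
scene <- simulate_scene(scene_config(n_cells = 200, seed = 11,
                                     n_replicates = 3))
calib <- simulate_scene(scene_config(n_cells = 80, mean_srna = 2,
                                     mean_mrna = 0, kd_v = 1e9,
                                     n_marker_cells = 0, seed = 12))$fov
bg    <- simulate_scene(scene_config(n_cells = 50, mean_srna = 0,
                                     mean_mrna = 0, kd_v = 1e9,
                                     n_marker_cells = 0, seed = 13))$fov

report <- run_pipeline(list(
  conditions   = list(test = scene$fov),
  calibration  = calib,
  background   = bg,
  params       = list(baseline = "csr", csr_draws = 200),
  seed         = 7))
report
#> smcoloc pipeline report
#>   spot model: NB(r = 3.91, p = 0.121)
#>  condition n_cells mean_srna_copies sd_srna_copies mean_mrna_copies
#>       test     200            39.15          7.795            25.37
#>  coloc_fraction coloc_sd_replicates baseline_fraction    kd
#>          0.3848             0.02185           0.01119 49.73

scene$truth$true_bound_fraction
#> [1] 0.3918885
```

Reading the output: the calibrated spot model says a single detected RNA
cluster carries about 28 localizations on average; the pipeline counts
~39 sRNA copies per cell against a generative truth of ~31 — absolute
copy numbers read high because the maximum-likelihood inversion cannot
return zero copies for a detected cluster and occasional molecule
splitting adds clusters; this distortion is shared across conditions
imaged with the same optics, so K_D *ratios* are unaffected (see the
vignette); the colocalization fraction 0.385 recovers the generative
truth 0.392 after chromatic registration, against a random-colocalization
baseline of ~1.1%; and the apparent K_D is reported in copies per cell
volume. With two conditions and `reference_condition` set, the report
also contains the K_D ratio and affinity fold-change between them.

For sequencing pull-downs:

```r
sim <- simulate_maps_counts(n_genes = 1000, spike_gene_count = 5,
                            spike_fold = 8, seed = 1)
tbl <- enrichment_table(sim$counts, sim$samples)
dplyr::filter(tbl, flag_recovered_4x)   # the 5 spiked genes
plot_volcano(tbl)
```

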