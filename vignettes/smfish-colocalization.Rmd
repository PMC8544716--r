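---
title: "From blink localizations to binding affinity: the smcoloc methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From blink localizations to binding affinity: the smcoloc methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcoloc)
```

## The measurement problem

Two-colour 3D single-molecule FISH imaging of bacteria produces, per dye
channel, a table of blink localizations: every time a fluorophore switches
on, one row with a sub-diffraction position estimate. A single RNA molecule
carries one or more dye-labelled probes and therefore appears as a *cluster*
of localizations, not a single point. Three inferential steps separate the
raw tables from the biology:

1. which localizations belong together (clustering),
2. how many RNA molecules a cluster contains (copy-number calibration),
3. whether an mRNA molecule sits close enough to an sRNA molecule to call
   the pair a complex (colocalization), and what binding constant the
   bound fractions imply (affinity).

`smcoloc` implements these steps as composable functions plus an
orchestrating `run_pipeline()`, and ships generators that simulate the
entire data-generating process with known ground truth.

## Clustering: the Eps/Npt rule

`density_cluster()` is DBSCAN specialised to this assay. A localization is
a **core point** iff at least `npt` localizations, *counting itself*, lie
within 3D Euclidean distance `eps`; clusters are the connected components
of core points under the eps-neighbour relation, and non-core points within
`eps` of a core join that core's cluster. Defaults are `eps = 25` nm and
`npt = 2`, the empirically determined imaging values.

Two conventions needed fixing:

* **Counting includes the point itself and the test is `>= npt`.** With
  `npt = 2` this makes a blinking pair a cluster and an isolated blink
  noise. The alternative (strictly more than two neighbours excluding
  self) would discard genuine two-blink molecules wholesale.
* **Border ties** (a non-core point in reach of cores from two clusters)
  go to the cluster of the lowest-indexed core neighbour, which makes the
  labelling deterministic and permutation-stable up to relabelling.

Distance is isotropic 3D Euclidean with a single `eps`; the axial
dimension is not down-weighted, in keeping with a single distance scale
across the analysis. The neighbour search uses a dense vectorized pass for
small inputs and a grid-bucketed search beyond 3,000 points; both are
exactly equivalent to the all-pairs definition, and the test suite proves
equivalence against a brute-force neighbour-matrix oracle on a thousand
random instances.

Clustering is run per cell and per channel (`cluster_localizations()`);
whether the original analyses clustered per cell or per field of view is
not documented, and per-cell is the conservative choice because it can
never bridge localizations across cells.

## Copy numbers: negative-binomial calibration

In cells expressing only basal RNA levels, molecules are sparse enough
that clusters can be taken as single RNAs. Their spot counts sample the
localizations-per-molecule distribution directly, and
`fit_single_molecule_model()` fits

$$P(N = n) = \binom{n + r - 1}{n} p^r (1-p)^n,
\qquad \mathbb{E}N = \frac{r(1-p)}{p},$$

by maximum likelihood (Nelder–Mead on $(\log r, \mathrm{logit}\, p)$),
initialized at the method of moments ($p_0 = \bar n / s^2$,
$r_0 = \bar n p_0/(1-p_0)$). Under-dispersed counts (variance below the
mean) are refused — a negative binomial is then unidentifiable — with an
optional Poisson fallback. At least 30 calibration clusters are required;
fewer make $r$ effectively unconstrained.

A cluster containing $k$ molecules has the $k$-fold convolution of this
pmf, which for the NB family is available in closed form:
$\sum_{i=1}^{k} \mathrm{NB}(r, p) = \mathrm{NB}(kr, p)$.
`build_reference_matrix()` nevertheless builds $P(n \mid k)$ by explicit
convolution — the closed form then serves as an *independent* oracle, and
the tests require entrywise agreement to $10^{-10}$. Columns must hold at
least 99.9% probability mass or the function refuses with the achieved
mass; by default `n_max` is auto-grown.

`estimate_copy_number()` inverts a cluster's spot count by maximum
likelihood over $k \in \{1, \dots, k_{\max}\}$ with a uniform prior, ties
toward the smaller $k$ (a posterior-mean rule is available as
`rule = "posterior_mean"`). Per-cell copies are the sum of per-cluster
estimates, and `correct_background()` subtracts the mean apparent copies
measured in a deletion-strain control, clamped at zero. The subtraction is
a pooled mean rather than a per-cell resample, for determinism.

**Known limitation.** The ML rule cannot return $k = 0$ for a detected
cluster, so in regimes where nearly every cluster is a single molecule the
per-cell sum reads high: under NB(10, 0.5) the expected estimate per
singleton cluster is about 1.16 because spot counts of 15 or more (about
15% of draws) cross to $\hat k = 2$. The acceptance suite measures a
+14–16% mean error at 30 singleton-dominated copies per cell. Two
consequences matter in practice: (i) absolute copy numbers carry this
upward bias at low molecular density, while clusters genuinely containing
several molecules are estimated nearly unbiasedly ($\mathbb{E}\hat k
\approx 2.05$ at $k = 2$); (ii) K_D *ratios* between conditions imaged
with the same optics are unaffected, because the multiplicative distortion
cancels (see below).

## Chromatic registration

Marker cells stained in both dye channels provide cluster centroids that
should coincide up to the chromatic offset of the optics.
`estimate_chromatic_shift()` pairs centroids by mutual nearest neighbour
within a 200 nm match radius and takes the component-wise **median** of
the displacements — robust to a minority of mispaired clusters — and
`apply_shift()` subtracts the translation from the mRNA channel. A
translation-only model is deliberate: no functional form for a
field-dependent warp is available at desk scale, and the median of
displacements recovers a synthetic offset exactly in the noise-free case
and within $3\sigma/\sqrt{n}$ under centroid noise.

## Colocalization and its random baseline

`colocalization_percentage()` counts an mRNA cluster as colocalized iff
its centroid lies within the cutoff (default 50 nm, chosen to match the
axial resolution of astigmatism-based 3D imaging) of at least one sRNA
cluster centroid in the same cell. The denominator is **all** mRNA
clusters: only that convention yields a percentage bounded by 100, which
is how colocalization is plotted and compared. Centroid-to-centroid
distance is used rather than nearest-member distance, again for
determinism; per-replicate fractions are reported when replicate labels
are present and summarised as mean ± SD.

Random colocalization is quantified two ways. Empirically, an unregulated
mRNA imaged together with the sRNA gives a negative-control fraction. In
silico, `csr_baseline()` places sRNA clusters as a Poisson process of
intensity $\lambda$ in the cell geometry and mRNA clusters uniformly, and
returns the Monte-Carlo colocalized fraction with its standard error,
alongside the unbounded closed form
$1 - \exp(-\lambda \tfrac{4}{3}\pi d^3)$ (the Poisson void probability of
a ball of radius $d$). In a box much larger than the cutoff the two agree
within Monte-Carlo error; inside a rod-shaped cell the MC value is the
one to use, since boundary effects make the closed form approximate.

## Affinity

Mass action for a single binding site: with $S$ sRNA copies, $M$ mRNA
copies, a bound mRNA fraction $f$ and cell volume $V$,

$$K_D = \frac{(S - fM)(1 - f)}{f\,V}.$$

This is the minimal model consistent with reasoning of the form "less
sRNA is present, yet colocalization is comparable, so the dissociation
constant must be lower"; the package documents it as an interpretation
rather than a measured quantity. The bound fraction may first be reduced
by the random-colocalization baseline (default on in the pipeline). With
$V = 1$, K_D is reported in copies per cell volume — sufficient for
ratios whenever cell volumes match across conditions; absolute molar
output just requires $V$ in litres times Avogadro's number.

`equilibrium_complex_count()` solves the forward problem,
$C = \bigl((S+M+K_DV) - \sqrt{(S+M+K_DV)^2 - 4SM}\bigr)/2$, evaluated in
the cancellation-free form $2SM/(b + \sqrt{b^2 - 4SM})$; `estimate_kd()`
is its exact algebraic inverse, which the tests verify to floating-point
accuracy. `kd_ratio_and_fold()` converts a K_D ratio into an affinity
fold-change as the reciprocal: a ratio of 0.40 is a 2.5-fold higher
affinity.

Why ratios are robust: if copy-number estimates in both conditions are
inflated by a common factor $c$ (same optics, same calibration), then
$\hat K_D = c\,(S - fM)(1-f)/(fV)$ in both, and $c$ cancels in the ratio.
The simulation-recovery tests confirm this: absolute copies read ~25%
high in dense scenes, while the recovered K_D ratio stays within ±0.1 of
the generative 0.4 averaged across seeds.

## MAPS enrichment statistics

`enrichment_table()` implements the sequencing statistics from their
definitions:

* **FPKM**: $\mathrm{count} \cdot 10^9 / (\mathrm{length}_{bp} \cdot
  \mathrm{library})$, with library sizes defaulting to column sums.
* **Exact test with zero dispersion**: with no overdispersion the NB
  model degenerates to Poisson. Replicate counts are scaled to a common
  library size (the geometric mean of all library sizes) and pooled per
  group; conditional on the pooled total $T$, the tagged-group total is
  $\mathrm{Binomial}(T, n_A/(n_A+n_B))$ under the null. The two-sided
  p-value sums all outcomes with point probability not exceeding the
  observed one (minimum-likelihood method), capped at 1. For equal
  library sizes this coincides with edgeR's `exactTest(dispersion = 0)`,
  which the tests use as an independent cross-check — never as the
  implementation.
* **BH**: the literal step-up, $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$
  capped at 1, checked against both a brute-force oracle and
  `p.adjust(method = "BH")`.
* **Flags**: a pseudocount of 0.5 fragments is added at the count level
  *for the enrichment ratio only* (finite volcano coordinates when a
  control count is zero), never for the test. `flag_2x` marks enrichment
  ≥ 2 with q < 0.05 (the volcano guide lines); `flag_recovered_4x` marks
  enrichment > 4 with q < 0.05 (the efficient-recovery rule).

Under a pure Poisson null the conditional test is exact-to-conservative;
the suite verifies a type-I rate of at most 0.055 at the 0.05 level over
10,000 null genes. Replicate counts per group are a configuration value,
not a constant, since designs with two and three replicates both occur.

## The synthetic-data generators

`simulate_scene()` emulates the full imaging stack, per cell: copies
$S \sim \mathrm{Pois}(\bar S)$, $M \sim \mathrm{Pois}(\bar M)$; expected
complexes from the equilibrium solver, realized binomially; free
molecules uniform in a spherocylinder; each complex's partners separated
by an isotropic Gaussian offset; each molecule emitting
$N \sim \mathrm{NB}(r, p)$ localizations convolved with Gaussian
localization error; Poisson background blinks; a rigid chromatic shift of
the mRNA channel; dual-labelled marker cells for registration. Everything
is deterministic given the seed, and the truth object maps every
localization to its molecule so pipeline output can be scored against
both *total* truth (all molecules) and *detected* truth (molecules whose
localizations survive `npt`).

Defaults, with reasoning:

| parameter | default | why |
|---|---|---|
| cell geometry | L = 2000 nm, R = 400 nm shaft + caps | typical exponential-phase *E. coli* rod (~1.3 fL) |
| copies / cell | ~30 sRNA, ~20 mRNA | moderate induction; hundreds of localization spots per cell |
| `kd_v` | from `bound_fraction = 0.4` | scenes are parameterized by their intended bound fraction via the exact equilibrium inverse |
| `sigma_pair` | 20 nm RMS 3D separation | probe sites on a base-paired duplex sit within tens of nm; the offset vector is drawn with per-axis SD $20/\sqrt{3}$ so complexes overwhelmingly fall inside the 50 nm cutoff before noise |
| spot model | NB(10, 0.25), mean 30 blinks | molecules carry several dye-labelled probes (14 on the mRNA construct) that each blink repeatedly; with a mean-10 model, 25 nm clustering fragments single molecules, inconsistent with an empirically tuned Eps |
| `sigma_xy`, `sigma_z` | 10, 21 nm | lateral STORM precision ~10 nm; 21 = 50 nm axial FWHM / 2.355 |
| background | 5 blinks/cell/channel | sparse nonspecific probe binding, mostly removed by `npt = 2` |
| shift | (12, −9, 18) nm | tens-of-nm chromatic offsets after coarse alignment |

What the generator does **not** model — and therefore what passing tests
cannot certify about real data: frame-resolved blinking kinetics and
photobleaching, multi-emitter fitting artefacts, drift,
z-dependent detection efficiency, field-dependent (non-rigid) chromatic
aberration, cell segmentation errors (ROIs are taken as given), and any
spatial organisation of molecules beyond uniformity (no membrane or pole
enrichment). The calibration step absorbs per-cluster blink statistics
empirically, but nothing in the pipeline can correct a molecule that
fragments into two clusters or two molecules that fuse into one; the
simulations quantify how much those effects move each estimate.

`simulate_maps_counts()` generates the sequencing twin: NB (or Poisson)
counts for a tagged/control design, spiked genes multiplied in the tagged
group, gene lengths log-uniform on 200–5000 bp.

## Problem sizes and numerical choices

The shipped simulations use 200 cells for the colocalization recovery,
two conditions of 150 cells across three seeds for the K_D-ratio
recovery, 100 cells for copy-number recovery, and 10,000 genes for the
null-calibration of the exact test — sizes chosen to hold Monte-Carlo
error comfortably below the tolerances being checked while keeping a full
run in the minutes range on a single core. Other numerical choices:
reference-matrix truncation at 99.9% column mass with closed-form
extrapolation beyond `n_max`; squared-distance comparisons with a 1e-9
slack so grid and dense neighbour searches agree bitwise; the equilibrium
root in its cancellation-free form; empty-denominator colocalization
reported as 0 with a warning rather than NaN; all warnings collected into
the pipeline report rather than dropped.
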