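---
title: "Identifying freeze-damaged corn seeds from hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying freeze-damaged corn seeds from hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostspec)
```

## The problem

Corn (*Zea mays*) seed lots grown in regions prone to cold snaps contain a
mixture of sound seeds and seeds damaged by freezing. Freeze damage degrades
germination but leaves no reliable visible mark, and the classical viability
assays (conductivity tests, enzyme assays, tetrazolium staining) are
destructive and slow. Visible/near-infrared hyperspectral imaging (HSI)
offers a nondestructive alternative: each seed yields a reflectance spectrum
whose shape carries information about membrane integrity, starch and protein
state, and surface condition, all of which shift with freezing injury.

`frostspec` implements a complete single-seed classification pipeline for
this setting, with three freeze-damage classes (1 = normal, 2 = slightly
damaged, 3 = severely damaged) and separate treatment of the two kernel
faces. The embryo (germ) face holds the metabolically active tissue and
responds more strongly to freezing; the endosperm face is mostly starch and
responds less. The pipeline lets both faces be processed identically so
their diagnostic value can be compared.

## Pipeline overview

1. **Calibration.** Raw sensor counts $I_o$ are converted to relative
   reflectance with a dark-current cube $I_B$ and a white-reference cube
   $I_W$:
   $$I = \frac{I_o - I_B}{I_W - I_B}.$$
   This cancels dark current and any smooth spatial or spectral
   non-uniformity of the illumination (`calibrate()`). Voxels where
   $I_W = I_B$ have no signal; the default policy is to raise an error
   (masking to `NA` is available) because silently propagating NaN through
   region means corrupts every downstream statistic.

2. **Band trimming.** Sensor edges are noisy; analysis is restricted to a
   450–979 nm window. Trimming is available both by 1-based inclusive band
   index (`trim_bands()`, so that keeping bands 36–455 of a 477-band sensor
   leaves exactly 420 bands) and by wavelength window
   (`trim_wavelengths()`), which is the default in the command-line tool
   because the exact band centres of any given instrument binning are
   rarely published.

3. **Segmentation.** Seeds lie on a dark stage. A single gray band is
   extracted (700 nm for endosperm-face images, 500 nm for embryo-face
   images — the conventional pairing, configurable), contrast-stretched
   between its 1st and 99th percentiles, thresholded by Otsu's method over
   a 256-bin histogram, and labeled into connected components
   (8-connected by default, components under 50 px discarded as glare).
   The percentile stretch is strictly monotone, so it can only change which
   histogram bin the Otsu optimum falls in, never the ordering of pixels.
   Per-seed mean spectra are the arithmetic mean over the region's pixels
   at every band (`mean_spectra()`), which is invariant to pixel
   enumeration order.

4. **Preprocessing** (`snv()`, `sg53()`). SNV standardises each spectrum to
   mean 0, sample standard deviation 1, removing per-seed multiplicative
   scatter and baseline offsets; it is idempotent and invariant to affine
   distortions $a x + b$, $a > 0$. The 5-3 smoother is a Savitzky–Golay
   filter with a 5-point window and cubic polynomial — interior kernel
   $(-3, 12, 17, 12, -3)/35$, boundary points from the boundary window's
   own polynomial fit — so any cubic passes through unchanged. One pass is
   applied by default; the pass count is exposed but there is no reason to
   iterate a least-squares smoother, and repeated passes progressively
   flatten genuine absorption structure.

5. **Wavelength selection.** Two complementary selectors, both fitted on
   the training partition only:

   * **SPA** (`spa_select()`), the successive projections algorithm. From a
     start band, each step appends the band whose column has the largest
     norm after orthogonal projection onto the complement of the selected
     columns — a greedy minimum-collinearity forward selection. The chain
     itself is unsupervised; chain prefixes of size 1–20 from every start
     band are scored by 5-fold cross-validated LDA misclassification, and
     the lowest-error subset wins (ties prefer smaller subsets, then the
     smaller first band). Fold assignment is deterministic (within-class
     cyclic dealing in row order) so the selection is reproducible without
     an RNG.
   * **2DCOS** (`cos2d_select()`), two-dimensional correlation
     spectroscopy. The three class-mean spectra, ordered by severity, form
     the external-perturbation series; the synchronous spectrum is the
     covariance of the mean-removed series,
     $\Phi(\nu_1, \nu_2) = \tfrac{1}{m-1}\sum_j \tilde y_j(\nu_1)\,\tilde y_j(\nu_2)$,
     and wavelengths are taken at local maxima of its diagonal
     ("autocorrelation peaks") — the bands that respond most strongly to
     increasing freeze severity, including weak features a variance-based
     selector would miss. The $1/(m-1)$ normalisation is conventional; any
     positive constant gives the same peak positions. Peaks must have
     topographic prominence of at least 5 % of the diagonal maximum
     (configurable); the prominence rule prunes noise-induced micro-maxima
     while keeping genuinely separated features.
   * **Fusion** (`fuse_selections()`): the sorted, de-duplicated union of
     the two sets, with per-wavelength provenance. SPA contributes
     low-redundancy discriminative bands, 2DCOS contributes
     perturbation-responsive bands; their union is small (typically 7–19
     wavelengths) yet consistently at least as accurate as either set
     alone, which is what makes a cheap multispectral implementation of the
     method plausible.

6. **Partitioning and models.** The train/test split is Kennard–Stone
   (`ks_split()`): within each class, greedy max–min Euclidean selection
   starting from the two mutually farthest samples, stopping at
   `round(n_c * 2/3)` per class. Run per class, the 2:1 ratio with class
   sizes 800/640/480 gives training counts 533/427/320 exactly. The split
   is deterministic; max–min ties take the lowest row index. One split per
   face is computed and shared by every model cell, and the testing rows
   never inform preprocessing or selection (SNV and smoothing are
   row-local, selection is train-only by construction).
   Three classifiers are provided (`fit_predict()`): KNN (default
   $k = 5$), LDA restricted to 2 discriminant components (the maximum for
   three classes), and an RBF-kernel SVM (default
   $\gamma = 1/(B \cdot \mathrm{var}(X_{\text{train}}))$, cost 10). The SVM
   hyperparameters are fixed, documented defaults rather than the result of
   an internal grid search: a search would add an RNG-sensitive layer with
   marginal benefit at these problem sizes, and both parameters are
   overridable in `model_spec()`.

7. **Evaluation** (`eval_report()`). Confusion matrices are oriented rows =
   actual, columns = predicted. Accuracy is $100 \cdot \mathrm{tr}(C)/N$;
   sensitivity is per-class one-vs-rest recall $C_{cc}/\sum_k C_{ck}$. The
   chance-corrected reference is
   $$\mathrm{Accuracy}_{RND} = 100 \cdot \frac{\sum_c r_c\, k_c}{N^2},$$
   the expected accuracy of a classifier that reproduces the predicted
   marginals $k_c$ at random against the actual marginals $r_c$ — for three
   perfectly balanced classes this is 33.3 %, so a perfect balanced
   classifier scores $100 - 33.3 = 66.7$ above chance. The difference
   $\mathrm{Accuracy} - \mathrm{Accuracy}_{RND}$ is the headline
   skill-above-chance figure and is robust to class imbalance. Raw values
   are kept unrounded; the `display` element rounds to one decimal with
   R's `round()` (half-to-even), and the displayed difference is taken
   between the rounded terms, as results tables conventionally print it.

## The synthetic generator

No public single-seed freeze-damage HSI dataset exists, so the package
ships a generator (`gen_spectra()`, `gen_cube()`) rather than fixtures.
Its model:

* a smooth base reflectance curve with a sigmoidal red-edge rise (the
  embryo profile sits 0.05 higher — embryo-face images are brighter);
* a **latent severity continuum**: each seed draws
  $s \sim N(\text{class} - 1,\ \sigma_s)$ and its mean curve interpolates
  the class curves at $s$. This is the generator's central realism device:
  freezing injury is a continuum and borderline seeds are what actually get
  misclassified, so class overlap is produced by biology-like variation
  rather than by inflating sensor noise. Defaults $\sigma_s = 0.33$
  (endosperm) and $0.26$ (embryo) place default-configuration test
  accuracies in the 85–98 % range with the embryo face reliably ahead —
  discriminative but not saturated;
* strictly increasing additive severity offsets (damaged seeds reflect
  more — frost-killed tissue scatters light differently), kept small
  (0, 0.008, 0.016) so that the class signal is carried mainly by three
  class-dependent Gaussian absorption features at 745/850/930 nm, matching
  the observation that severity response concentrates in 700–979 nm;
* per-seed multiplicative gain $U(0.9, 1.1)$ and baseline $U(-0.02, 0.02)$
  (so SNV genuinely changes selections), plus band-wise Gaussian noise
  (sd 0.008);
* for cubes: spectra painted into non-overlapping ellipses over a dark
  background, then un-calibrated into sensor counts as
  $\text{raw} = I_B + R\,(I_W - I_B)$ with a configurable dark level and
  optionally spatially graded white field, so `calibrate()` inverts the
  construction to machine precision regardless of illumination gradients.

Everything is driven by one RNG seed in `synth_config()`; identical
configurations give bitwise-identical output, and the generator restores
the caller's RNG state.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the pipeline exploits — severity-ordered reflectance,
localized informative bands, scatter, class overlap — but not optical
physics (no Kubelka–Munk scattering theory), seed morphology beyond
ellipses, touching seeds, specular glare, or instrument artifacts like
smile/keystone or dead pixels. Pipeline correctness and statistical
behaviour validated on it (band recovery, face ordering, chance-level
nulls) are evidence about the algorithms, not about any particular
instrument's real-world accuracy.

## Numerical and design notes

* **Otsu** maximises between-class variance over a 256-bin histogram; ties
  take the lowest cut. Constant images are rejected. The implementation
  (cumulative-moment recursion) is tested against an exhaustive per-cut
  search from raw pixel values.
* **SPA** deflates the residual matrix in place (Gram–Schmidt); columns
  with projected norm below `max|X| * 1e-10` are treated as exhausted, so
  exact duplicates are never chained consecutively. The chain is invariant
  to a common positive rescaling of the matrix.
* **Kennard–Stone** uses `round(n_c * 2/3)` implemented as
  `floor(x + 0.5)` — an explicit half-up rule, so training counts do not
  depend on banker's-rounding edge cases. Degenerate classes (< 3 samples)
  are rejected.
* **Permutation nulls** must fix the Kennard–Stone split *before*
  permuting labels. Stratified KS deliberately leaves each class's interior
  points to the testing set, which correlates test-point position with the
  class label used for stratification; permuting before splitting therefore
  scores above chance even for pure noise. This is a property of
  stratified max–min designs worth knowing when evaluating with KS splits.
* **Band indices are 1-based inclusive** everywhere in the user interface,
  matching both R convention and the way waveband ranges like "bands
  36–455" are quoted for this class of instrument.
* **Problem sizes in the test-suite**: the stochastic validation suites run
  at reduced scale (40–60 bands, ~100–250 seeds, 25–50 seeded replicates)
  chosen so the full suite completes in about a minute while keeping every
  statistical margin comfortable; the benchmark class counts (800/640/480)
  are used where the quantity under test is the split arithmetic itself.

## Known limitations

* Touching or overlapping seeds are not separated (no watershed step);
  layouts must keep seeds disjoint.
* The SPA search is exhaustive over start bands; at 420 bands with the full
  1–20 size range it is the most expensive step (minutes, not seconds).
  `spa_starts` subsamples start bands when a faster, near-identical answer
  suffices.
* LDA-based SPA scoring assumes class-conditional Gaussians with shared
  covariance on small subsets; heavily non-Gaussian data would warrant a
  different scorer.
* The 2DCOS series has $m = 3$ points (one per severity class), so the
  synchronous matrix has rank ≤ 2; this is intrinsic to a three-category
  perturbation, not a numerical defect.
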