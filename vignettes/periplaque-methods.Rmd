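---
title: "Quantifying the peri-plaque microglial barrier, neurite dystrophy, and a plasma miRNA screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the peri-plaque microglial barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

In amyloid pathology, microglia envelop compact plaques and form a
physical barrier whose integrity shapes the toxicity of the plaque
microenvironment: perimeter sectors left uncovered accumulate swollen,
Lamp1-positive dystrophic neurites. `periplaque` implements the full
quantification chain for this biology from multi-channel fluorescence
stacks — plaque segmentation, arc-based microglial coverage,
sector-resolved dystrophy, plaque-associated microglia counts — together
with Sholl analysis of neuron morphologies, phagocytosis scoring of
FITC-amyloid uptake, and the statistics of a plasma miRNA
case/control screen. Because no real acquisition accompanies the
package, every stage is exercised on synthetic data whose ground truth
is known exactly; the synthetic generators are first-class, tested code.

# The synthetic study conditions

The generator defaults define the study conditions and are not tuned
per experiment:

* **Geometry and calibration.** Fields default to 80 × 80 µm at
  0.5 µm/pixel with 5 optical slices at a 3 µm z-step, emulating 40×
  confocal stacks of hippocampal sections. Plaques are disks (compact,
  ThioS-like deposits); microglial envelopment is an annulus of 2 µm
  thickness present only over the specified angular intervals; somata
  are 6 µm disks, a typical microglial soma size that remains
  detectable at these pixel sizes.
* **Angular convention.** Angles are measured counterclockwise from the
  +x axis of the image physical frame, and covered intervals are
  half-open `[start, end)` so that degree partitions are exact: the
  ground-truth coverage is exactly the summed interval length over 360.
* **Dystrophic neurite halo.** Lamp1 signal is a boolean model of 1.5
  µm-radius blobs (the scale of a swollen neurite cross-section) between
  the plaque edge and an outer halo radius. The blob intensity is chosen
  so the expected positive-area fraction equals the requested
  sector-class density: for density $f$ and blob area $a$, blobs are
  laid down at rate $\lambda = -\log(1-f)/a$ per unit area. This makes
  the rendered per-degree area match the nominal density in expectation,
  and the blob scale keeps the thresholded area faithful after PSF
  blur — point-speckle noise would not survive blurring with its area
  intact.
* **Noise model.** Each slice is blurred with a Gaussian PSF
  (σ = 0.4 µm for histology; σ = 0.15 µm for the phagocytosis assay,
  reflecting the higher-NA oil objective used for cultured cells) and
  receives additive Gaussian noise (default sd 0.02 on a unit intensity
  scale). Imaging noise levels are not prescribed by the assay, so
  `noise_sd` is exposed rather than fixed.
* **Determinism.** One integer seed fixes all randomness; two runs with
  an equal configuration are bit-identical. Cohort drivers derive one
  seed per field as `seed * 1000 + i` (reduced modulo 2^31 − 1).

What the generator does *not* emulate: ramified microglial morphology
(arcs stand in for the process barrier), optical sectioning physics,
spectral bleed-through, and non-convex plaque shapes. Tests passing on
these synthetics therefore validate the measurement chain — not
performance on real tissue, where thresholding and soma detection face
harder conditions.

# Coverage and sector dystrophy

For each plaque the package projects three optical slices through the
plaque centre (maximum intensity), segments the plaque channel (Otsu by
default; 4-connected components; minimum area 10 µm², below which a
blob is unlikely to be a genuine deposit at these resolutions), and
takes the intensity-weighted centroid as the plaque centre point.

The perimeter is then scanned in $360/\Delta\theta$ angular bins
(default $\Delta\theta = 1°$, finer than any structure at the stated
pixel sizes while keeping degree sums exact). For each bin a ray from
the centroid locates the **outermost** plaque-mask crossing — coverage
concerns the external barrier, so interior voids of non-convex masks
are ignored — and the bin counts as covered when any Iba1-positive
pixel lies within ±1 µm of that crossing along the ray. The band makes
reproducible what a human rater would judge at the perimeter; it is
exposed in the interface. Coverage is covered degrees over 360, and
covered plus uncovered degrees equal 360 exactly by construction.

Dystrophy extends each bin radially to the farthest Lamp1-positive
pixel along its ray (plaque area excluded). Every Lamp1-positive pixel
outside the plaque is assigned to the bin of its angle and kept if it
lies within the bin's radial extent, so the covered-sector and
uncovered-sector areas partition the assigned area exactly. Per-degree
values divide each class's area by its total degrees; a class with zero
degrees is reported as `NA` (undefined), never as 0. Total Lamp1 area
(the quantity correlated with coverage) is the sum over both classes;
per-degree values are reported alongside.

Plaque-size bins for the correlation default to equivalent diameters
[0, 9), [9, 18), [18, ∞) µm — only the 9 µm edge is anchored by the
small-plaque effect this assay is known for; the others are exposed
defaults. The correlation is Pearson (two-sided p from the t
distribution on n − 2 df), with Spearman available as an option.

Two discretization caveats are documented deliberately. First, the
per-pixel angular-histogram oracle used in tests needs several pixels
per degree-bin at the perimeter, so oracle comparisons run at 0.25
µm/pixel on 12 µm plaques with the centre off the pixel grid; a centre
sitting exactly on a pixel boundary creates a measure-zero degeneracy
at axis-aligned angles. Second, interval-edge bins can flip under PSF
blur, so sector-contamination statements are evaluated in aggregate
across plaques.

# Plaque-associated microglia

Somata are detected as 4-connected Iba1 components whose area is within
[0.25, 4] times the nominal 6 µm soma disk; two somata closer than a
soma diameter merge into a single detection — documented behaviour
rather than a split heuristic. Counts use Euclidean distance from the
plaque centre point with ties at exactly the 25 µm radius included.
(The assay's convention is a 25 µm *radius* from the plaque centre;
descriptions of the same measurement as a "diameter" exist, and the
radius reading is implemented.)

# Sholl analysis

From SWC morphologies, intersections at radius $r$ are exact
segment–sphere crossing counts: each edge contributes the number of
solutions of $|p_0 + t(p_1 - p_0)| = r$ with $t \in (0, 1]$, so an edge
that dips inside and exits again counts twice, and shared nodes are
counted once (as the parent edge's endpoint). Radii step by 5 µm, the
standard spacing for this assay. From binary masks, circles are
rasterized with the midpoint algorithm, ordered by angle into an
8-connected closed path, and each maximal foreground run counts as one
intersection; neurites must be rendered with physical thickness because
two one-pixel-wide digital curves can cross without sharing a pixel.
The two routes agree within ±1 except at radii nearly tangent to a
node shell (a branch point or tip sitting on the circle), where the
count is ill-conditioned in either representation; tests exclude radii
within 1.5 µm of a node distance. The profile summary is the
trapezoidal AUC; a plain sum of counts is exposed as an option since
either convention appears in practice. Basal-versus-apical restriction
uses SWC type codes when present; otherwise all neurites are counted.

# Phagocytosis scoring

Cells are segmented by a nuclei-seeded watershed (labels propagate from
thresholded nuclei over the thresholded Iba1 area); label images from
an external segmenter can be supplied directly. A cell is
Aβ-positive when its FITC-positive area reaches a minimum punctum area
(default 1 µm²) at a data-driven threshold (Otsu over in-cell FITC
values) — the positivity criterion for a phagocytic cell is not
standardized, and this punctum-area rule is the implemented
interpretation. Two intensity summaries are kept because they answer
different questions: the whole-cell mean FITC reflects total uptake
per cell, while the mean over a cell's FITC-positive pixels estimates
the intensity of the engulfed material itself; the cohort summary
`mean_fitc_positive` uses the latter, which recovers the generator's
punctum intensity on synthetic data.

# The miRNA screen

The screen follows the standard small-cohort plasma workflow on a
feature × sample count matrix with two groups (the simulated cohort is
11 cases vs 14 controls):

* **Filter.** Keep features with count ≥ 10 in strictly more than 50%
  of samples *within each group* (for 11 and 14 samples that means at
  least 6 and at least 8). The strict-majority reading is used
  consistently; published descriptions of this rule are sometimes
  internally inconsistent about the implied per-group minimums.
* **TMM.** Normalization factors are the doubly-trimmed (30% of
  M-values, 5% of A-values, per tail) precision-weighted mean of
  log-ratios against the sample whose upper-quartile fraction is
  closest to the cohort mean, rescaled to geometric mean 1. The
  factors are exactly scale-free for whole-library depth changes;
  the precision weights depend on absolute counts, so scaling a single
  library perturbs factors at the 10⁻³–10⁻² level — a property shared
  by reference implementations and verified against one in the tests.
* **Test.** A negative-binomial exact-style conditional test:
  library-size-equalized counts are summed per group, the group sums
  are modelled as NB with a pooled method-of-moments common dispersion,
  and the two-sided p-value is the conditional probability (given the
  feature total) of all splits no more likely than the observed one.
  The conditional distribution is evaluated on a window around its
  mode that captures all but ~10⁻¹⁵ of the mass. On 5000-feature null
  simulations at dispersion 0.1 the empirical type-I rate at α = 0.05
  is ~0.046–0.052. The test choice and dispersion are recorded in the
  output attributes, and an externally estimated dispersion can be
  plugged in.
* **Fold change and scales.** log2FC is the ratio of group-mean
  TMM-CPM with pseudo-count 0.5 (avoiding log 0). CPM is used for
  testing; a depth-referenced per-million scale is emitted for
  reporting (for miRNA counts, with no length correction, the two
  coincide).
* **DEM selection.** BH-FDR (`stats::p.adjust`) with status `up`/`down`
  when |log2FC| > 1 and FDR < 0.05.
* **Signature rule.** A feature is flagged when *every* case sample
  falls outside the 95% interval built from controls. The interval is
  prediction-style, $\bar{x} \pm t_{0.975,\,n-1}\, s \sqrt{1 + 1/n}$,
  because the rule is applied to individual case values; the narrower
  CI-of-the-mean is available as an option so both readings of a "95%
  confidence interval of control levels" can be compared. Zero control
  variance degenerates to the point interval [mean, mean]: any
  differing case value then counts as outside. Features detected in at
  least one case and in no control are additionally marked exclusive
  to cases.
* **PCA.** Centered SVD (`prcomp`) of samples × features with a fixed
  sign convention (largest-magnitude loading positive) so scores are
  deterministic.

# Problem sizes and numerical choices

The test-suite and acceptance cohorts use 80 µm single-plaque fields
(100 fields for coverage recovery across coverage levels 0–1, 70 for
the effect-direction study), 5000-feature null simulations, and
100-cell phagocytosis fields — sizes at which every recovered quantity
is stable across seeds while a full run stays interactive on one core.
Otsu is the default for every threshold (parameter-free, invariant to
intensity rescaling); a flat channel thresholds to all-positive if
saturated and to empty if zero. Ray sampling steps at half a pixel;
plaque ordering is by centroid (y, x); all tables are written with a
package version stamp and a configuration hash.

# Known limitations

Coverage is a 2D arc measure on a central projection, not a 3D solid
angle; plaques are treated as star-convex about their centroid (the
outermost-crossing rule makes mild concavity safe, but strongly
non-convex deposits would need a boundary parameterization); the
generator's somata-plus-arcs picture omits microglial process
morphology; the NB test uses one common dispersion rather than
per-feature shrinkage estimates, which is adequate at the simulated
dispersions but less powerful on strongly heteroskedastic real data;
and the signature rule inherits the usual fragility of
all-samples-outside criteria at small n.
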