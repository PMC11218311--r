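# periplaque

Quantification of the peri-plaque microenvironment in amyloid
pathology, plus the statistics of a plasma miRNA case/control screen —
for researchers measuring how well microglia contain amyloid plaques
and what that containment costs the surrounding neurites.

Microglia envelop compact amyloid-β plaques and form a barrier; where
the barrier is incomplete, Lamp1⁺ dystrophic neurites accumulate.
`periplaque` implements this measurement chain from multi-channel
fluorescence stacks and exercises every stage on synthetic data with
exact ground truth (the package deposits no real acquisitions; the
synthetic generators are first-class, tested code).

## What it computes

* **Microglial coverage** of a plaque perimeter: the fraction of
  1° arcs whose perimeter point colocalizes with Iba1,

  coverage = (Σ covered arc degrees) / 360,  covered + uncovered = 360° exactly.

* **Sector-resolved neurite dystrophy**: covered/uncovered angular
  sectors are extended radially to the Lamp1 limit (plaque area
  excluded); Lamp1⁺ area is summed per sector class and normalized to
  that class's degrees (µm²/degree). Coverage vs total Lamp1 area is
  correlated (Pearson, t-distribution p) within plaque-diameter bins
  [0, 9), [9, 18), [18, ∞) µm.
* **Plaque census**: Otsu segmentation, 4-connected components, area
  and equivalent diameter 2√(A/π), Iba1⁺ area fraction, and counts of
  microglial somata within a 25 µm radius of each plaque centre.
* **Sholl analysis** from SWC morphologies (exact segment–sphere
  crossing counts at 5 µm radial steps) or binary masks (foreground
  runs along midpoint-rasterized circles), with trapezoidal AUC.
* **Phagocytosis scoring**: nuclei-seeded watershed segmentation, a
  punctum-area positivity rule for Aβ⁺ cells, proportion positive and
  mean FITC intensity of engulfed material.
* **miRNA screen**: expression filter (count ≥ 10 in > 50% of each
  group), TMM normalization (doubly-trimmed weighted mean of M-values),
  a negative-binomial exact-style test with BH-FDR, DEM selection at
  |log2FC| > 1 and FDR < 0.05, a 95% control-interval signature rule,
  PCA scores, and 2^−ΔΔCt relative expression.

## Worked example

The numbered scripts under `analysis/` run the whole study on
synthetic data (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate_fields.R     # images, SWCs, counts + truth
Rscript analysis/02_plaque_census.R
Rscript analysis/03_barrier_dystrophy.R
Rscript analysis/04_sholl_phago.R
Rscript analysis/05_mirna_screen.R
```

`analysis/03_barrier_dystrophy.R` simulates 70 plaques whose uncovered
sectors carry a ten-fold denser Lamp1 halo than covered ones
(area-fraction densities 0.5 vs 0.05) and prints:

```
coverage recovery: MAE 0.026 over 70 plaques
per-degree Lamp1: uncovered 1.113 vs covered 0.192 um2/deg (paired t = 35.9, p = 2.33e-46, uncovered>covered)
size bin <9um     n= 6  r=-0.835  p=0.0385
size bin 9-18um   n=46  r=-0.926  p=3.47e-20
size bin >=18um   n=18  r=-0.977  p=4.13e-12
```

Read: estimated coverage tracks the generator's truth to within 0.026
on average; dystrophy per degree is significantly higher outside the
microglial barrier; and plaques with less coverage carry more total
Lamp1⁺ area in every size bin, including the smallest (< 9 µm
diameter). `analysis/05_mirna_screen.R` recovers all 40 simulated DEMs
(20 up + 18 down pass both cutoffs at the simulated effect size) with
zero false discoveries, and `analysis/04_sholl_phago.R` separates
control from hypotrophic morphologies by Sholl AUC (712 vs 278
µm·crossings) and scores the phagocytosis field at 40/100 positive
cells with mean engulfed-FITC intensity 0.797 against a generated
plateau of 0.8.

A minimal in-session example:

```r
library(periplaque)
cfg  <- sim_config(seed = 1)
spec <- plaque_spec(center_um = c(40, 40), radius_um = 8,
                    covered_intervals_deg = list(c(20, 200)),
                    lamp1_density_covered = 0.05,
                    lamp1_density_uncovered = 0.5,
                    lamp1_outer_radius_um = 18,
                    n_somata_background = 6)
sim  <- simulate_histology_stack(cfg, list(spec))
proj <- project_central_slices(sim$stack)
plq  <- segment_plaques(proj)[[1]]
prof <- build_angular_profile(proj, plq)
microglia_coverage(prof)$coverage     # ~0.50 (truth: 180/360)
dystrophy_by_sector(proj, prof, plq)  # per-degree Lamp1 by sector class
```

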