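---
title: "Quantifying NF-kB heterogeneity and beta-cell proliferative decline: methods"
author: "isletAging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NF-kB heterogeneity and beta-cell proliferative decline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletAging)
```

## The scientific problem

Pancreatic beta-cells lose proliferative capacity with age, and they do so
heterogeneously: within one islet, cells with high NF-kB transcriptional
activity (read out by a GFP reporter driven by tandem NF-kB binding sites)
divide less than their low-activity neighbours, express more *socs2*, and
become more numerous as the animal ages. Quantifying this in zebrafish
islets involves several measurement modalities, each with its own small
analysis pipeline:

* **imaging** — per-cell nuclear fluorescence from 3D confocal stacks,
  with the FUCCI reporter pair marking cell-cycle state (G0/G1 red via
  cdt1, S/G2/M green via geminin; "green-only" = proliferating),
  EdU/PCNA as proliferation markers, and mosaic CFP marking transgene
  carriers;
* **single-cell RT-qPCR** — censored cycle-threshold (Ct) tables, where
  Ct = 40 is the "not detected" sentinel of a 40-cycle assay;
* **bulk RT-qPCR** — relative quantification between sorted GFP-high and
  GFP-low populations;
* **flow cytometry** — splitting a bimodal one-dimensional GFP intensity
  distribution into low and high populations.

Because the underlying live-animal measurements are not reproducible from
data alone, the package pairs every analysis stage with a seeded
synthetic-data generator that *plants* the reported group means as ground
truth. Validation is then parameter recovery: the pipeline must read back
what was planted, within the sampling error its cohort sizes imply.

## Per-cell fluorescence quantification

An analyzed cell is reduced to a single optical section: the z plane on
which its nucleus has the largest labelled area (`findCenterPlane()`;
ties resolved to the smallest z, so the choice is deterministic). The
region of interest is the nuclear mask on that plane — no dilation margin
by default, because a mask-exact ROI is reproducible and parameter-free;
`measureCells(dilatePx = )` exposes an optional in-plane disc dilation
for workflows that want perinuclear signal. Per-channel means over the
ROI give the raw readouts, and the NF-kB activity of a cell is its
DAPI-normalized GFP,

$$\mathrm{normalized\ GFP} = \frac{\overline{GFP}_{ROI}}{\overline{DAPI}_{ROI}},$$

which cancels per-cell differences in optical depth and staining
efficiency (any common gain applied to both channels leaves it
unchanged; this invariance is tested). A zero DAPI mean makes the ratio
undefined and is a hard error, never a silent NaN. All voxel indices are
1-based with axis order (z, y, x).

For secondary islets, where individual nuclei are not resolved, the
volume-normalized readout `isletGfpDensity()` reports mean GFP intensity
within a region divided by the region's volume in µm³.

### Classification

The per-islet threshold GFP^total is the mean normalized GFP over all the
islet's measured cells (`gfpTotalThreshold()`). The wording "average of
all the images belonging to one islet" admits two readings — a cell-pooled
mean or a mean of per-section means; the default pools cells because the
result is then independent of how cells happen to distribute across
optical sections, and `mode = "section_mean"` provides the alternative.
Cells strictly above the threshold are GFP-high, all others GFP-low: ties
go to low (the reported rule is "higher than GFP^total", i.e. strict),
and the two classes always partition the islet. The same tie rule is used
by the FACS gate.

EdU/PCNA positivity was originally thresholded by eye; the package
replaces this with Otsu's method on the distribution of per-cell marker
means, with a fixed-value override (`markerPositive()`). Otsu on constant
input is an instructive error, not a guess.

### Proliferation scores

The FUCCI proliferation percentage is
$100 \times \#\{\text{green-positive and red-negative}\} / \#\{\text{all beta-cells}\}$ —
double-positive cells are *not* proliferating under this formula, and a
property test asserts that adding a double-positive cell can only lower
the score. Mosaic islets are scored class-wise over CFP+ and CFP− cells
separately; an empty class yields an explicit `undefined` flag rather
than 0, and such islets are excluded (and counted) by the paired
comparison.

### Statistics

Stage comparisons of per-islet percentages use one-way ANOVA; GFP-class
comparisons use a two-tailed paired t-test with each islet contributing
one high and one low percentage; detection-fraction comparisons use
Pearson's chi-square on the 2×2 detected/not table without continuity
correction (the cohorts are ~40–90 cells per group, where the correction
would be unnecessarily conservative for a test that is named, not
approximated). Degenerate inputs have documented conventions instead of
NaNs: identical paired percentages report p = 1 with flag `"identical"`;
a constant non-zero difference reports p = NA with flag
`"zero_variance"`; an all-constant ANOVA reports F = 0, p = 1 with flag
`"constant"`. No multiple-testing correction is applied anywhere, by
design.

## Censored qPCR analysis

A transcript is *detected* in a cell iff Ct < 40, strictly; 40 is a
reserved sentinel that detected draws can never produce. Cells failing
detection for any housekeeping gene (*b-actin1*, *ef1a*, *rpl13a*) are
removed before analysis, with the removal count logged. For plotting and
correlation, Ct values map to −log10(Ct), a strictly decreasing
transform under which the sentinel becomes the "undetectable" floor
−log10(40) ≈ −1.6.

Bulk relative quantification uses the standard 2^−ΔΔCt estimator:
per-replicate ΔCt against the reference gene within each group, group
difference ΔΔCt, fold change 2^(−mean ΔΔCt), and a two-tailed paired
t-test of the per-replicate ΔΔCt against zero. Because the reference
gene absorbs any per-replicate plate shift, the estimator is invariant
to adding a constant to all Ct values of a replicate — a tested
invariance.

The fluorescence–expression correlation of index-sorted cells is the
squared Pearson correlation between per-cell GFP fluorescence and
expression on the −log10(Ct) scale, with censored cells excluded by
default (`dropCensored = FALSE` keeps them at the −1.6 floor). The scale
choice is switchable (`scale = "ct"`) since the original analysis does
not state it; −log10 matches the representation scale used throughout.

## FACS population splitting

The division point between GFP-low and GFP-high populations was
originally drawn by hand. The deterministic surrogate
(`splitThreshold()`) takes a Gaussian KDE of log-intensities with
Silverman's bandwidth, keeps modes carrying at least 2% of the peak
density (KDE tail wiggles otherwise masquerade as modes), and places the
gate at the density minimum between the two largest modes; the valley
must dip below 95% of the lower mode, otherwise the distribution is
declared unimodal and a fixed gate is demanded. Proportions follow the
shared tie rule (events equal to the gate are low) and sum to exactly
100 by construction.

## The synthetic-data generator

### What it emulates

`simulateIsletStack()` packs non-overlapping spherical nuclei (radius
3 µm, isotropic 0.5 µm voxels — the scale of adult zebrafish islet
imaging, kept below desk-scale 256³ volumes) into an axis-aligned
ellipsoid flattened 0.7× along z, by rejection sampling with a hard cap
of 10 000 attempts per cell; exceeding the cap is an explicit error
naming the packing limit, never an endless loop. Seven channels are
rendered (DAPI, insulin, NF-kB GFP, EdU, FUCCI red, FUCCI green, mosaic
CFP): DAPI is constant in every nucleus, reporter channels are on/off
per the planted per-cell states, and NF-kB GFP draws per-cell intensity
from a two-component log-normal mixture — the distributional reading of
the bimodal, salt-and-pepper reporter expression; its weights and
log-means live in the scenario file, never in code. The forward noise
model is the standard fluorescence-microscopy one: Gaussian blur (σ in
µm), a constant background, then Poisson shot noise of scaled
intensities. Ground truth (labels, classes, cell states) is recorded
before noise, so recovery tests have an exact reference.

Cheaper stages (single-cell Ct tables, bulk replicate tables, FACS
events, indexed-cell pairs, leukocyte counts) are generated directly at
the table level with the same planting discipline; `render = FALSE`
returns the per-cell truth table of an islet without voxelizing it,
which is what count-based scoring consumes. The unit suite verifies on
rendered islets that the image route (measure, threshold, count) and the
table route agree.

The indexed-cell generator places a latent linear relation on the
−log10(Ct) scale and scales independent Gaussian noise so the population
R² equals the planted value exactly in expectation — `target_r2 = 1`
therefore yields a sample R² of exactly 1, and `target_r2 = 0` yields
independence.

### The paper-calibrated scenario

`paperCalibratedScenario()` loads the packaged YAML whose plants are the
study's reported group means: FUCCI green-only percentages of 1.53 / 0.15
/ 0.06 at 35 dpf / 3 mpf / 1 ypf (5 / 9 / 10 islets); mosaic socs2
proliferation of 8.44% (CFP−) vs 1.08% (CFP+) over 9 islets; NF-kB
reporter positivity of 32.2% in tnfrsf1b-injected larvae (6 animals) vs
2.4% in controls (5); 25% tnfα-reporter-positive intra-islet leukocytes
at 3 mpf; socs2 planted at 2.6-fold in GFP-high sorted cells (the
reported enrichment is "more than 2.5-fold", so the plant sits just
above the bound); a 1.5-fold GFP transcript increase between 3 mpf and
1 ypf; and an indexed-sort R² of 0.28 at n = 5000.

Beta-cells per islet are not reported per stage; the packaged defaults
grow with age (300–600 at 35 dpf, 600–1000 at 3 mpf, 800–1200 at 1 ypf,
150–300 in mosaic 23 dpf islets, 25–40 beta-cells in 5 dpf larvae) as
order-of-magnitude choices consistent with islet growth, and they are
ordinary scenario fields — nothing in the code depends on them. FACS
mixture weights and the EdU/PCNA conditional probabilities reproduce the
reported *orderings* (more GFP-high cells with age; fewer
marker-positive cells among GFP-high) rather than unreported magnitudes.

### What it does not emulate

No depth-dependent PSF, spectral bleed-through, illumination gradients,
or segmentation-hostile nuclear shapes; immune cells are planted count
fractions, not migrating agents. Passing recovery tests therefore
demonstrates that the *analysis* is correct and unbiased under a clean
forward model — not that segmentation or classification would survive
the pathologies of real confocal data.

## Fallback segmentation

When a stack arrives without labels, `segmentNuclei()` provides a
distance-transform watershed in seeded form: global Otsu foreground, a
3D distance-to-background estimate (the minimum of per-plane 2D
Euclidean distance maps over the three axis orientations), seeds at
distance-map local maxima at least one nuclear radius apart, and
nearest-seed assignment of foreground voxels, followed by minimum-volume
filtering (default 40 µm³) and consecutive relabelling. On synthetic
islets at default noise it recovers ≥ 95% of planted nuclei 1:1 at
IoU > 0.5 (tested). When ground-truth labels exist they are always used
directly — segmentation quality is measured, never assumed.

## Determinism and numerical choices

* One root seed governs everything; per-islet, per-table and
  per-replicate streams derive from it by a published multiplicative-hash
  mix (`deriveSeed()`), so any unit can be regenerated in isolation and
  end-to-end runs are byte-identical under a fixed seed (tested).
* Detected single-cell Ct draws are Normal(25, 2) truncated to (0, 40)
  by inverse-CDF sampling, so the sentinel is never produced by a
  detected draw.
* The Gaussian blur is separable, implemented as banded sparse matrix
  products with edge renormalization (flat fields stay flat at
  boundaries).
* Otsu thresholds use a 256-bin histogram maximizing between-class
  variance.
* Bulk simulation plants E[ΔΔCt] = −log2(fold); the 2^−ΔΔCt estimator is
  slightly Jensen-inflated under replicate noise (≈ +0.2% at the default
  0.2-cycle SD), far below the recovery tolerances used.

## Problem sizes

The test suite exercises rendered islets of 15–60 cells and table-level
cohorts of up to 300 replicates; the acceptance script renders 100
full-size 35 dpf islets (~300–600 cells each) for the image-route FUCCI
target and uses 100–200 table-level replicate cohorts per stochastic
recovery target, sizes at which each Monte-Carlo standard error is several
times smaller than the corresponding recovery tolerance. These sizes are
the package's validation choices and are trivially adjustable in the
scripts.

## Known limitations

* The optics model is deliberately minimal (see above); segmentation
  performance on real data will be worse than on synthetic islets.
* The ΔΔCt estimator assumes perfect amplification efficiency; no
  efficiency calibration or melt-curve QC is modelled.
* Mosaic and class comparisons treat islets as exchangeable replicates;
  no mixed-effects modelling of cell-within-islet nesting beyond the
  per-islet paired design.
* FCS files are not parsed; FACS events enter as plain CSV/data.frame
  tables (an upstream converter is assumed).
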