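---
title: "Methods: individual-cell cytometry in hexagonal picowell arrays"
author: "picocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-cell cytometry in hexagonal picowell arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picocyte)
```

## The measurement problem

Micro-well ("picowell") array slides hold individual suspension cells, or
small cell groups, at fixed, re-identifiable positions through staining,
imaging and culture.  The chamber floor is a densely packed hexagonal
lattice of transparent wells at either 20 um pitch (one cell per well) or
100 um pitch (up to ~20 cells per well).  Because the same physical cell
can be re-imaged across sequential staining rounds, several functional
read-outs can be combined per cell:

* **TMRM** — a potentiometric mitochondrial dye.  The whole-cell mean
  fluorescence intensity (mean FI, in camera units, au) proxies the
  mitochondrial membrane potential (MMP); the within-cell standard
  deviation of the signal (FI SD) proxies staining heterogeneity
  (mitochondrial vs cytoplasmic localisation).
* **FDA** — fluorescein diacetate, hydrolysed to fluorescein by
  intracellular esterases.  Five frames at 60 s spacing give a per-cell
  kinetic trace; the ordinary-least-squares slope of FI against time (in
  au/min) measures esterase activity and membrane integrity.  Cells with a
  compromised plasma membrane retain no fluorescein, so their slope is not
  positive.
* **Annexin V (FITC)** and **PI** — the standard early/late apoptosis
  pair: Annexin+/PI- marks early apoptosis, Annexin+/PI+ late apoptosis,
  PI+ alone membrane-compromised (dead) cells.

`picocyte` implements the full analysis chain for such acquisitions:
lattice detection, per-picowell ROI tessellation, segmentation, per-cell
quantification, two-round linking via saved stage positions,
multi-parametric gating, and per-picowell proliferation statistics — plus a
ground-truthed synthetic image generator so that the whole chain is
testable without access to raw micrographs.

## The synthetic field generator

The generator is first-class, tested code; its defaults encode the study
conditions the analysis is meant for.

**Population structure.**  A field is a mixture of functional subgroups
(`subgroup_params()`), each with a mixture fraction, a per-cell TMRM
mean-FI distribution, a per-cell FI-SD distribution, a per-cell FDA slope
distribution, and fixed Annexin/PI status.  All per-cell draws are normals
truncated at 0: the published mean +/- SD values (e.g. an FDA slope of
9.05 +/- 12.2 au/min) would otherwise produce negative intensities.  The
post-thaw preset (`postthaw_subgroups()`) uses the published four-subgroup
composition — live 62%, late apoptotic 18%, early apoptotic MMP+ 5%, early
apoptotic MMP- 14%.  These printed percentages sum to 99, so the preset
renormalises them (each divided by 0.99); the generated live fraction is
therefore 62.6% rather than 62%.  The untreated-culture preset uses the
published spontaneous-apoptosis composition (12% early, of which 9 points
of the total are MMP+, 5% late).  Early-MMP+ channel levels in untreated
cultures are not published; moderate values (TMRM 150 +/- 50 au, slope
18 +/- 8 au/min) were chosen once as plausible "considerable but reduced"
activity and never revisited.

**Occupancy.**  Per-picowell counts are Poisson draws truncated at the
picowell capacity: 20 for the 100-um pitch, 1 for the 20-um pitch.  The
default occupancy mean is 9.6 cells/picowell, the published time-0 value
for 100-um arrays.

**Geometry.**  Cells are disks of default radius 7 um — round suspension
cells with no published morphology model.  The default scale is
0.65 um/px (a x20-objective class value; the acquisitions do not state
pixel size, so this is configuration, not a claim).  Disks are placed
uniformly in their well with pairwise overlap capped at 10% of a cell's
area (the cap relaxes gradually in crowded wells so placement always
terminates).

**Imaging model.**  The camera is 14-bit (values 0..16383).  Transmitted
light shows a uniform bright background, the hexagonal wall lattice as a
dark band of 4 px width along the Voronoi boundaries of the well centres,
and cells as darker disks.  Fluorescence channels show each cell as a disk
over a uniform 50 au background.  Within-cell pixel values are drawn from
a gamma distribution (support >= 0) and affinely standardised so that the
noise-free within-mask sample mean and population SD equal the cell's true
mean and FI SD *exactly*; when the standardisation would produce negative
pixels they are clamped at 0 and the mean is restored by an iterative
shift, trading a slight understatement of the FI SD for an exact mean.
The image is then blurred by an isotropic Gaussian PSF (default sigma
1 px), Poisson shot noise is applied, Gaussian read noise (default SD
20 au) is added, and values are rounded and clipped to the 14-bit range.
PSF and noise follow the standard CCD model; neither is published, and
both are switchable for exactness tests.

**Growth.**  48-hour growth multiplies each occupied well's count by a
ratio drawn from a normal truncated at 0 (default 1.26 +/- 0.71, the
published distribution), rounds, and caps at capacity; colonies stay
confined to their picowell.  New cells clone a random parent's ground
truth; shrinkage removes a random subset.

**What the generator does not emulate:** brightfield texture, cryo-optical
artefacts, uneven illumination, focus drift, cell morphology changes, or
correlations between channels beyond subgroup membership.  Passing the
recovery tests therefore demonstrates that the *analysis chain* is
unbiased under the stated statistical structure — not that it is robust to
every nuisance real micrographs contain.

## Lattice detection

Pitch and orientation come from the autocorrelation of the mean-subtracted
transmitted image (computed spectrally on a centre crop of power-of-two
size): a hexagonal lattice yields six first-order peaks at radius equal to
the pitch.  Peak positions are refined to sub-pixel precision by local
intensity centroids; the basis pair is the strongest peak plus the
ring-peak nearest 60 degrees from it, and orientation is reported modulo
60 degrees (hexagonal symmetry).  If the first-order peak does not exceed
the annulus noise floor by a configurable signal-to-noise ratio (default
5), detection fails with a diagnostic error rather than returning a
spurious grid; known grid parameters can be supplied directly to
`build_roi_map()` in that case.

The lattice origin is recovered by exhaustive search over one unit cell.
The criterion contrasts smoothed image brightness at the predicted well
centres against the three wall-midpoint sublattices (the centres shifted
by half of each bond vector): walls are dark regardless of how many cells
occupy the wells, so this contrast is peaked at the true origin at any
occupancy, with roughly twofold separation from the strongest false
optimum.  The search step stays below the peak width (wall band plus
smoothing) and the winner is polished by Nelder-Mead.  Two cheaper
designs were tried and rejected: scoring centre brightness alone develops
near-degenerate false optima once cells darken the well centres, and
estimating the origin from the Fourier phase at the reciprocal basis
vectors inherits biases of up to a tenth of a period from the coherent
part of the random cell-coverage signal.

ROIs are the Voronoi cells of the lattice sites, computed in O(pixels) by
scoring the 3x3 block of lattice candidates around each pixel's fractional
lattice coordinates.  Interior ROIs are full hexagons of area
(sqrt(3)/2) * pitch^2; sites whose hexagon does not fit inside the image
are flagged and excluded from measurement so that edge truncation cannot
bias area or occupancy statistics.

## Segmentation and measurement

Segmentation runs on the transmitted-light image, where every cell is
visible regardless of staining status — a fluorescence-based segmentation
would silently drop TMRM-negative (dead or late-apoptotic) cells and bias
every population fraction.  Pixels darker than the robust background
(median - 5 MAD) form the foreground; the wall band is removed
*analytically* (pixels within the lattice-boundary band of the ROI map,
default total width 10 px = rendered wall plus PSF tail) rather than by
morphological opening, so cell masks keep their exact boundaries.
Touching cells are split by watershed on the distance map (tolerance 1),
components below 50 px are discarded, and each mask is assigned to the
picowell containing its centroid.

Per-cell statistics are the background-subtracted mask mean (floored at 0)
and the population SD over mask pixels.  The background is the median of
non-cell pixels (cell masks dilated by 4 px are excluded); in fluorescence
channels the well floors and walls are equally non-cell background, so
this is the natural generalisation of "wall-pixel background".  Masks are
eroded by 3 px before measuring (watershed boundaries count as edges;
masks that would fall below 9 px fall back to the full mask): with a
1 px Gaussian PSF the outermost ~2 px of a mask lose signal to blur, and
the erosion removes exactly that biased rim.  Measurement is affine in
intensity, and with PSF and noise disabled the full-mask round trip
reproduces each cell's true mean to < 1 au.

Kinetic traces take the *signed* background-subtracted means (the floor at
0 would bias slopes of dim cells), and the slope is the OLS fit of FI
against time in minutes, with r^2 defined as 1 - SS_res/SS_tot and the
0/0 case of a perfectly fitted constant trace taken as 1.

Positivity calls (Annexin, PI) are strict threshold exceedances; the
default policy is background + 5 background-SDs, resolved per image.  A
cell exactly at threshold is negative.

Rounds are linked by first translating round-2 centroids into the round-1
frame using the saved stage positions, then matching within the same
picowell by nearest centroid within 6.5 px (0.3 of a 21.5 px cell
diameter), greedily on increasing distance.  Unmatched cells are flagged
`matched = FALSE` and excluded from gating as unclassifiable — never
silently dropped.

## Gating

Thresholds are population-relative: 30% of the arithmetic mean TMRM mean
FI and 30% of the mean FDA slope over the analyzed population (all
analyzable cells, not the live subgroup — the most literal reading of a
population-relative rule), plus a fixed low-MMP cut (default 200 au, used
for histogram reporting) and a TMRM detection floor (default 3 background
SDs).  The decision order follows the established Annexin/PI assessment
first:

1. Annexin- and PI- : **live**
2. Annexin+ and PI+ : **late apoptotic**
3. Annexin+ and PI- : **early apoptotic**, split by detectability of the
   TMRM signal into MMP- (below the detection floor) and MMP+; the gate
   path records whether an MMP+ cell is below both 30% thresholds
   ("MMP_low") or not ("MMP_not_low")
4. Annexin- and PI+ : **necrotic/unclassified**, reported as a separate
   flagged class rather than forced into a gate the scheme does not
   define.

The published description leaves open where an Annexin+/PI- cell with
detectable MMP *above* the 30% thresholds belongs; this implementation
keeps it in the MMP+ subgroup and preserves the ambiguity on the gate
path, because the MMP+/MMP- split is defined by detectability and the 30%
rules describe the typical levels of the subgroup rather than a hard gate.
Any missing measurement yields `unclassifiable`.  Cell-level gating is
verified against an independent truth-table oracle on thousands of random
small tables.

## Proliferation

Counts per picowell are taken over interior ROIs, with empty picowells
reported as 0.  The growth ratio of a picowell is count(48 h)/count(0 h),
defined only for wells occupied at time 0; wells empty at 0 h but occupied
at 48 h are flagged as tracking anomalies.  The headline statistic is the
*unweighted mean* of per-picowell ratios (matching the "average ratio"
convention), with totals at both timepoints reported alongside.
"Proliferating" means ratio strictly greater than 1 — the complement
("no change or a decrease") forces the boundary to the non-proliferating
side.  Simulated growth statistics are validated against a Monte-Carlo
oracle of the truncation/rounding/capping model and, for the subset
means, a brute-force conditional-mean oracle.

## Reporting

`compare_groups()` is classical one-way fixed-effects ANOVA on
replicate-level values; the replication unit is the field/device, not the
cell, to avoid pseudo-replication.  Identical group means return F = 0,
p = 1 exactly.  `run_pipeline()` chains simulation, detection,
quantification, gating and (optionally) proliferation from a validated
configuration, and writes a manifest with the configuration, seed, package
version and an md5 checksum of every output — a fixed seed reproduces
every CSV byte for byte.

## Numerical choices and problem sizes

* All randomness flows through explicit integer seeds (`withr::with_seed`);
  there is no hidden global RNG state, and detection contains no
  randomness at all.
* Pixel coordinates are 1-based with pixel centres at integer positions
  (R's native matrix convention); images are matrices indexed (x, y).
* FI SD uses the population (not sample) normalisation, fixed for
  determinism across mask sizes.
* Ties in picowell assignment cannot arise from the centroid rule;
  orientation ties between equivalent hexagonal bases resolve to the
  smaller angle.
* The recovery studies run at the published design points: 1000 cells for
  the mixture and TMRM round trips, 500 cells for the kinetic slopes, 300
  picowells at 9.6 cells/picowell for proliferation.  These sizes make
  3-sigma recovery bands of roughly +/- 4.6 percentage points on the live
  fraction, +/- 5.3 au on the TMRM mean, +/- 3.3 au/min on the slope mean,
  and +/- 0.12 on the growth ratio.

## Known limitations

* The within-cell FI SD is attenuated by the PSF (a 1 px Gaussian reduces
  pixel-level dispersion substantially), so FI SD is comparable between
  cells of one acquisition but is not an absolute estimate of the
  pre-optics dispersion; no acceptance quantity depends on it.
* Intensity units are camera au and are not comparable across experiments
  with different exposure; the package never compares au across
  acquisitions.
* Heavily overlapping cells (beyond the generator's 10% cap) would merge
  under watershed; the published arrays hold round suspension cells at
  densities where this is rare.
* Lattice detection assumes at least a few complete periods in the image
  and a hexagonal (not square or irregular) array.
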