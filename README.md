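# picocyte

Individual-cell image cytometry for hexagonal picowell arrays.

## The problem

Picowell-array slides hold suspension cells (or small cell groups) in a
dense hexagonal lattice of transparent micro-wells — 20 um pitch for
single cells, 100 um pitch for groups of up to ~20 — so that the *same
physical cell* stays identifiable across staining rounds, imaging and
days of culture.  That makes multi-parametric, per-cell functional
read-outs possible: mitochondrial membrane potential from TMRM staining,
esterase activity and membrane integrity from the kinetics of FDA
(fluorescein diacetate) hydrolysis, and apoptosis staging from
Annexin V / PI double staining, plus per-well proliferation by direct
counting.  `picocyte` is the analysis side of such experiments, for
people who have the micrographs and need per-cell numbers:

* **grid detection** — recover the hexagonal lattice (pitch, orientation,
  origin) from a transmitted-light image and tessellate it into one ROI
  per picowell;
* **quantification** — segment cells, measure per-cell TMRM mean FI and
  within-cell FI SD, call Annexin V / PI positivity, fit per-cell OLS
  slopes of FI(t) over a timed FDA series (5 frames / 60 s by default),
  and link the same cells across staining rounds via saved stage
  positions;
* **gating** — the four-way functional classification: live
  (Annexin-/PI-), late apoptotic (Annexin+/PI+), and early apoptotic
  (Annexin+/PI-) split into MMP+ / MMP- by TMRM detectability, with
  population-relative thresholds (30% of the population mean FI and mean
  slope) recorded on each cell's gate path;
* **proliferation** — per-picowell counts across timepoints, growth
  ratios (48 h / 0 h), and the proliferating subset (ratio strictly > 1);
* **synthetic fields** — a ground-truthed generator (14-bit camera model,
  Gaussian PSF, Poisson + read noise, truncated-normal per-cell
  intensities) so the entire chain is testable end to end without any
  raw-data download.

The model at the core of the gating is population-relative: with
per-cell TMRM mean FI `F_i` and FDA slope `s_i`, thresholds are
`0.30 * mean(F)` and `0.30 * mean(s)` over the analyzed population, a
fixed low-MMP cut (200 au) and a TMRM detection floor (3 background SDs);
the slope estimator is ordinary least squares of FI against time in
minutes.

## Worked example

Simulate a post-thaw population, image it in two rounds, and run the full
pipeline:

```r
library(picocyte)

st <- run_multiparametric_study(postthaw_subgroups(), n_cells = 400, seed = 11)
st$scene
#> field_scene: 400 cells in 48 occupied picowells, image 1539 x 1318 px, t = 0 h

print(st$classified$summary[1:4, c("class", "n", "pct", "tmrm_mean_fi", "fda_slope")],
      digits = 3)
#>                     class   n   pct tmrm_mean_fi fda_slope
#> 1                    live 253 63.25     1474.998    36.658
#> 2          late_apoptotic  76 19.00        0.593     0.126
#> 3 early_apoptotic_MMP_pos  17  4.25      433.775     9.049
#> 4 early_apoptotic_MMP_neg  54 13.50        0.405    13.626

unlist(st$classified$thresholds)
#>     mean_fi_30pct       slope_30pct      tmrm_low_cut tmrm_negative_cut
#>        285.461769          7.630238        200.000000         62.269200
```

All 400 generated cells were segmented, linked across rounds and
classified; the recovered class percentages (63.2 / 19.0 / 4.2 / 13.5)
match the generating mixture (62.6 / 18.2 / 5.1 / 14.1 after
renormalisation) within binomial sampling error, and the recovered
per-class channel statistics (live TMRM ~1475 au, live slope
~36.7 au/min) reproduce the generating distributions.  The thresholds row
shows the population-relative gates actually used: an MMP+ cell below
285 au *and* 7.6 au/min is flagged "MMP_low" on its gate path.

Proliferation works the same way:

```r
pr <- run_proliferation_study(n_picowells = 60, seed = 5)
pr$growth
#> growth_summary: 60 picowells, mean ratio 1.261 +/- 0.589, totals 572 -> 701
pr$subsets$proliferating$fraction
#> [1] 0.6
```

## Command line

A thin CLI over the same functions ships in `inst/scripts/picocyte`
(subcommands `simulate`, `detect-grid`, `quantify`, `proliferate`,
`run-all`); the R functions and the methods vignette
(`vignettes/picocyte-methods.Rmd`) are the primary interface.
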