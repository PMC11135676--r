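# pulchkin

Quantitative analysis of pulcherrimin regulation in *Bacillus subtilis*:
production kinetics anchored to the growth-phase transition, flow-cytometry
reporter gating, and differential peak-height analysis of fluorescent
DNase I footprinting — with seeded synthetic-data generators that provide
known ground truth for every stage.

Pulcherriminic acid is a secreted iron chelator whose insoluble red iron
complex (pulcherrimin) absorbs at 410 nm. Its biosynthetic operon is
repressed during exponential growth by the transition-state regulators ScoC
and AbrB and the MarR-family repressor PchR. Asking *when*, *how fast* and
*how much* pigment each regulatory mutant makes — and *where* each regulator
sits on the promoter — requires three separate quantitative pipelines, which
this package implements for anyone analyzing growth-phase-coupled pigment
production, promoter-fusion reporters, or capillary-electrophoresis
footprints.

## The models and statistics

**Production kinetics.** A410 accumulation follows the modified (Zwietering)
Gompertz curve

    y(t) = y0 + (K − y0) · exp(−exp(mumax·e·(λ − t)/(K − y0) + 1))

with baseline `y0`, plateau (carrying capacity) `K`, maximum rate `mumax`
(the slope at the inflection) and lag `λ`. Times are anchored to T0, the
point where log-linear OD600 growth ends: the steepest sliding-window
log-linear fit (R² ≥ 0.99, ODs above the quantitation floor) is extrapolated
and T0 is the first sustained 5% shortfall. Production start is the first
sustained excess of a mutant's fitted curve over the reference background
curve; duration is the inflection-tangent interval `(K − y0)/mumax`; strains
are compared per parameter by Welch t-tests with Bonferroni correction.

**Reporter gating.** `percent positive = 100 · #{events > max(control)}/n`,
with the threshold taken from a no-GFP control so the control itself is
exactly 0% positive; medians are reported on the linear scale.

**Footprinting (differential peak height).** Electropherograms with and
without protein are calibrated to the GeneScan-500 LIZ ladder
(monotone piecewise-linear scan→bp), peaks are detected as strict local
maxima, matched across traces by size, sum-normalized over the matched set,
and subtracted (`D = with − without`, so protection < 0 <
hypersensitivity). Regions are maximal runs of the standardized score
`n·(D − median D)` beyond ±τ, reported in zero-free promoter coordinates
(… −1, +1 … relative to the TSS).

## Worked example

The `analysis/` drivers run the whole study at synthetic scale, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic panel + ground-truth manifest
Rscript analysis/02_growth_kinetics.R
Rscript analysis/03_flow_gating.R
Rscript analysis/04_footprinting.R
```

`02_growth_kinetics.R` prints the per-genotype kinetics (replicate means,
start relative to T0):

```
    strain start_h duration_h max_rate max_a410
    triple   -9.00      26.65  0.03506   0.9474
      pchR   -6.90      15.46  0.03497   0.5509
 pchR_abrB   -6.83      17.63  0.04484   0.8007
 pchR_scoC   -6.03      13.17  0.05990   0.7999
 scoC_abrB   -5.10      10.62  0.06985   0.7518
      scoC   -3.07      11.26  0.03014   0.3497
      abrB   -2.90       9.56  0.03037   0.2999
        WT      NA      11.09  0.00803   0.0997

75 of 105 pairwise comparisons significant at adj. p < 0.05
```

The triple regulator mutant starts producing ~9 h before the transition
(earliest of all backgrounds, already under way at the first sample), the
*pchR* deletion is the strongest single mutant, and WT recovers its
generating plateau K = 0.10 (WT has no start time: it *is* the reference
background). `03_flow_gating.R` recovers the WT reporter at 69.7% GFP
positive (truth 69.8%) with the control at exactly 0%, and
`04_footprinting.R` calls the protected windows:

```
  PchR  protected      +6 .. +28  (23 peaks, mean D -0.0027)
  AbrB  protected      -30 .. +60  (90 peaks, mean D -0.0024)
  ScoC  protected      -10 .. +60  (70 peaks, mean D -0.0025)
```

i.e. the PchR site sits just downstream of the TSS while AbrB and ScoC
protect broad windows spanning the core promoter.

## Layout

- `R/` — package code: coordinates and probes, Gompertz kinetics, T0
  detection, gating, peak/ladder/profile analysis, generators, pipeline
  runners, TSV I/O.
- `analysis/` — the numbered study drivers shown above.
- `tests/testthat/` — oracle-backed unit, property and recovery tests.
- `scripts/acceptance.R` — headline-number reproduction.
- `vignettes/pulcherrimin-analysis.Rmd` — the methods notes: model
  assumptions, parameter choices, design decisions, limitations.
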