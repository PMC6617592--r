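---
title: "From line scans to LiDAR Volume: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From line scans to LiDAR Volume: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swardscan)
library(dplyr)
```

## The measurement problem

Forage breeding trials need per-plot herbage mass, repeatedly, over many
regrowth cycles. Cutting and weighing is destructive and ends the
measurement series; visual scoring is cheap but coarse. A downward-looking
line-scan LiDAR towed along the trial rows measures the canopy surface
non-destructively: each emission yields one lateral profile of heights, and
an odometer stamps every profile with its along-track position. `swardscan`
turns these streams into a per-plot volumetric biomass proxy — the LiDAR
Volume (LV) — and provides the downstream statistics used when calibrating
and exploiting it (percent dry matter, coefficients of variation, relative
growth rates, yield regressions).

## The pipeline

Processing one scanned column proceeds in five steps.

**1. Normalization and filtering.** Columns scanned on the return leg of a
serpentine pass are reversed to increasing odometer. No-return samples
(recorded as `NA`) are counted and flagged; they never contribute to any
later computation. Heights are then smoothed with a centred moving average
*along the lateral axis of each scan line* (default window 5 samples),
skipping invalid samples and truncating the window at the swath edges so no
data is invented beyond what was observed. One scan is one line, so
"the direction of the scan" is read as the within-line axis; smoothing
across successive lines would mix plots near boundaries and couple the
filter to platform speed.

**2. Segmentation.** Plots are sown on fixed geometry, so a column of
declared length $L$ is cut into $k$ equal half-open windows
$[x_0 + (i-1)L/k,\; x_0 + iL/k)$. Half-open intervals assign every boundary
scan to exactly one plot. Occasional misplanted or poorly separated plots
are handled by operator-supplied signed offsets per plot, after which
disjointness is re-validated. $L/k$ must come out to a whole millimetre;
anything else indicates a mis-declared geometry and is refused rather than
allowed to drift down the column.

**3. Ground estimation.** Ground level varies between plots, so each window
gets its own estimate: the 5th percentile (linear interpolation between
order statistics) of all valid heights in the window. Inter-row soil and
canopy gaps populate the low tail of the height distribution even under a
dense canopy, which makes a low quantile robust without needing an explicit
soil classifier. The percentile is configurable; 0.05 assumes at least ~5%
of samples see soil, which holds for single- and paired-row plots where the
swath is wider than the sown row.

**4. Virtual cutting.** Each valid height becomes
$h^+ = \max(h - \text{ground} - c,\, 0)$ with $c$ the virtual cutting
height (default 40 mm). This mimics the residual left by mechanical
defoliation: herbage below the cut would not be harvested and should not
count. $h^+$ is invariant to a common datum shift of heights and ground,
and raising $c$ can only lower it.

**5. Volume integration.** Each line's cross-section area is the
trapezoidal integral of $h^+$ over the lateral axis, taken across the valid
samples: consecutive valid samples are connected, so an isolated no-return
does not delete the canopy around it (strict panel exclusion would bias LV
low by roughly twice the no-return rate — a sensor artifact, not a canopy
property). Leading and trailing invalids truncate the swath instead. The
plot index is then

$$ LV = \frac{\left(\sum_i A_i\right) \times d}{n} $$

with $A_i$ the per-scan integrals, $d$ the along-track distance actually
covered by scans in the window and $n$ the scan count — i.e. mean
cross-section area times distance. Dividing by $n$ makes LV invariant to
scan rate and platform speed, which recurrent scanning of the same plots on
different days requires. Using the *observed* span for $d$ (not the nominal
window length) means partially covered plots are not extrapolated; a
coverage fraction is reported instead. Internally LV is in mm³; the
published index is unitless and a configurable scale factor (default 1)
accommodates legacy magnitude conventions.

Plots whose window holds no valid sample are flagged `empty` and excluded
with a warning rather than reported as zero — silent zeros would corrupt
any downstream regression.

## The raster-surface cross-check

An independent integration path guards the implementation: $h^+$ samples
are binned onto a regular grid over the observed extent (cell means), empty
cells are filled from their nearest occupied cell and masked as
interpolated, and the volume is the cell sum times cell area. For a
constant canopy both paths reduce to height × span × swath and agree
exactly; for smooth canopies on dense regular sampling they agree to well
under 2%. The raster path is a diagnostic and oracle only; the LV equation
above is the operative definition.

## The synthetic field simulator

Real field data for this instrument class are not redistributable, so the
package ships a generator whose ground truth is analytic. A simulated
column is

$$ h(x, y) = g(x) + z_p(y) + \varepsilon, $$

a slow ground sinusoid $g$ (default amplitude 20 mm, wavelength 20 m),
a per-plot canopy profile $z_p$ constant along-track, and Gaussian sensor
noise $\varepsilon$ (default SD 5 mm); samples drop out as no-returns with
probability 0.02 by default. Two canopy families are provided: a **box**
(uniform height over a centred band — an idealized dense row) whose volume
above the cut is closed-form, and a **Gaussian ridge** (peak, SD — a single
row with a rounded crown) integrated by adaptive quadrature. Sample spacing
is equal in both axes and set by a point density; the default 7,000
points/m² is a hundredth of the instrument-class density, keeping a 100-plot
study near 10⁵ samples, with the full density available for convergence
work. A request implying more than 10⁷ samples is refused outright.

What the simulator does *not* emulate: beam divergence and footprint,
multi-return physics, wind motion, specular dropouts correlated with wet
leaves, lodging, weeds, and within-plot along-track structure. Passing
recovery tests therefore demonstrates that the *geometry and arithmetic* of
the pipeline are right under realistic noise and dropout — not that LV
predicts biomass in a particular field, which is an empirical calibration
question requiring harvest data.

## Verification results the test suite computes

* On 100 simulated plots (five 40 m columns of twenty 2 m × 550 mm plots,
  mixed boxes and ridges with heights spanning 150–750 mm, noise SD 5 mm,
  2% dropout, undulating ground), the squared correlation between pipeline
  LV and analytic truth exceeds 0.95 and the median relative volume error
  stays under 5% (measured ≈ 0.997 and ≈ 1%).
* Noiseless box canopies at the full instrument density recover truth
  within 1% per plot, with the moving average off — there is no noise to
  suppress, and smoothing a noiseless step edge across the cut threshold
  leaves a small systematic loss proportional to window × spacing × cut
  that says nothing about the volumetric method.
* Scan-rate invariance (< 1% change on doubled line density), exact
  linearity in canopy height, ground-datum shift invariance,
  duration-weighted RGR additivity and CV scale invariance all hold on
  seeded synthetic inputs.

## Trait statistics

The analysis stage mirrors customary trial summaries. Percent dry matter is
$DW/FW$ (returned as fraction, percent, and the 2-dp fraction that summary
tables conventionally print). The coefficient of variation is
$\sigma/\mu$ with the *sample* ($n-1$) standard deviation — the convention
that reproduces published cultivar-trial summaries exactly, verified in the
tests. Relative growth rate is $(\ln Y_2 - \ln Y_1)/(t_2 - t_1)$ per day;
contraction between scans yields negative rates and is reported as such.
The calibration regression is ordinary least squares of LV on fresh weight;
besides slope, intercept and $R^2$ it reports the X-intercept
$-b/m$ — in grams, the fresh weight at which the index extrapolates to
zero, interpretable as the unscannable residual below the virtual cut. A
normalized covariance (Pearson correlation) matrix of per-entry parameters
checks for entry effects on the calibration.

```{r example}
traits <- ryegrass_cultivar_traits()
coefficient_of_variation(traits$fw_g)
fit <- linear_fit(traits, x = "fw_g", y = "lv")
glance(fit)
```

## Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7).
* Trapezoid panels require two valid samples; lines with fewer contribute
  zero area, and a plot where most lines are that sparse is flagged
  `sparse`.
* The raster path needs at least 2 × 2 cells; a grid coarser than the plot
  is a parameter error, and cell extents divide the observed span exactly
  so the constant-canopy equality is exact, not approximate.
* A canopy cut at or above its top has volume 0 by definition, not an
  error.
* The on-disk dialect stores heights to 0.1 mm; round-trips are exact at
  that precision. The no-return marker is the token `NA` on disk and
  `NA_real_` in memory.
* All randomness in the simulator flows from one mandatory integer seed
  (`withr::with_seed`), so streams are bit-reproducible.

## Known limitations

* The 5th-percentile ground estimator needs soil in view; a canopy
  overhanging the entire swath (e.g. a Gaussian ridge whose tails never
  clear the cut within the swath) inflates the ground estimate and biases
  LV low by a few percent. Widening the swath relative to the row, or
  lowering the percentile, mitigates this.
* The moving average trades speckle suppression against edge blur at the
  virtual cut; with very sharp canopy edges and coarse lateral spacing the
  bias can reach ~1% per plot at default settings.
* LV is a proxy. Converting it to dry-matter yield requires a harvest
  calibration, which is outside what synthetic data can validate.
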