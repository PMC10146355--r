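---
title: "Scoring genotoxicity from high-content gammaH2AX imaging"
author: "genotoxHCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genotoxicity from high-content gammaH2AX imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotoxHCS)
```

## The assay and its model

Phosphorylated histone H2AX (gammaH2AX) accumulates at DNA double-strand
breaks within minutes of damage, which makes its overall immunofluorescence
intensity a sensitive genotoxicity biomarker. In the plate-based form of the
assay, adherent cells in a 96-well plate are stained with a DNA dye (DAPI /
Hoechst, the segmentation channel) and an anti-gammaH2AX antibody coupled to
a Cy3-range fluorophore (the signal channel), and each well is imaged as a
4 x 4 tile of widefield fields. Because non-viable cells detach and are
washed away during staining, the remaining stained nuclei area also serves
as the cytotoxicity readout: no extra viability dye is needed.

Per well, the package computes pooled object-level statistics and then three
derived quantities for each treated condition against its negative control:

* **MoA** (mean fluorescence value over area): the well mean of per-nucleus
  mean Cy3 intensity, divided by the well mean nucleus area,
  `MoA = MFV / area`. Scaling by area penalises conditions whose apparent
  brightness rise merely reflects shrunken, condensed nuclei.
* **fold**: `MoA_sample / MoA_ctrl`. Fold is dimensionless and invariant to
  any common intensity gain (exposure, illumination) and to the spatial
  calibration, which cancels between numerator and denominator.
* **RA** (relative area): `100 * area_sample / area_ctrl`, the proxy for
  relative cell counts used by the flow-cytometry version of the assay.

The decision rules are: fold > 1.5 with RA > 25% is **genotoxic**; fold
< 1.5 at any RA is **non-genotoxic**; fold > 1.5 with RA < 25% is a
**cytotoxicity-driven false positive** (too few surviving cells to trust the
signal); fold exactly at 1.5 with RA >= 25% is **equivocal**. Two cells of
this table are undefined (fold exactly 1.5 with RA < 25%, and fold > 1.5
with RA exactly at 25%); rather than silently coercing them, the package
returns `NOT_EVALUABLE` with a warning. RA above 100% (proliferation beyond
control) is reported as-is and classified by the same rules -- the 0-100%
range in the rule table is descriptive, not a clamp.

```{r}
fold <- foldChange(moa(2.179, 1.423), moa(1.641, 2.130))
ra <- relativeArea(1.423, 2.130)
c(fold = fold, ra = ra)
classifyGenotox(fold, ra)
```

## Image analysis steps and their parameters

**Sorting.** Acquisition software dumps all fields of a plate into one
folder, named `ChannelName_DateToken_Well_PositionInWell_AcqRun.tif`.
`sortPlate()` groups files by well and pairs DAPI with Cy3 by exact
position-token match (not ordinal rank, so a missing field cannot shift the
pairing). The date token is treated as an opaque string: its day-field width
is ambiguous in the convention, and nothing downstream needs a date.
Channel token spellings vary between installations, so the canonical-name to
token map is a parameter everywhere filenames are touched.

**Segmentation.** Nuclei are detected in the DAPI channel by Otsu
auto-thresholding on a 256-bin histogram spanning the image's own
`[min, max]` range (the convention ImageJ applies to data deeper than
8 bits). Foreground is *strictly above* the threshold, and criterion ties
resolve to the lowest qualifying bin -- both fixed so results are
bit-reproducible. By default the threshold is computed once per well, on the
lexicographically first field, and propagated to the other 15 fields; this
stabilises segmentation across fields of the same well, where staining is
common but content varies. Because the source of the well threshold is a
genuinely open choice, a pooled-histogram mode (`per_well_pooled`) and an
independent per-image mode are provided, and the mode plus threshold values
are written to the run log. Objects are 8-connected components; objects
touching any image border are discarded to avoid truncated-area bias. No
size filter and no hole filling are applied by default, though both exist as
options (`minAreaPx`, `fillHoles`). There is deliberately no declumping /
watershed step and no focus counting: the statistic of interest is overall
intensity, and every extra segmentation heuristic is a reproducibility
liability.

**Background subtraction.** Before measurement the Cy3 channel (never the
DAPI channel) is background-subtracted with a rolling ball of radius 50 px.
The package defines the operation exactly as grayscale opening with a
sphere-cap structuring element: the background can contain no structure
smaller than the ball, never exceeds the image, and subtracting it is
invariant to constant offsets and idempotent. Classic ImageJ instead uses a
sliding-paraboloid approximation with internal image shrinking; per-pixel
values can therefore differ slightly from ImageJ's, which is immaterial for
fold and RA since both are ratio statistics (verified on synthetic plates).
For radii above 10 px the opening runs on a block-minimum shrunken copy
(factor 2/4/8 growing with radius, ImageJ-style) and is interpolated back,
then clamped below the image; `shrink = 1` forces the exact opening and is
what the test-suite oracle compares against. An optional 3 x 3 mean
pre-smoothing of the background-estimation copy exists but defaults to off.

**Measurement and well statistics.** Per-nucleus mean background-subtracted
Cy3 intensity ("MFV") is measured under the DAPI-derived label exactly (no
ROI dilation). Objects from all 16 fields of a well are pooled with no
per-field averaging. Because the per-object distributions of this assay are
heavy-tailed, each feature is screened with a Jarque-Bera omnibus
skewness/kurtosis test (verdict at alpha = 0.05, minimum n = 8) and
dispersion is reported as the IQR, computed with the linear-interpolation
quantile convention (`quantile` type 7) -- the IQR value depends on this
convention, so it is fixed and documented. The well *mean* is reported
alongside despite the non-normality because the MoA/fold statistics consume
means; the median is exported too for inspection. The normality verdict
never gates the pipeline.

## The synthetic plate generator

`generateField()`/`generatePlate()` replace the microscope for development
and validation. Each field receives elliptical nuclei (area-preserving axis
ratio 0.75-1, orientation uniform) with normal radii (mean 6 px, sd 1.2,
truncated at 3 px), placed by rejection sampling so that nuclei never
overlap -- the segmentation has no declumping step, and simulator realism
must not be confounded with segmentation limits. Per-nucleus amplitudes are
log-normal; treatment effects are multiplicative: `cy3Gain` on the Cy3 pixel
amplitude, `areaScale` on nucleus area, `countScale` on expected count,
matching the observed direction of a genotoxic and cytotoxic compound
(brighter gammaH2AX, smaller/fewer nuclei). Both channels are blurred
(Gaussian sigma 1 px, emulating soft nuclear edges at 10x), receive an
additive planar background gradient, Poisson shot noise and Gaussian read
noise, and are quantised to 16 bits. Defaults: 16 fields per well of
512 x 512 px (a 2048 x 2048 sensor binned 4 x 4) at 2.6 um/px, about 120
nuclei per field so pooled well totals land near 1900, inside the 1000-3000
objects per well typical of the assay. The published per-well nuclei areas
of roughly 1-3 "um^2" are not plausible for nuclei at this magnification,
so the generator's geometry was chosen at the pixel scale and the spatial
calibration is left configurable; the scale-invariant ratios (fold, RA) are
what the validation leans on.

A note on what the injected effects imply: since `cy3Gain` acts on pixel
amplitude and `areaScale` on area, the recoverable quantities are the MFV
ratio (close to `cy3Gain`), RA (close to `100 * areaScale`), and the MoA
fold, which composes both as `cy3Gain / areaScale`. End-to-end tests assert
all three. The recovered MFV ratio sits a few percent below the injected
gain because threshold-boundary pixels of the blurred edge dilute small
nuclei slightly more than large ones; the effect is at the percent level
for the default geometry and largely cancels in the ratios.

```{r, eval = FALSE}
cfg <- syntheticPlateConfig(seed = 11L)
dir <- tempfile()
generatePlate(cfg, dir)
res <- runPipeline(dir, file.path(dir, "out"), layoutFromConfig(cfg))
res$conditions
```

What passing on synthetic plates does *not* show: real plates add uneven
illumination beyond a plane, optical PSF structure, apoptotic morphology
(fragmented, intensely stained nuclei that can inflate the signal at late
time points), touching nuclei at high confluency, and channel crosstalk.
The generator intentionally models none of these.

## Numerical choices and degenerate inputs

* Otsu on a constant image has no threshold; the error is raised with a
  dedicated condition class, the well is flagged in the log and excluded,
  and dependent condition results become `NOT_EVALUABLE` -- never silently
  zeroed.
* Thresholds returned are integers on the intensity scale, chosen so that
  "strictly above threshold" coincides exactly with the chosen histogram
  cut on integer data.
* A rolling ball larger than both image dimensions is an error.
* Empty wells produce an `nObjects = 0` summary with undefined means and a
  warning; header-only CSVs are still written so output schemas are stable.
* Fields missing one channel are kept for DAPI-based thresholding but
  yield no intensity records; the incomplete pair is flagged.
* CSVs use "." decimals and "," delimiters; reruns on identical input are
  byte-identical except for the log's timestamp line.
* Per-field RNG streams are derived deterministically from (seed, well,
  field index), so generated fields do not depend on generation order.

## Problem sizes used in the test suite

Unit tests run on constructed fixtures of 30-200 px and small synthetic
plates (2 wells x 3 fields of 256 x 256 px, ~50 nuclei per field), enough
for stable well means at second-scale runtimes. The end-to-end recovery
check runs one full-scale plate (3 conditions x 16 fields of 512 x 512 px,
~120 nuclei per field, low noise) -- about half a minute of compute -- and
the threshold oracle check covers 200 random 8- and 16-bit images.

## Known limitations

* The rolling-ball background differs per-pixel from ImageJ's legacy
  sliding-paraboloid implementation (documented contract here: exact ball
  opening, optionally shrink-accelerated).
* Single wells per condition yield descriptive statistics only; no
  replicate-based inference is attempted.
* No dose-response modelling, no foci detection, no multi-endpoint
  high-content scoring, no proprietary microscope formats or OME metadata.
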