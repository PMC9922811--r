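---
title: "Methods: automated tumor-stroma ratio scoring"
author: "tsrscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tumor-stroma ratio scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrscore)
```

## The problem

The tumor-stroma ratio (TSR) is a prognostic factor in colorectal cancer:
patients whose tumors are stroma-rich (more than 50% stroma in the most
stroma-rich tumor field) do worse. Conventionally a pathologist selects,
by eye, the "hot-spot" — the field of view with the highest relative
amount of stroma, at 100x magnification (a circle of about 2.0 mm
diameter) — and estimates the stroma percentage in increments of 10%.

tsrscore automates this scoring on top of a pixel-level tissue-class
segmentation of the slide. The segmentation model itself is out of scope:
the package starts from a label map, a 2-D grid of integer codes naming
one of 13 classes per pixel (background plus 12 tissue types), with a
physical pixel spacing in micrometres. Two scoring modes are provided,
mirroring the two levels of automation used when such algorithms are
evaluated against human observers, plus the statistical battery used for
that comparison.

## Semi-automated scoring

In semi-automated mode the hot-spot is still chosen by a human and
supplied as a circular ROI (centre + diameter, default 2.0 mm). The score
is a pure pixel ratio inside the circle:

$$\mathrm{TSR}_{semi} = 100 \cdot
  \frac{\#\,\text{stromal pixels}}
       {\#\,\text{ROI pixels} - \#\,\{\text{mucus, necrosis, background}\}}$$

where the stromal classes are tumor-associated stroma, lymphocytes,
erythrocytes, muscle, healthy stroma, nerve and stroma lamina propria.
Only mucus, necrosis and background leave the denominator; fatty tissue
stays in it (excluding fat is part of the *visual field-selection*
protocol, not of this formula, which we follow literally). An ROI whose
denominator is empty (all mucus/necrosis/background) is *unassessable*
and raises a dedicated error class rather than returning a number.

Circle membership is deterministic: a pixel belongs to the ROI when its
centre lies within the radius (inclusive). Physical radii convert to
pixels by round-half-up; the same single convention is used everywhere in
the package so that module boundaries cannot disagree by one pixel.

## Fully automated scoring

Without a human hot-spot the pipeline must decide *where* scoring is
meaningful and then find the hot-spot itself:

1. **Tumor bulk.** All tumor-gland pixels are taken as seeds and
   post-processed into the "tumor bulk" — the region enclosing all tumor
   glands, including the invasive edge. No specific concave-hull
   algorithm is canonical here, so the bulk is operationalized as a
   deterministic morphological pipeline: closing with a disc (default
   radius = the field-of-view radius, 1.0 mm), hole filling, and removal
   of connected components smaller than a minimum area (default = one
   field-of-view area, $\pi$ mm$^2$), which discards small
   false-positive specks. All three parameters are exposed; setting them
   to zero degrades gracefully to the filled gland components.
2. **Valid centres.** A circle centre is admissible when its whole
   2.0 mm field of view lies inside the bulk and contains no background
   (lack of tissue or tears). This is exactly a binary erosion of the
   bulk by the circular structuring element, with an extra
   background-free condition evaluated with the same disc. A slide whose
   tumor area is too narrow to fit the circle anywhere is *unassessable*,
   which reproduces the known failure mode of this design on narrow
   tumor areas.
3. **TSR heatmap.** Sliding the circle over the slide and counting
   classes per position is a convolution, so per-class in-circle counts
   are computed in the Fourier domain (zero-padded 2-D FFT, kernel = the
   binary disc). Counts are rounded back to integers and cross-checked:
   if the raw convolution deviates from integrality by more than
   $10^{-3}$ of the disc area a numerical-integrity error is raised;
   tiny negative artifacts are clipped at zero. This makes the FFT path
   *exactly* equal to brute-force per-centre counting, which the test
   suite verifies against an independent direct-summation oracle. The
   heatmap value is
   $100 \cdot S/(S+T)$ with $S$ = tumor-associated stroma + lymphocytes
   + nerve + erythrocytes and $T$ = tumor glands + healthy glands
   (healthy glands inside a tumor bulk are, in practice, well
   differentiated tumor glands). Note the deliberate asymmetry with the
   semi-automated formula: muscle and healthy stroma are stromal in semi
   mode but not here; both groupings are kept distinct in the class
   scheme rather than unified, because each mode's definition is stated
   independently and neither is derivable from the other.
4. **Validity rules.** Fields with too much nuisance tissue are
   invalidated: fat $\ge$ 5%, erythrocytes $\ge$ 10% or necrosis
   $\ge$ 30% of the disc area. The thresholds are strict
   (a field exactly at a threshold is dropped — the bounds are written
   as "< 5%" etc.), and fractions are relative to the full disc area;
   background inside the disc is already impossible after step 2.
5. **Hot-spot ranking.** TSR-1 is the global heatmap maximum; each next
   rank is the maximum after zeroing a suppression region *as large as
   the field of view* (a disc of one FOV radius) around the previous
   selection. A circular region is used for geometric consistency with
   the field itself; ties break towards the smallest row, then column,
   making results fully reproducible. Ranks are therefore non-increasing
   and pairwise centres are always more than one radius apart.

The heatmap is computed at stride 1 (every pixel a candidate centre); a
stride parameter exists purely as an efficiency knob for very large
slides and is pinned to 1 in all oracle tests.

## Observer-agreement statistics

The comparison battery mirrors how such scoring methods are evaluated
against pathologists:

* **Consensus rule** — three raters score in 10% increments; when all
  three or two of three agree, that value is the consensus, otherwise
  the case is flagged `needs_meeting` and is never auto-resolved (such
  cases are excluded from statistics unless a resolved value is
  supplied).
* **Dichotomization** — stroma-low (≤ 50%) vs stroma-high (> 50%).
* **Cohen's kappa** — unweighted, on the dichotomized labels (the
  setting in which kappa is conventionally reported for TSR).
* **ICC** — the model is not uniquely implied by "ICC" alone; we use
  ICC(2,1), two-way random effects, absolute agreement, single measures,
  the standard choice for interchangeable human raters when the clinical
  question is "do they give the *same percentage*", and the model name
  is emitted in every report. The 95% CI uses the F-distribution bounds
  with Satterthwaite degrees of freedom. No installed package provides
  this model with its CI, so it is implemented from the ANOVA mean
  squares and verified against an `aov()`-based oracle to $10^{-10}$;
  simulation shows the CI covers a known true ICC in ~94% of replicates.
* **Spearman** — Pearson correlation of mid-ranks (tie-aware, important
  on the 10% grid), p-value from the t approximation; adequate at the
  n ≈ 75 scale these studies use, so no exact permutation by default.
* **Bland-Altman** — mean difference ± 1.96 SD of differences.
* **t-tests** — via `stats::t.test()`, with the all-zero-difference
  paired case flagged rather than erroring.

## Synthetic fixtures

Real slides and segmentation weights are not redistributable, so every
stage is tested against generated label maps with analytic ground truth.
The generator emulates the structure the fully automated pipeline
assumes: one roughly circular tumor blob (sinusoidal boundary roughness)
whose interior pixels are drawn *per-pixel Bernoulli* between
tumor glands and tumor-associated stroma from a planted stroma-fraction
field (base level + Gaussian bumps with known peak location), optional
solid nuisance discs of fat/erythrocytes/necrosis with exactly
constructible in-disc fractions, and background outside. Per-pixel
labelling (rather than smooth regions) is deliberate: expected in-disc
counts equal the disc-mean of the planted field, so recovery tolerances
are derivable. The ground truth includes the disc-smoothed field and its
argmax, computed by *direct* spatial summation, independent of the FFT
path it is used to check.

Default study conditions (chosen once, as realistic desk-scale
conditions): a 640×640 grid at 8 μm/pixel (a 5.1 mm square region; tests
use 512×512 at 10 μm/pixel), tumor blob radius 2.2 mm, base stroma
fraction 0.4 with one bump of amplitude +0.3 and σ = 0.5 mm, rater noise
SD 5 percentage points on the 10% grid, three raters. The scoring
constants are fixed by the protocol being automated: 2.0 mm field of
view, 50% cut-off, 10% increments, fat/erythrocyte/necrosis validity
bounds of 5/10/30%. At 10 μm/pixel the FOV radius is 100 px, so the
Bernoulli SD of a disc mean is
$\sqrt{0.25/31416} \approx 0.3$ percentage points — comfortably inside
the ±1 point recovery tolerance the tests assert.

What the generator does **not** emulate: realistic tissue morphology
(gland architecture, stroma texture), spatially correlated segmentation
errors (only a flat label-flip rate is available), staining variation,
and scanner artifacts. Passing tests therefore demonstrate correctness
of the *scoring machinery* given a segmentation, not robustness to
segmentation error on real slides.

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 7)
gen  <- generate_labelmap(spec)
ana  <- fully_auto_tsr(gen$map, tissue_scheme())
summary(ana)
```

## Numerical choices and limitations

* FFT sizes are padded to products of small primes; counts are exact
  after rounding (verified, not assumed — the integrity check is always
  on).
* Closing is forced extensive (original gland pixels are unioned back
  in) so border-touching tumors are never eaten by the dilate-erode
  pair's zero padding.
* Centres closer than one radius to the image border are never valid:
  their circle leaves the grid.
* `round_half_up()` is used for all physical-to-pixel conversions; base
  R's round-half-even would make circle sizes depend on parity.
* The 8-bit raster I/O limits class codes to 0–255, which is ample for
  13 classes.
* Degenerate inputs are first-class: empty bulk, too-narrow tumor, ROI
  of pure mucus/necrosis/background, constant raters (undefined kappa /
  ICC) each raise a distinct condition class, and the CLI maps them to
  distinct exit codes.
* Performance: the direct-summation oracle decomposes the disc into row
  chords over per-row prefix sums, $O(r \cdot N)$ — slower than the FFT
  but exact and transform-free, which is what makes it a meaningful
  oracle.
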