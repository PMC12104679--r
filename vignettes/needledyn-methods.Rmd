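---
title: "Methods: needle-angle dynamics and image-based drought-stress detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: needle-angle dynamics and image-based drought-stress detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needledyn)
```

## The problem

Conifer seedlings raised in nursery systems are highly vulnerable to
drought, and the economically relevant question is not *whether* a
water-stressed seedling eventually shows damage but *how early* the stress
can be read off non-destructive measurements. `needledyn` implements a
complete analysis chain for side-view time-lapse experiments on potted
seedlings under a controlled drought contrast: a control group irrigated
daily and a drought group with irrigation withheld from day 1, imaged
twice a day (morning and evening) over a week. The chain quantifies three
families of indicators --- apical needle-angle parameters, whole-seedling
binary-mask morphometrics, and thermal/physiological covariates --- and
asks, for each parameter, at which capture session the two groups first
diverge.

Because the motivating experiments deposit no raw images, the package
ships a first-class synthetic-experiment generator. Every downstream
stage (colour correction, segmentation, morphometrics, angle derivation,
thermal indices, statistics) is exercised end to end against the
generator's ground truth.

## Needle-angle model

The needle angle $\theta$ is the signed interior angle between the
horizontal through a needle's base and the base-to-tip vector, clamped to
$[-90^\circ, +90^\circ]$; tips above the horizontal are positive. In
image coordinates (origin top-left, row $y$ increasing downward) this is

$$\theta = \mathrm{atan2}\!\left(y_\text{base} - y_\text{tip},\;
  |x_\text{tip} - x_\text{base}|\right)\cdot 180/\pi .$$

Individual needles cannot be tracked reliably across sessions, so the
apical image is divided into four quadrants at the centre of the apical
bounding box; needle angles are averaged within each quadrant and the
session value is the unweighted mean of the non-empty quadrant means
(`quadrant_mean()`). Quadrant means are *not* needle-count weighted: the
quadrant average exists precisely to stop a densely needled quadrant from
dominating, and the convention is documented rather than configurable.

Derived parameters (`derive_angle_parameters()`), all in the
"reference minus current" direction so that positive values mean the
needles dropped (wilting) and negative values mean they rose (recovery):

* **BD-M** --- pre-drought (baseline session `BD`) angle minus current;
* **PM-M** --- immediately preceding session minus current;
* **PM-M(ST)** --- previous session of the same time of day minus
  current. `BD` counts as the day-0 morning, so `D1M` references `BD`
  while `D1E` has no same-time predecessor.

**STx bins** partition $[-90^\circ, +90^\circ]$ into six 30-degree
intervals, left-closed except the last (`ST6` includes $+90^\circ$
exactly); `stx_level()` scores them 1--6 when a numeric response is
needed for regression.

**Vitality bookkeeping** (`classify_vitality()`): a session counts as
wilted when the drop from baseline is at least `wilt_drop_min` (default
15 degrees; the motivating work assessed this visually, so the threshold
is a synthetic-pipeline parameter and config-exposed). The state display
marks survival, recovery (the morning immediately after a first wilt, if
the angle returned within the threshold) and death (apical discoloration
at or above `dead_frac`, default 0.8; absorbing). Seedlings with an
unmeasurable apical part are excluded from that session's tally.

## Mask morphometrics

All eleven seedling-level features are computed from a binary mask under
two self-consistent coordinate conventions:

* **pixel centres** for centre of mass, fitted-ellipse centre and the
  longest-path centroid test: pixel $(r, c)$ (1-based matrix indices)
  has centre $(x, y) = (c-1, r-1)$;
* **corner lattice** (pixel as unit square) for hull area and perimeter,
  so a filled convex digital shape has solidity exactly 1 and area and
  hull area share units. The crack-boundary perimeter of a $10\times10$
  square is 40 and of a single pixel 4.

The *longest path* reading of "longest distance passing through the
centre" is: the maximum Euclidean distance between two boundary corner
points whose connecting segment passes within `eps` (default 0.75 px) of
the mask centroid; if no chord qualifies, twice the maximum
centroid-to-boundary distance is reported and flagged. The candidate set
is enumerated exactly up to 1200 boundary corners (which covers every
mask up to 32 x 32) and reduced to convex-hull vertices above that, a
documented speed approximation for full-scene masks. The *ellipse
centre* fits an algebraic conic to the outer-contour pixel centres by
total least squares and reports the conic centre; the contour-based
reading ("fitted to the outline") is a convention choice --- whole-mask
moment fitting would be equally defensible, and for the symmetric shapes
in the tests both agree.

Segmentation (the front end feeding the morphometrics) is chart-based
colour correction (affine by degree-1 least squares; a polynomial degree
would fit the original framework but degree 1 is invertible and
testable), an excess-green ($2G-R-B$) Otsu cut in automatic mode or
inclusive RGB/HSV bounds in manual mode, component cleanup
(8-connectivity, minimum size, hole filling with 4-connected background),
and ROI-based per-plant separation in which a connected component is
assigned *wholly* to the ROI of maximal overlap --- so a tall seedling
reaching above its rectangle keeps its crown. Ties go to the lowest ROI
index and are logged.

## Thermal indices

With $T_l$ leaf and $T_a$ air temperature (degC) and $AH$ relative
humidity (percent), the package implements the Tetens-form vapour
pressures and the derived stress indices, in kPa and degC:

$$\mathrm{LVP} = 0.61078\, e^{17.27\,T_l/(T_l+237.3)},\qquad
  \mathrm{AVP} = 0.61078\, e^{17.27\,T_a/(T_a+237.3)}\cdot AH/100,$$
$$\mathrm{VPD} = \mathrm{LVP} - \mathrm{AVP},\qquad
  \mathrm{CWSI}(T_l) = \frac{T_l - T_{lw}}{T_{ld} - T_{lw}},$$
$$\mathrm{CWSI}(T_l - T_a) =
  \frac{(T_l - T_a) - (T_{lw} - T_{aw})}{(T_{ld} - T_{ad}) - (T_{lw} - T_{aw})},\qquad
  \mathrm{LTD} = \overline{T_l}^{\,\text{control}} - T_{l,i}.$$

Two interpretation choices are deliberate and config-visible. First, the
denominator symbol in the $\mathrm{CWSI}(T_l)$ source print is read as
$T_{ld}$, the only defined maximum leaf temperature. Second, the wet/dry
reference anchors $T_{lw}, T_{ld}, T_{aw}, T_{ad}$ are the min/max
*pooled across both treatments within a capture session*, so control and
drought share anchors; the scope is recorded in the output and
per-treatment scoping is available by pre-filtering. LTD is computed for
every seedling including controls, which makes the control-group LTD
average exactly zero each session --- a useful internal check. Leaf
temperature per seedling is the mean of thermal-map pixels under the
seedling's mask (`NaN` dead pixels excluded), standing in for the
labelled-region averaging of an IR camera workstation.

## Statistical battery

* `rm_anova()` --- univariate mixed repeated-measures ANOVA for balanced
  complete designs: one between-subject factor crossed with one (2-way)
  or two (3-way) within-subject factors, subjects nested in treatment.
  Between effects test against subjects-within-groups; each within
  effect and its treatment interactions against the matching
  subject-by-factor stratum. Missing cells are a hard error that names
  the offending cells --- the caller filters dead seedlings first. No
  sphericity correction by default; Greenhouse-Geisser sits behind
  `gg_correction`.
* `pairwise_t_bonferroni()` --- all pairwise t tests on one comparison
  axis with family size $m$ = number of pairs and $p_{adj} = \min(1, m\,p)$.
  Comparisons across days within a treatment are paired on the subject
  id; across treatments, unpaired (the source material does not state
  its pairing; both are supported and this default is documented).
* `compact_letter_display()` --- insert-absorb with a completion pass;
  minimality of the letter count is not guaranteed, correctness is:
  groups share a letter iff non-significant.
* `kw_mw_battery()` --- tie-corrected Kruskal-Wallis, then pairwise
  Mann-Whitney with Bonferroni when the omnibus test is significant. The
  exact rank-sum null is used whenever the data are tie-free (combined
  n up to 100); with ties, the tie-corrected normal approximation. Using
  the exact null beyond tiny samples matters: with n = 10 vs 10 the
  normal approximation cannot produce a two-sided p below roughly
  2e-4, which would make small-sample parameters undetectable under a
  report-wide Bonferroni family.
* `stepwise_regression()` --- forward selection with backward
  elimination on partial-F p values, entry 0.05 / removal 0.10 (the
  de-facto defaults of classic stepwise implementations; the source
  material does not print its thresholds, so they are exposed as
  arguments). Near-collinear candidates (tolerance ~ 0) are skipped
  with a warning. Reported diagnostics: R^2, adjusted R^2, final-step F
  change and its p, per-predictor p, tolerance, VIF = 1/tolerance,
  standardized betas from a refit on z-scored data, and the
  Durbin-Watson statistic of the residuals in supplied row order.
* `pca_cor()` --- eigendecomposition of the correlation matrix;
  orthonormal loadings, scores of the standardized data, variance
  proportions.

## The synthetic world

`experiment_config()` fixes the scenario; `simulate_experiment()` renders
it. The defaults are the stated world of the package's tests:

* **Design**: 30 seedlings per treatment over 7 days (`BD`, then
  `D1M/D1E` ... `D6E`); 10 per treatment appear in rendered frames, four
  plants per frame (control, drought, control, drought) above a black
  background with a 24-patch colour chart strip. The wider cohort mirrors
  a design in which angle digitisation and instrument covariates cover
  more seedlings than the imaging rig.
* **Wilt/recovery/death**: every drought seedling wilts at `D2E` (the
  stated first-signs session), with a per-seedling angle drop of
  17 +/- 5 degrees --- chosen so the group-mean BD-M at onset (~17
  degrees) mirrors the reported onset-session moment --- and an apical
  sag of 18 +/- 4 px (about 20% of the 92-px stems). The sag drives the
  centre-of-mass(y) and height signals; at the rendering scale it is
  conservative relative to the ~25-px CoM(y) displacement reported on
  real images. 70% of wilted seedlings recover the following morning
  (evening-wilt/morning-recovery cycling thereafter) and the apical part
  dies 1--2 days after first wilting: discoloration starts at 0.7 and
  accrues 0.3/day, which takes the rendered apical tissue out of the
  excess-green mask range, exactly as a fully wilted crown drops out of
  a colour-range mask.
* **Physiology and temperature**: drought PhiNPQ rises to 0.24 +/- 0.04
  from day 6 (control 0.13 +/- 0.04), with companion drops in Fv'/Fm'
  and PhiII; the D6 spread is kept at the pre-stress instrument-level SD
  because the generator draws values for measurable tissue --- the much
  larger printed D6 dispersion of real cohorts mixes seedlings at
  heterogeneous stages of dying, which the generator does not model.
  Needle temperature is air temperature minus 2 degC of transpirational
  cooling, plus a drought shift of 1.6 +/- 0.5 degC from day 6 (matching
  the reported day-6 LTD of about -1.6 degC).
* **Environment**: session-level series with the reference means/SDs
  (AH 79.13 +/- 13.88%, AT 30.46 +/- 4.72 degC, SR 194.32 +/- 233.92
  W/m2, ST 29.55 +/- 4.06 degC), a diurnal structure (humidity and
  radiation higher in the morning, temperature higher in the evening,
  amplitudes folded into the total SD so the configured moments are
  preserved), control soil moisture stable at 29.48 +/- 1.22% and
  drought soil moisture declining linearly to 13.97%.
* **Rendering**: plants are a two-pixel stem polyline with needle
  segments in whorls; the apical region is the top 20% of the stem and
  carries 12 annotated needles (3 per quadrant). Scenes receive an
  affine per-channel capture distortion plus Gaussian sensor noise, so
  chart-based colour correction is exercised end to end. Thermal maps
  are per-pixel true leaf temperature + N(0, 0.2 degC) over plant
  silhouettes and air temperature elsewhere. The stated ground-truth
  pixel set is the *filled* silhouette: pockets enclosed between
  crossing needles belong to the plant region, matching the fill-holes
  cleanup convention downstream.

All randomness flows from one integer seed with per-seedling and
per-frame substreams, so identical configs are bitwise reproducible and
per-seedling draws do not depend on rendering order.

What a green test does **not** establish: the generator produces neither
photorealistic canopies, nor 3D geometry, nor mechanistic chlorophyll
fluorescence (physiology is drawn from configured distributions), nor the
staggered wilt onsets, partial canopy dieback and weather-driven
variation of real nurseries. Detection results on synthetic scenes
validate the *pipeline logic*, not field performance.

## Detection logic

`run_pipeline()` composes the stages and, per parameter and session,
compares drought against control: BD-M / PM-M / PM-M(ST) per seedling
for angles (a session enters only while at least `min_angle_values = 30`
individual drought needle measurements remain, encoding the "at least 30
angle values" analysis rule); baseline-minus-current differences of the
eleven morphometric features (differencing removes between-seedling
geometry, which is what makes a 10-seedling imaging design detect a
6-pixel shift); raw instrument covariates per day; and the thermal
indices per session. Test choice follows the sample-size rule --- groups
of n <= 10 use Mann-Whitney, larger groups a pooled t test.

The Bonferroni family is **every test in the report** (m ~ 290 under the
default scenario). This is stricter than correcting within one
parameter's sessions, and it is a design choice: the report's contract
is "which parameters fire, and when", so its type-I error should be
controlled report-wide --- under a null scenario the chance that *any*
parameter flags is about alpha. The earliest session per parameter is
the first with adjusted p strictly below alpha; increasing alpha can only
advance, never delay, detection. Session granularity is morning/evening,
not day, because the earliest real signal is specifically an evening
phenomenon. Electrical conductivity is carried as a covariate but no
irrigation-EC mechanism is modelled, so the generator gives it no
treatment contrast.

On the default scenario the report reproduces the qualitative headline
ordering: the three needle-angle parameters and centre of mass(y) (with
height and ellipse centre(y) alongside) flag at `D2E`, while PhiNPQ and
all thermal indices flag no earlier than day 6 --- image-based apical
signals lead physiology by about four days.

## Numerical and degenerate-input choices

* Empty masks yield flagged records, not exceptions; empty thresholds
  warn; a singleton or constant temperature session is a hard error for
  CWSI (zero reference span).
* The Otsu cut maximises between-class variance over 256 bins of the
  observed range; with a clean bimodal signal the argmax lies in the
  inter-mode gap (ties resolve to the lowest bin, i.e. the upper edge of
  the background mode).
* Conic fitting centres the contour before the SVD for conditioning and
  declares degeneracy when the fifth singular value vanishes (collinear
  or sub-minimal contours).
* Exact-zero residuals make Durbin-Watson undefined (flagged `NA` with a
  warning); degenerate pairwise tests (constant data) short-circuit to
  p = 1 for identical groups and p = 0 for a constant nonzero shift.
* `stepwise_regression()` requires `removal_p >= entry_p`, which rules
  out enter/remove cycling.

## Known limitations

* The angle route rests on annotation coordinates (rendered or
  digitised); automatic needle segmentation from real photographs is out
  of scope.
* The RM-ANOVA is the classical univariate decomposition for balanced
  designs only; unbalanced cohorts (after mortality) must be filtered or
  analysed per session, as the pipeline does.
* The hull-vertex reduction of the longest path above 1200 boundary
  corners can differ from exact enumeration when the constrained chord's
  endpoints fall on edge interiors; for the mask sizes of the oracle
  suite the exact path is always taken.
* Bonferroni across ~290 tests is conservative; with the exact
  Mann-Whitney null the smallest attainable two-sided p at n = 10 vs 10
  is ~1.1e-5, so detection at that design size needs near-perfect rank
  separation --- which is exactly the regime the stated world puts the
  onset-session signals in.
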