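---
title: "Quantifying nuclear envelope formation and growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear envelope formation and growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedyn)
```

The early *C. elegans* embryo rebuilds its nuclear envelope (NE) at every
division: ER-derived membranes wrap segregated chromatin, nuclear pore
complexes (NPCs) assemble into them, import of NLS-bearing cargo begins, and
the nucleus expands roughly thirty-fold in volume before the next mitosis.
nedyn implements the measurements this system calls for — import kinetics
from two-channel time-lapse stacks, FRAP turnover of nucleoporins at the
rim, volume morphometry of traced pronuclei, line-scan rim profiles, and
scoring of nascent-NPC membrane holes on tomogram traces — together with
synthetic-data generators that provide closed-form ground truth for every
stage. This vignette describes the models, the parameters that matter, and
the design choices where the procedures left room for judgement.

## Nuclear import

The import metric for a frame is

$$\mathrm{nc} = \frac{N - bg}{C - bg}\cdot A_{\mathrm{nuc}},$$

with $N$ the mean reporter intensity inside the segmented nucleus, $C$ the
mean in a cytoplasmic box, $bg$ the mean in a camera-background box placed
in a vacant part of the field, and $A_\mathrm{nuc}$ the nuclear area. The
subtraction removes the camera offset exactly and any uniform gain cancels
in the ratio, which the test suite asserts to machine precision. Two points
were open:

* **Area units.** Whether the area factor is in pixels or µm² is not
  essential to the ratio's shape, but physical units make values comparable
  across calibrations, so µm² is the default (`area_units = "pixel"` gives
  the pixel variant), and the bare ratio is always reported alongside.
* **Segmentation.** A manual chromatin trace is replaced by Otsu
  thresholding on the chromatin channel with removal of components below
  `min_area_px` (default 20) and selection of the largest remaining
  component. A user-supplied polygon via the point-list reader overrides
  the automatic trace. Isolated per-frame failures become missing values;
  failure on more than half the frames aborts the trace.

Onset of import is not defined by eye anywhere we could adopt, so
`detect_onset()` uses a standard change-point heuristic: the first time the
trace exceeds the baseline mean plus `k_sd` (default 3) baseline standard
deviations for `persistence` (default 2) consecutive frames, with the first
`baseline_n` (default 3) points as baseline. The rule is monotone in
`k_sd`, which the property tests exercise. `normalize_and_difference()`
min–max rescales each trace to [0, 1], averages across traces on their
common grid, and returns first differences of the average — a curve whose
peak shifts with delayed import onset.

## FRAP recovery

Bleached-region intensities are normalized to the mean of the prebleach
frames and time is re-zeroed at the first post-bleach frame. The recovery
model is the single exponential

$$f(t) = A\,(1 - e^{-\tau t}),$$

fit by bounded nonlinear least squares (Levenberg–Marquardt): $A$ is the
mobile fraction, $1 - A$ the immobile fraction, and $T_{1/2} = \ln 2 / \tau$
the half-time. Numerical choices:

* **Bounds.** $A \in [0, 1.5]$ rather than $[0, 1]$: clipping at a hard
  physical bound would bias estimates downward near full recovery; values
  above 1 are flagged instead.
* **Initialization.** $A_0$ from the tail of the curve, $\tau_0 =
  1/\mathrm{median}(t)$; if that start fails, a multistart over five decades
  of $\tau$ is attempted before declaring a fit error.
* **Bleach depth.** The printed model forces $f(0) = 0$ (full bleach), so
  no offset term is fit by default; `offset = TRUE` adds a free baseline
  $b$ for incomplete bleaching, and on generator curves with known depth it
  recovers $b$ and the attenuated amplitude $(1-d)A$.

Fits are validated two ways: noiseless generator curves must be recovered
to $10^{-6}$, and on noisy curves the fitted $(A, \tau)$ must agree with an
exhaustive 200×200 grid-search oracle to within one grid cell, with fitted
RSS no worse than the best grid point. Replicates are summarized by
per-curve fitting followed by arithmetic mean ± sample SD (the alternative,
fitting an averaged curve, is deliberately not used, so dispersion across
embryos stays visible).

## Volume morphometry and sphericity

Two independent volume estimators are implemented. From a single central
section, `measure_diameter()` thresholds, keeps the largest component, and
converts its area to an equivalent diameter $2\sqrt{A/\pi}$, from which
surface area $4\pi r^2$ and volume $\tfrac43\pi r^3$ follow exactly. From a
traced z-stack, `contour_volume()` integrates shoelace polygon areas times
the slice spacing (default 0.1625 µm, the isotropic light-sheet spacing) as
a plain Riemann sum with no end-cap correction — fidelity to the original
summation; the sphericity tolerance absorbs the discretization error.
`theoretical_volume()` converts the *widest* slice (largest area; "widest"
could also have meant largest linear extent, but the area reading is
consistent with the equivalent-diameter convention and more robust to
tracing noise) to an equivalent radius and a sphere volume. The relative
deviation between the two estimators is the sphericity statistic; traced
pronuclei are accepted as spherical when it is within 10%. On an ideal
radius-4 µm sphere traced as 256-gons at 0.1625 µm spacing the deviation is
about 0.02% — far inside the bound — while a 2:1 prolate ellipsoid fails it
at a deviation near 1.0, and the integrator is exactly cubic under
coordinate scaling. The slice grid of the contour generator is anchored at
the equator, so a radius-4 µm sphere yields 49 interior slices and no
tangent plane. Expansion rates come from an OLS fit of volume against time
over the growth phase.

## Line-scan rim profiles

`extract_profile()` samples every pixel along a line with the intensity at
each sample averaged over an odd `width_px` (default 3) of bilinearly
interpolated perpendicular offsets — the "three-pixel-wide line" of
standard practice, with a 1-pixel step chosen to preserve resolution. The
two printed recipes are kept as distinct presets rather than merged:
`"twocell"` averages the line with its 90° redraw and subtracts the mean of
the first and last two samples; `"if"` subtracts a camera-background value,
max-normalizes, and reports NE:cytoplasm and NE:nucleoplasm ratios as the
peak over the mean of the first/last five samples. The NE point for the
ratios is the profile maximum — the only feature the profile itself marks.
Ratios are computed on corrected, normalized values; correction can be
skipped via `camera_bg = 0`. The composition background-correct →
max-normalize is invariant to affine intensity maps $aI + b$ ($a > 0$),
which is what makes ratios comparable across staining intensities.

## Nascent-NPC holes on membrane traces

Tomogram membranes arrive as 2-D polyline chains per slice (the same
information visual scoring used; 3-D meshing is out of scope).
`detect_gaps()` pairs chain endpoints that are mutually nearest within
`pairing_max_nm` (default 300 nm) and not on the same chain — mutual
nearestness prevents pairing across unrelated membrane sheets — and leaves
unpaired endpoints (large ruptures, field edges) reported separately. A
candidate's width is the endpoint-to-endpoint distance; its flank lengths
are the arc lengths of the two chains.

`classify_hole()` applies three criteria, all of which must hold: the gap
is strictly narrower than 100 nm (the boundary value 100 is rejected, a
literal reading of "less than"); both edges taper; and continuous membrane
of at least `flank_min_nm` (default 100 nm, the same length scale as the
width criterion) flanks the gap on both sides. "Tapered to a point" refers
to inner/outer membrane fusion, which a single polyline cannot show, so the
package operationalizes it geometrically: the perpendicular spread of the
terminal $k = 5$ vertices about the flank's approach direction must not
exceed `taper_max_nm` (default 20 nm). An edge that narrows smoothly along
its line scores near zero; an edge that hooks away bluntly scores its hook
amplitude. The surrogate is monotone in the bend of the edge and the
generator uses a 50 nm hook for blunt edges, well separated from the
20 nm bound. Densities are accepted counts over region areas; because
"average density" is ambiguous between the mean of per-region densities and
the pooled count over pooled area, both are always reported (they coincide
for equal-area regions).

## Tabular assays

`lethality()` sums hatched and unhatched counts over scoring windows per
worm — the windows are exchangeable, only totals matter — and reports
per-worm lethality percentages and brood sizes with condition mean ± SD and
range; zero-brood worms are excluded with a warning rather than producing
0/0. `ddct()` averages technical replicates per sample and gene first (the
standard order), forms $\Delta C_t$ against the reference gene,
$\Delta\Delta C_t$ against the mean control $\Delta C_t$, and fold change
$2^{-\Delta\Delta C_t}$; a plate-wide additive shift of a sample's $C_t$
values cancels exactly. The reference gene is a required argument with no
default, because assay designs legitimately differ in their housekeeping
gene and a silent default would hide that choice. Fold changes are
summarized by arithmetic mean ± SD, with a geometric-mean option for
log-scale correctness.

## What the synthetic data does and does not emulate

The generators produce: a two-channel embryo (disk-shaped cytoplasm on a
camera offset, nucleus growing linearly in radius, nuclear reporter excess
following $C\,F\,(1-e^{-k_\mathrm{in}t})$ — the simplest saturating model
with a closed form; the analysis stages never assume it); FRAP curves from
the recovery model itself with configurable bleach depth; sphere contour
stacks with bounded radial jitter; and straight membrane fields with gaps
of requested widths, taper flags, and flank lengths. Noise is additive
Gaussian clipped at zero and intensities are integer camera counts.

Defaults mirror the study conditions: 20 s frame intervals with ~60-frame
time-lapses, 10 s FRAP intervals with 3 prebleach frames and full bleach,
0.1625 µm slice spacing, nuclei growing from 2 µm toward a ~8 µm diameter,
mobile fractions exercised at 0.20/0.47/0.59, and hole widths spanning
30–150 nm around the 100 nm criterion.

Not emulated: optical blur (no PSF), Poisson photon statistics,
photobleaching during acquisition, chromatin texture, nuclear movement,
out-of-focus drift, curved or branched membranes, and 3-D tomogram
geometry. Passing round-trip tests therefore shows the estimators are
correct on data satisfying their assumptions — unbiased segmentation
targets, single-exponential recovery, near-planar membranes — not that they
are robust to every artifact of real microscopy. The deliberately simple
structure is what makes exhaustive ground-truth agreement checkable.

## Problem sizes and determinism

Every generator is a pure function of its parameters including the seed.
The test suite runs at deliberately modest sizes — 60-frame 128×128
time-lapses, 60-point FRAP curves with up to 100 replicates per truth
value, 256-gon contour stacks, single-gap membrane fields over the
30–150 nm × taper × flank grid — chosen so that the full suite completes in
well under a minute while still leaving the estimators' error budgets
(e.g. median $|\hat A - A| < 0.05$ at noise SD 0.05) clearly visible.

## Known limitations

* Segmentation is global-threshold only; dim or textured chromatin on real
  data may need user-supplied polygons.
* The FRAP module fits a single exponential only — no reaction–diffusion or
  double-exponential models, no acquisition-bleaching correction.
* Contour volumes assume one object per stack and simple polygons;
  self-intersecting traces are rejected, not repaired.
* The taper criterion is a 2-D surrogate for a 3-D membrane feature; its
  20 nm bound is exposed as a parameter and should be recalibrated if
  traces come from a different reconstruction pipeline.
* No multiple-nucleus tracking, no mitotic-entry detection, and no
  amplification-efficiency correction in the qPCR module.
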