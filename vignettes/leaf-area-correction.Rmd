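---
title: "Correcting gas exchange measurements for smaller-than-gasket leaf area"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gas exchange measurements for smaller-than-gasket leaf area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgasket)
```

## The problem

Portable photosynthesis systems report gas exchange as rates per unit leaf
area, dividing the measured molar fluxes by the internal gasket aperture
area $A_G$ of the clamp-on chamber. That is only correct when the leaf fills
the aperture. A cereal blade narrower than the aperture diameter covers only
$A_L < A_G$, and every per-area rate — net photosynthesis $P_N$, stomatal
conductance $g_s$, transpiration $E$ — is then understated by the factor
$A_L / A_G$. At half coverage the error is already 100%. This package
estimates $A_L$ non-destructively by two routes and rescales the instrument
log accordingly.

## The width-based model

Assume the blade midrib passes through the centre of a circular aperture of
radius $r = \sqrt{A_G/\pi}$ and the two margins run, to a first
approximation, parallel at distance $y = W_L/2$ from the midrib, where $W_L$
is the caliper width at the chord through the aperture centre. The uncovered
region is then two equal circle segments. Each segment is the corresponding
circle sector minus an isosceles triangle:

$$\text{sector} = \pi r^2 \frac{\theta}{360^\circ}, \qquad
  \theta = 2\cos^{-1}(y/r)\frac{180^\circ}{\pi}, \qquad
  \text{triangle} = y\sqrt{r^2 - y^2},$$

so the enclosed area is

$$wA_L = A_G - 2\left[r^2 \cos^{-1}(y/r) - y\sqrt{r^2-y^2}\right].$$

`width_area()` exposes the whole construction (angle in degrees, sector,
triangle, segment, enclosed area) so each intermediate can be inspected;
internally all angles are radians and only the reported angle is converted,
avoiding repeated unit conversions. Numerical guards: the $\cos^{-1}$
argument is clamped to $[-1, 1]$ only when it is within $10^{-9}$ of that
interval (anything further out is a genuine input error), and a width at or
beyond the diameter $2r$ returns $A_G$ with `clipped = TRUE` plus a warning
— a leaf wider than the aperture is the ordinary full-coverage case, not an
error.

Assumptions worth stating plainly: the formula models a *centred* blade;
off-centre placement is not modelled and can only be caught by the imaging
route. Margins are assumed locally parallel; for tapering blades the
mid-chord width acts as an approximate median width, which is why the
formula stays accurate for gentle taper (see the synthetic study below).
Units are cm/cm² throughout the public interface; a single `units = "mm"`
option converts widths at the boundary, so there is exactly one place a
10× unit mistake could happen and it is explicit.

## The image-based pipeline

The manual procedure this automates traces the leaf by hand inside a
printed, to-scale impression of the aperture laid over the leaf on white
paper, after setting the scale from a printed 1 cm bar. The automated
pipeline makes each step deterministic:

1. **Scale calibration** (`calibrate_scale()`): the bar is the largest dark
   connected component with aspect ratio ≥ 5 that does not touch the image
   border (blades typically run off-frame; the bar never does). Its major
   extent in pixels over the known length gives px/cm. A region of interest
   or an explicit `px_per_cm` bypasses detection.
2. **Circle detection** (`locate_gasket_circle()`): a Hough-style vote. Edge
   pixels vote for centres via FFT ring correlation at each candidate
   radius. Two thresholding levels feed the edge map: everything darker than
   the background (leaf + ink), and the darkest class alone (printed ink),
   obtained by a second Otsu pass inside the dark class. The ink-only edges
   keep the impression circle detectable even when the blade covers the
   whole aperture. The peak must be supported by at least half the
   circumference, otherwise the function refuses and asks for a manual
   circle. The radius is refined to sub-pixel precision on the inner ink
   edge (lower half of the supporting edge distances, minus the half-pixel
   offset that boundary pixel centres carry).
3. **Segmentation** (`segment_leaf()`): Otsu's threshold computed only on
   pixels strictly inside the aperture, excluding a 2 px rim band so the
   printed outline cannot bias the histogram; below-threshold pixels are
   kept, closed with a 2 px disc brush, reduced to the largest connected
   component, and intersected with the aperture disc. A pixel belongs to the
   disc if its centre does; area is the pixel count over the squared scale.

When a gasket spec is attached (the default), the detected circle must imply
the declared aperture area within 2%, and the disc used for area accounting
is re-derived from the declared area at the detected centre: the printed
line sits just outside the true aperture, and the declared area is the more
trustworthy radius source. Degenerate contrast is resolved against the
physics of the scene rather than the histogram: if the Otsu classes inside
the aperture are separated by less than 0.15 (on the [0, 1] scale) the
aperture is essentially uniform — uniformly dark means full coverage (the
mask is the whole disc), uniformly bright means an empty aperture (area 0
with a warning); a bright aperture where the threshold still claims
near-total foreground is reported as an ambiguous-contrast error. RGB input
is reduced to luminance by default (`--channel green` exists because leaves
are green-dominant). The supported minimum resolution is 50 px/cm — below
that, pixel quantization alone approaches the 1% accuracy target. No
perspective correction is attempted; the leaf is assumed flat under the
impression.

## Correcting the instrument log

The correction is pure area rescaling: every per-area rate is multiplied by
$S/A_L$, where $S$ is the area the instrument assumed (its `Area` column,
normally $A_G$). This conserves molar flux exactly — corrected rate × $A_L$
equals original rate × $S$ — and is applied uniformly to $P_N$, $g_s$ and
$E$. Re-deriving $g_s$ from the raw water-vapour differentials with a
re-estimated boundary-layer conductance is *not* attempted: it would need
chamber-specific inputs the log does not carry, and simple rescaling is the
documented behaviour users should expect. That is a known limitation for
anyone needing a full biochemical recomputation. Intercellular CO₂ ($C_i$)
involves both fluxes, whose area terms cancel only approximately; it is
passed through unchanged and flagged (`ci_uncorrected` attribute) rather
than silently altered. $\Phi_{PSII}$ is a fluorescence ratio and is
area-independent; it passes through untouched. iWUE $= P_N/g_s$ is reported
before and after correction; the two are identical by construction, and the
test suite asserts the invariance to $10^{-12}$ relative.

Column names follow common instrument-export headers (`Photo`, `Cond`,
`Trmmol`, `Ci`, `Area`, `PhiPS2`) and are fully remappable, because log
dialects vary by firmware. The parser tolerates banner lines before the
header and both tab and comma delimiters. Batch correction never modifies
the source file and writes outputs atomically.

## Agreement statistics

`area_agreement()` compares the two estimators the way method-comparison
studies do: per-leaf signed divergence $100\,(wA_L - iA_L)/iA_L$ (the
reference is the imaging estimate; divergence is summarised by the maximum
of absolute values), a zero-intercept regression $Y = bX$ of $wA_L$ on
$iA_L$, and a paired *t*-test with a Shapiro–Wilk normality check on the
differences. For the through-origin fit two $R^2$ conventions exist; the
primary one reported here is referenced to the mean of $y$ (1 − RSS/TSS
about the mean), because for tightly clustered leaf areas the
origin-referenced variant is near 1 by construction and says little. Both
are available from `glance()`. A zero difference variance (identical
estimates) flags the *t*-test degenerate instead of erroring — perfect
agreement is a legitimate outcome of a comparison, not a failure.

## The synthetic ground-truth generator

Everything above is testable without any field data because the synthetic
module generates the full chain: parametric blade width profiles (constant,
linear, lanceolate — the last with quadratic margin curvature so margins are
neither straight nor parallel), a numerical oracle for the enclosed area,
rendered scenes, and internally consistent instrument logs.

The oracle integrates the blade–disc overlap with composite Simpson on
10⁴ panels after the substitution $s' = c + r\sin\phi$, which removes the
square-root endpoint singularity of the chord half-width; a half-resolution
pass provides a Richardson-style error estimate, bounded below
$10^{-5}$ cm² in the tests. For constant-width blades the oracle and the
closed-form width formula agree to integration tolerance across a width
grid — the central correctness property. An independent Monte-Carlo
point-in-region estimator (10⁷ samples per pair in the acceptance suite)
cross-checks the closed form within three standard errors on random
width/aperture pairs.

Rendered scenes emulate the photograph: white ground, dark lamina with an
optional 10%-darker midrib stripe (to stress segmentation), a 2 px printed
outline drawn *outward* from the true aperture radius (so the aperture
interior stays clean, mirroring an impression that marks the aperture
boundary), a 1 cm bar, and optional additive Gaussian noise, deterministic
per seed. Four blade archetypes (maize-, barley-, hard-wheat- and
soft-wheat-like; base widths 1.4/0.7/0.5/0.4 cm) are synthetic presets
chosen for a realistic width ordering — they are not calibrated species
measurements. The default agreement study draws 40 leaves (4 archetypes × 5
blade positions × 2 replicates, ~10% log-normal parameter jitter per leaf)
rendered at 100 px/cm; these sizes keep a full run of the study around a
minute on a single core while leaving pixel quantization well below the
effects being measured.

What the generator does **not** emulate — and therefore what passing tests
do not show about real photographs: uneven illumination and shadows, leaf
colour variation and translucency, perspective and lens distortion,
off-centre or skewed leaf placement, damaged or folded margins, and midrib
shadows darker than printed ink. The segmentation is deterministic and
validated, but on real imagery the manual-override paths (`px_per_cm`,
`circle`, `bar_roi`) exist precisely because detection heuristics can fail.

## Numerical and design choices, in brief

- Radians internally, degrees only in reported angles.
- Widths ≥ the aperture diameter clip to $A_G$ with a warning, not an error.
- arccos clamp tolerance $10^{-9}$; beyond it, invalid-width error.
- Segmentation is deterministic: identical bytes give identical masks.
- The correction refuses $A_L > S$ (a leaf cannot exceed the gasket) and
  $A_L \le 0$.
- All randomness flows through explicit seeds; the same seed reproduces a
  leaf, a scene, or a log byte-for-byte.
- One printed-number anchor is kept fixed: the circular fluorometer chamber
  preset `6400-40` with $A_G = 2$ cm²; a caption elsewhere giving
  20 mm² is treated as a typographical slip for 200 mm².

## Known limitations

Circular apertures only (no rectangular or elliptical gaskets); no
off-centre placement model in the width route; no CO₂/H₂O leak correction;
no $A$–$C_i$ curve support; rescaling-only $g_s$ correction as discussed
above. The width technique is built for linear-to-lanceolate blades; for
broad or lobed leaves use the imaging route.
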