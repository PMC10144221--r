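---
title: "Methods: rheology-based pressure planning and image-based printing accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rheology-based pressure planning and image-based printing accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printability)
```

# Scope

`printability` packages the quantitative backbone of a standardized
extrusion-bioprinting workflow: (i) planning the pneumatic pressure from
rheology so that two inks of different viscosity deposit the same
volumetric flow, (ii) measuring how faithfully printed single-layer
line, circle and angle structures match their CAD targets from
calibrated photographs, and (iii) quantifying cell viability from
flow-cytometry live/dead data. A synthetic-data generator renders all
three input kinds with known ground truth, so every analysis stage is
validated by recovery tests rather than by fixed example files.

# Rheology and pressure planning

Shear-thinning biomaterial inks (here alginate/GelMA formulations) are
described by the Ostwald–de Waele model
$\eta = K \dot\gamma^{\,n-1}$ with flow-behavior exponent $n$ and
consistency index $K$ (Pa·s$^n$). `fit_power_law()` fits by ordinary
least squares in log–log space, where the model is a straight line with
slope $n - 1$ and intercept $\log K$; this linearization is the
universal practice for power-law fits and makes the estimator
closed-form and deterministic. Real viscosity curves flatten into a
plateau at low shear, which is not part of the power-law regime; the
`fit_range` argument excludes it, and its default starts at 1 s$^{-1}$
because the plateau typically ends below that for these formulations.
The realized data range and the log–log $R^2$ are reported with the
fit.

Laminar flow of a power-law fluid through a cylindrical nozzle of
radius $R$ and length $l$ obeys the power-law Hagen–Poiseuille
relation

$$Q \;=\; \bar v \pi R^2 \;=\; \frac{n\pi}{3n+1}\,R^3
  \left(\frac{R\,p}{2 K l}\right)^{1/n},$$

which `flow_rate()` evaluates and `required_pressure()` inverts in
closed form,
$p = \tfrac{2Kl}{R}\left(\bar v (3n+1)/(nR)\right)^{n}$. A closed-form
inversion is used instead of root finding because the relation is
analytically invertible and the inverse is exact to machine precision;
the round trip `flow_rate(required_pressure(v))` $= \bar v \pi R^2$ is
a property test. At $n = 1$ both reduce to the classical
Hagen–Poiseuille formulas, which the tests verify to $10^{-12}$
relative as an independent oracle.

Units are a deliberate design point: the exponent $n+1$ on $R$ makes
the pressure formula exquisitely sensitive to unit slips, so the public
interface is uniformly mm / s / kPa / Pa·s$^n$ and all physics is
evaluated in SI inside one conversion layer.

With the published rounded parameters $n = 0.32$, $K = 284.09$ for the
stiffer ink and the 0.61 mm × 12.7 mm nozzle at
$\bar v = 10$ mm/s the planner returns 129.09 kPa. For the softer ink
($n = 0.35$, $K = 146.39$) it returns 76.8 kPa, whereas 80.5 kPa is the
operating point reported alongside those parameters; the rounded
two-decimal parameters cannot reproduce that value (the unrounded fit
presumably could), so the discrepancy is documented here and not
asserted anywhere.

# Image analysis

## Binarization

Photographs are monochrome, dark-background, ring-light illuminated, at
a known pixel pitch (52 px/mm by default). `binarize()` first replaces
each pixel by its 3×3 median to suppress shot noise, then applies a
local-mean threshold: a pixel is foreground iff its intensity exceeds
the mean over a `threshold_window` box plus `threshold_offset`. Local
(rather than global) thresholding makes the mask invariant to global
intensity shifts and robust to the uneven illumination that ring lights
produce; the window default (101 px) is about four times the expected
filament width in pixels, large enough that a filament never fills the
window yet small enough to track illumination drift. The offset rejects
background noise: with a symmetric-noise background, the local mean
sits at the background level and roughly half the background would
otherwise flicker above it, so for the renderer's contrast of ~180
intensity units an offset of 10–20 (a few noise standard deviations)
is appropriate; 0 is the right choice only for noise-free masks. Both
choices are exposed as parameters, because the threshold rule is the
one genuinely under-determined step of the published workflow.

Note one systematic effect: the local mean under a thin bright stroke
is pulled up in proportion to the stroke-width/window ratio, so the
threshold crossing shifts slightly along the blurred edge profile. With
a realistic optical blur (PSF $\sigma \approx 1$ px at 19 µm pixels)
this bias stays below ~1 px of width; a much softer focus would
amplify it. This is inherent to adaptive-mean thresholding, not to the
implementation.

## Segmentation and boundaries

Components are labeled 8-connected (so thin diagonal filaments stay
whole) and components below `min_area_mm2` (default 0.2 mm²) are
discarded as debris — small enough to keep real filament fragments,
large enough to drop specks. Boundaries are traced at the half-pixel
contour level (marching squares), giving sub-pixel closed polylines for
the outer boundary and each interior hole. At 52 px/mm the nozzle is
only ~32 px wide; integer-pixel boundaries would quantize widths by
~3%, while half-pixel contours keep radius and angle estimates well
inside the stated tolerances. Pixel centers sit at integer (row, col)
indices, x runs right, y runs down, and every physical output is in mm.

## Line metrics

The principal axis of the largest component defines the line direction.
Width is the mean foreground pixel count per one-pixel cross-section
perpendicular to the axis, averaged over the middle third of the
designed length (the ends are excluded because caps and start/stop
artifacts distort them); the normalized width is $w_n = w/d_{nozzle}$.
Length is the material-covered extent along the axis summed over the
components in the line corridor, minus the measured width per segment:
a deposited stroke with round caps overhangs its path by half a width
at each end, and subtracting $w$ removes exactly that overhang. An
ideal 30 mm print therefore scores $l_n = l/l_{model} = 1$, and an
interrupted line scores below 1 by precisely the missing material —
the sign convention that matches how shortfalls are reported.
`segment_count > 1` flags interruption.

## Circle metrics

The largest component is the printed annulus. Geometric
(orthogonal-distance) least-squares circles — algebraic (Kåsa)
initialization refined by Gauss–Newton — are fitted separately to the
interior-hole boundary ($r_i$) and the outer boundary ($r_o$);
geometric fitting is used because it remains unbiased on partial or
noisy arcs where the algebraic fit shrinks the radius. The normalized
radii to midline, $r_n = (r_i + r_o)/(2 r_{model})$, cancels the stroke
width: for any symmetric stroke on a perfectly placed circle $r_n = 1$
exactly, which is both a property test and the reason the metric is
robust to over/under-extrusion. The small start-marker circle
(3 mm design diameter) is located as the non-annulus component whose
bounding-box diameter best matches the design; its angular position
defines 0°, and the filament width is measured as the mean radial
outer-minus-inner boundary distance over 2% of the circumference
(7.2°) centered diametrically opposite the marker. Without a marker
the analysis falls back to 0° with a warning.

## Angle metrics

The angle composite is a stroked zigzag with designed vertex angles of
30°, 45° and 60°. No angle-measurement procedure is standard in the
printing literature, so the package defines one explicitly:

1. the outer boundary is simplified (Douglas–Peucker) to find corner
   candidates;
2. at each candidate, straight lines are fitted to the two boundary
   arms in an arc-length window 1–5 nozzle diameters from the apex —
   the lower bound excludes the rounded apex (printed corners and
   round joins are arcs, not points), the upper bound keeps the fit
   local; the apex is then refined to the arm-line intersection;
3. near-zero-angle candidates are rounded end caps and mark the path
   endpoints; remaining corners are paired across the stroke
   (inner/outer of one vertex), ordered by first boundary encounter
   from a cap — walking the contour traverses one stroke side in path
   order — and matched to the designed angles, trying both path
   directions;
4. at each vertex the reflex-turn member of the pair is the inner
   boundary angle $\alpha_i$ and the convex one the outer angle
   $\alpha_o$; the normalized angle is
   $\alpha_n = (\alpha_i + \alpha_o)/(2\alpha_{model})$.

The arm-window lower bound adapts to a distance-transform estimate of
the stroke width so that wide strokes' cap arcs never contaminate the
arm fits. Filament width is probed perpendicular to the centerline at
five points on the straight segments (segment midpoints first), each
probe measuring the contiguous foreground run at the centerline so a
probe near a sharp vertex cannot include the neighboring arm. A
documented limitation: flat-capped structures whose designed corners
are close to 90° can confuse the end-cap heuristic that separates
band ends from true vertices; the printed structures end in round caps,
where the limitation does not arise.

All pose information (line axis, circle center and marker, angle path
direction) is estimated from the data; no fiducials are assumed.
Normalized metrics are scale- and rotation-invariant by construction,
which the tests check at 52 vs 104 px/mm and under arbitrary rotation.

# Cytometry

Events carry forward/side scatter and green (calcein-AM) / red
(propidium iodide) fluorescence. A rectangular scatter gate excludes
debris (low scatter) and agglomerates (very high scatter); instrument
units are arbitrary, so the defaults are percentile-based and the
bounds are normally set between the visible clusters, exactly as a
rectangular FlowJo gate would be drawn. The red threshold is derived
from an all-dead control (fixated and permeabilized cells): the 1%
lower quantile of the control's red distribution, so ≥ 99% of
known-dead events classify as dead. In-gate events are dead if red
exceeds the threshold, live if green exceeds its threshold and red does
not, and unclassified (double-negative, i.e. not cells) otherwise.
Double-positive events count as dead because PI entry indicates a
compromised membrane; the choice is configurable. Viability is
live/(live + dead), with an exact binomial confidence interval; the
estimator is invariant to any monotone channel rescaling that preserves
threshold crossings. No spillover compensation is applied, as none is
reported for this dye pair.

# Statistics

Replicate metrics aggregate per formulation as mean ± sd with n, a
Jarque–Bera normality check at $\alpha = 0.05$
($JB = \tfrac{n}{6}(S^2 + (K-3)^2/4)$, asymptotically
$\chi^2_2$; implemented directly and verified against an external
statistical library on a frozen sample), and a one-way ANOVA across
formulations with significance at $p < 0.05$ plus unadjusted pairwise
comparisons. No multiple-testing correction is applied — each
comparison is reported at its own $\alpha$, and reports carry a footer
saying so. Uncertainties of the normalized metrics propagate by the
first-order (Taylor) method for independent inputs,
$\sigma_f = \sqrt{\sum_i (c_i\sigma_i)^2}$; because Eqs. for $w_n$,
$l_n$, $r_n$ and $\alpha_n$ are linear in their measured inputs, the
first-order result is exact for them (and is cross-checked against a
Monte-Carlo oracle in the tests). Inputs are treated as independent
because no covariances are reported for the measurement chain.

# The synthetic generator

`render_structure()` rasterizes the CAD path as a constant-width
stroke with round caps and joins using a signed-distance field with
area-coverage anti-aliasing — edge pixels take intermediate
intensities, as in real photographs, which is what makes sub-pixel
boundary tests meaningful. Defaults emulate the acquisition setup:
52 px/mm pitch, dark background (intensity 20) with bright material
(200), optical blur $\sigma = 0.02$ mm (about one pixel, a realistic
machine-vision PSF at 19 µm pixels), additive Gaussian sensor noise
$\sigma = 3$ intensity units, and a 10-unit linear illumination ramp
across the frame. Defects are explicit: gaps (material removed along
the path, with round caps at the new ends) and bulges (local
over-deposition discs). Renders are deterministic per seed and each
ships with a ground-truth sidecar (stroke width, material path length,
centerline radius, vertex angles, gap count, marker angle, achievable
normalized metrics); recovery tests always compare against the sidecar,
never against hard-coded numbers.

What the generator does *not* emulate — and hence what passing recovery
tests cannot show about real prints: die swell and spreading dynamics
(strokes are constant-width by construction), transparency of the ink
and specular highlights, perspective or lens distortion, and focus
variation across the field. The generator validates the measurement
chain, not the printing physics.

`simulate_viscosity()` produces log-spaced curves with multiplicative
lognormal noise (mean-one, given CV), matching how rheometer scatter
behaves across decades of shear rate. `simulate_cytometry()` draws
events from four lognormal clusters (live, dead, debris, agglomerates)
with documented default locations and spreads; the published workflow
gives no instrument calibrations, so the defaults are chosen to
reproduce the qualitative topology of calcein/PI scatter plots
(well-separated live/dead in fluorescence, debris low in scatter,
agglomerates high) and are fully overridable.

# Numerical choices and problem sizes

Tolerances used by the validation suite mirror the resolution budget:
widths to ±0.05 in normalized units (≈ 2 px at 52 px/mm), lengths to
±0.01, radii to ±0.005 (sub-pixel, achievable because the circle fit
averages thousands of boundary points), angles to ±0.03. The circle
fit runs 25 Gauss–Newton iterations or to a $10^{-12}$ relative step,
whichever comes first. Recovery sweeps use 20 rendered structures per
kind, 9 noisy replicate curves per ink for fit recovery, 5,000–10,000
events per cytometry sample, $10^5$ Monte-Carlo draws for the
propagation oracle and 1,000 repetitions for the type-I-error check —
sizes at which the binomial/standard-error bounds in the tests are
meaningful while the whole suite stays comfortably runnable on a
laptop.

Degenerate inputs fail loudly with specific errors: curves with
non-positive or non-increasing shear rates, fit windows holding fewer
than three points, empty masks ("no object detected"), annuli without
holes ("no ring detected"), vertex-count mismatches
("structure/CAD mismatch"), all-excluded gates, and zero classified
cells. Ties in the circle start-marker search resolve to the component
farthest from the annulus radius band.
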