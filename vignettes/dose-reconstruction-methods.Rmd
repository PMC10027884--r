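---
title: "Methods: linear-interpolation dose reconstruction from rotational array measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear-interpolation dose reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcdose)
```

# The problem

Patient-specific QA of VMAT deliveries often measures planar doses with a 2D
ion-chamber array rotating with (or inside a phantom under) the gantry, then
reconstructs a volumetric dose by linear interpolation and percent-depth-dose
(PDD) scaling, and finally compares DVH metrics with the planned dose. The
chamber lattice is sparse — 7 to 10 mm between centres against dose
structures (penumbrae, modulation) of comparable scale — so the interpolation
step is a real error source. `arcdose` provides a fully synthetic, seeded
implementation of this chain so that the error structure can be studied in
isolation: the ground truth is analytic, the measurement is exact sampling of
it, and every deviation downstream is attributable to the reconstruction.

# Geometry and conventions

All lengths are millimetres internally; PDD depths are quoted in cm at the
user interface. The world frame has the isocenter at the origin and the
phantom (cylinder) axis along z, which is also the gantry rotation axis. At
gantry angle $\theta = 0$ the detector plane is the x–z plane and the beam
travels along $-y$; positive angles rotate counter-clockwise seen from $+z$
(a `direction` flag gives the clockwise convention, since rotation sense is
a machine convention, not a physical one). Cylindrical coordinates use
$r=\sqrt{x^2+y^2}$ and the three-branch azimuth rule ($0$ at the axis,
$\arcsin(y/r)$ for $x\ge 0$, $\pi-\arcsin(y/r)$ for $x<0$), with outputs
reduced modulo $2\pi$ so coordinates are single-valued. Voxel lattices use
the voxel-centre convention; the default reconstruction lattice is
$109^3$ voxels at 2.5 mm — a 27 cm cube with a voxel centre exactly on the
isocenter, so chamber positions of the 10 mm and 7.07 mm arrays coincide
with lattice nodes.

The three built-in arrays are generated, not tabulated: a $27\times27$
square grid at 10 mm pitch (729 chambers, $27\times27$ cm$^2$), two
interleaved square grids ($27^2 + 26^2 = 1405$ chambers) whose
nearest-neighbour distance is the lattice diagonal $5\sqrt2 \approx 7.07$ mm,
and a $32\times32$ grid at 7.62 mm with the four corner chambers absent
($1020$, $24\times24$ cm$^2$). These are the unique centred layouts matching
the published counts, spacings and areas.

# The synthetic ground truth

Each control point contributes a parallel beam:
$$D_i(u, v, w) \;=\; W_i \, g(u)\, g(v)\, \frac{\mathrm{PDD}\!\left(F_i,\, d_\rho(u,w)\right)}{100},$$
where $(u, w)$ are beam's-eye-view coordinates (lateral, along-beam), $v$ the
axial coordinate, $W_i$ the control-point weight, $g$ a flat profile with
logistic penumbra (80–20% width 6 mm by default — a typical 6 MV penumbra;
no published profile model exists for the emulated systems, so the logistic
form is a package choice), and $d_\rho$ the radiological depth
$\int \rho\, dl$ from the phantom surface. The PDD family is
$(1-e^{-d/d_b})\,e^{-\mu(F) d}$ normalised to 100 at its maximum, with
$d_b = 0.35$ cm (depth of maximum $\approx$ 1.4 cm, 6 MV-like) and
$\mu(F) = 0.055 - 5\times10^{-4} F$ per cm, so that larger fields fall off
more slowly (scatter). That puts PDD(10 cm) for a $10\times10$ field at
66%, a realistic value. The field-size ordering of the curves is guaranteed
beyond the buildup maximum; in the buildup region normalisation can invert
it, which is why the monotonicity tests start at the maximum.

Beams are parallel, not divergent: divergence changes dose gradients only
geometrically and is orthogonal to the interpolation questions studied here,
while parallel beams keep the truth analytic. Radiological-depth scaling is
the **only** heterogeneity effect modelled — no lateral scatter perturbation
— which mirrors the depth-scaling character of phantom-based commercial
reconstruction and bounds what the heterogeneity experiment can show (see
below). For cylindrical phantoms with rod inserts the density is constant
along z, and the depth integral has a closed chord-length form, so the truth
is exact to machine precision; spherical inserts use a numeric per-slice ray
integral instead (transverse rays never cross slices).

Plans distribute a 2 Gy prescription over evenly spaced control points with
seeded uniform weight modulation (0.5–1.5) and seeded per-point square field
sizes. Doses are normalised so the PTV D95 equals the prescription, the
clinical acceptability convention.

# Measurement

`measure_plan()` evaluates the analytic beam model exactly at the rotated
chamber centres — an ideal point detector. `sample_planar()` offers the
grid-sampling route (trilinear lookup in a stored dose grid, or a chamber
box average on a $3^3$ Gauss–Legendre quadrature); both routes agree on
smooth fields and the exact route is used by the experiments so that all
downstream error is attributable to the reconstruction, not to sampling a
voxelised truth. Volume averaging is off by default: whether commercial
systems deconvolve it is not public, so both modes are exposed.

The dose-rate surrogate is a per-control-point machine rate (delivered
weight over delivery time at constant gantry speed). Readings of control
points below a rate threshold (5 cGy/min in the dropout experiment) become
explicit no-response markers (`NA`), never silent zeros.

# Reconstruction

The planar interpolant of a measurement is piecewise bilinear on the chamber
lattice: two-point linear interpolation along rows, then across — the order
is immaterial, and the value equals the area-weighted mean of the four
surrounding chambers. Checkerboard lattices are first completed at the
unmeasured parity class from the four diagonal neighbours (two in-line
neighbours on edges), missing corners by parallelogram completion; all fills
are exact for affine fields, preserving the interpolant's affine-exactness
and node-exactness (interpolation error at nodes is identically zero).
Beyond the outermost chambers values clamp to the nearest node: linear
extrapolation would fabricate gradients where nothing was measured.
Dropped-out readings are either bridged by widening the interpolation
interval (`"interpolate"`, the default) or zero-filled (`"zero"`, the
pathological behaviour the dropout experiment quantifies); a fully
dropped-out plane is rebuilt chamber-wise by linear interpolation in gantry
angle between the nearest responsive control points, wrapping across the
closure of a full arc.

Depth extension multiplies each densified plane by
$\mathrm{PDD}(d(u,w))/\mathrm{PDD}(d(u,0))$ along its rays, where $d$ is the
water-equivalent depth of the homogeneous cylinder (entry at
$\sqrt{R^2-u^2}$) — deliberately ignorant of any inserts, as a phantom-based
method must be. PDD curves at non-tabulated field sizes are linear mixes of
the bracketing tabulated curves. Rays grazing the rim (reference depth
< 3 mm) contribute zero rather than dividing by a vanishing PDD.

`reconstruct_volume()` accumulates per-beam lattices onto the world grid by
trilinear pull and summation (dose is additive). Because the axial lattice
coincides with the target z axis, the pull is bilinear in $(u, w)$ with
exact z alignment; the implementation fuses plane value and depth ratio into
one gather pass, and a test asserts bit-level equivalence with the explicit
densify → depth-extend → trilinear-pull composition. On the rotation axis
all beam lattices coincide and the summed contributions average naturally.

# DVH metrics and statistics

$D_p$ is the dose exceeded by exactly $p\%$ of the volume; from raw voxels
that is the $\lceil np/100\rceil$-th largest voxel dose (ties toward the
higher dose), from a curve the linear inverse of the cumulative histogram.
The two agree within one dose bin (default 0.01 Gy); pipelines use the voxel
route, and Dmax always comes from raw voxels. $V_d$ defaults to the
*at-least* convention — the only clinically meaningful reading for
lung-V5-style metrics — with *at-most* computable for completeness.

Deviations are absolute percent differences
(`pdd_percent()` / `vd_percent()`), scale-invariant by construction.
Aggregates report mean, SD and a 95% CI; the default CI is a seeded
percentile bootstrap of the mean ($10^4$ resamples) because clinical
deviation samples are skewed and published intervals of this kind are
asymmetric; a t-interval and the raw 2.5–97.5 sample percentiles are also
returned, labelled. `compare_paired()` runs Shapiro–Wilk on each sample at
the 5% level (on each sample, not the differences — matching the practice
emulated), then a paired t-test if both pass, otherwise the Wilcoxon
signed-rank test. No multiple-testing correction is applied; experiments
report raw p-values.

# The experiments and their study conditions

All statistical scenarios share one frozen condition set: **20 plans**,
**24 control points** per arc, **220° partial arcs** with seeded random
start, per-point fields drawn U(4, 12) cm, 2.5 mm/$109^3$ grids. The choices
matter and are worth stating:

* *Partial arcs.* Clinical VMAT QA cohorts are dominated by double/partial
  arcs. They also avoid a degeneracy of idealised full arcs: with a
  near-exponential PDD tail, the depth-model error of two exactly opposed
  beams is antisymmetric about the measurement plane and cancels pairwise,
  hiding the heterogeneity effect that partial arcs expose.
* *Field sizes 4–12 cm.* VMAT control points deliver sub-fields that only
  partially cover the target, so field edges sweep through the PTV and the
  in-plane interpolation error is actually exercised there; the range also
  stays inside the mandatory 4–26 cm PDD table.
* *Problem sizes.* 24 control points and 20 plans keep a full scenario in
  tens of seconds while leaving the paired tests with overwhelming margins
  (p < 1e-6 typically); the per-control-point interpolation structure, not
  the control-point count, drives the error.

One master seed expands into per-plan seeds and arc starts; arms share the
plan ensemble exactly, making the comparisons paired by construction.

The **spacing** scenario compares the 10 mm square and 7.07 mm checkerboard
arrays on the PTV mean dose: the finer lattice roughly halves the mean
deviation. The **heterogeneity** scenario places a lesion-type PTV (20 mm
sphere) inside a 35 mm lung-like rod (density drawn U(0.01, 0.26) g/cm³ per
plan). The placement is deliberate: because the reconstruction anchors each
ray at its measured isocenter-plane value, an insert far from an ROI shifts
radiological depth by a constant that largely cancels in the PDD ratio, and
the reconstruction error concentrates *in and around* the low-density
region — the regime the scenario probes, and the reason lung-adjacent
structures are the hard case for depth-scaling reconstructions. The
**small_volume** scenario compares Dmax deviations of a 0.2 cm³ lens-scale
sphere placed 50 mm off-axis — inside the penumbra sweep of the 4–12 cm
fields, as ocular structures sit near field edges — against a 50 cm³
organ-scale sphere: the tiny structure spans at most one chamber gap, so its
Dmax is systematically less trustworthy. The **nyquist** scenario feeds the
10 mm array a cosine modulation of period 15 mm (sub-Nyquist: 20 mm is the
limit) versus 40 mm. The recovered peak amplitude is defined as half the
difference between the densified map's mean at the modulation's true crest
positions and at its true troughs — the amplitude the reconstruction
attributes to the known modulation where it peaks. Under this estimator the
sub-Nyquist arm loses ~79% of the amplitude while the super-Nyquist arm
recovers it exactly (the sampling lattice contains the crests). A spectral
(least-squares sinusoid) estimator would instead report the piecewise-linear
transfer loss $\mathrm{sinc}^2(h/\lambda)\approx 19\%$ even super-Nyquist —
a property of every linear interpolator, not of the sampling density, which
is why the peak-based estimator is the informative one here. The
**dropout** scenario lengthens the delivery time of 3 control points so
their machine rate falls below 5 cGy/min at full monitor units (a gantry
slowdown): zero-filling those planes discards ~12% of the delivered dose,
while angular re-interpolation recovers it to within ~2%.

# Numerical choices and degenerate inputs

Queries numerically at a lattice node are snapped (tolerance $10^{-9}$ of a
cell) so node exactness is not eroded by floating-point index drift.
Degenerate interpolation intervals, empty ROI masks, all-no-response planes,
zero-span arcs, non-positive reference doses, and out-of-table depths or
field sizes all raise errors naming the offending object — never silent
fallbacks. Reconstruction errors are tagged with the control-point index.
The binary grid format (flat little-endian float64 plus JSON header) is
bit-exact on round trip.

# What the synthetic study does and does not show

The generator reproduces the *geometric and sampling* structure of
rotational array QA: sparse planar sampling, arc superposition, penumbral
gradients, depth scaling, density inserts, low-rate dropout. It does not
model MLC aperture shapes, output factors, detector energy/angular response,
beam divergence, lateral scatter in heterogeneity, or fluence-correction
schemes of model-based commercial systems. Consequently the experiments
establish *orderings and mechanisms* — finer spacing better, heterogeneity
worse, sub-Nyquist unrecoverable, small volumes unreliable, zero-filling
pathological — at deviation magnitudes of order 0.5–3%, smaller than
clinical cohorts show (several percent), since real deliveries add all the
unmodelled effects on top. Passing tests therefore validate the
reconstruction machinery and the direction and mechanism of each effect,
not clinical deviation magnitudes.
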