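---
title: "Reconstructing cranial surfaces from CT slice contours"
author: "cranioball"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cranial surfaces from CT slice contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioball)
```

## The problem

Cranial vault fractures leave a defect whose implant geometry must be
designed from the patient's own CT scan.  A CT study is a stack of parallel
2D slices; on each slice the bone boundary is a closed curve interrupted by
the fracture gap.  `cranioball` reconstructs the missing surface in three
steps:

1. **Per slice**: extract the bone boundary by mathematical morphology,
   split it at corner points, and fit each piece with a rational cubic Ball
   curve; consecutive pieces are joined with GC1 geometric continuity and
   the free shape parameters are optimized by a genetic algorithm.  Where a
   broken ring is detected, the gap is bridged by a curve continuing the
   fitted boundary smoothly across it.
2. **Stacking**: lift the fitted 2D contours to 3D at equidistant heights
   $z^i = z_1 + (i-1)\Delta z$.
3. **Lofting**: blend consecutive contours into a surface with a cubic Ball
   interpolant whose cross-slice tangent field follows the contour geometry,
   and triangulate the result to STL/OBJ.

## The curve model

The cubic Ball basis is
$$S_0 = (1-\theta)^2,\; S_1 = 2\theta(1-\theta)^2,\;
  S_2 = 2\theta^2(1-\theta),\; S_3 = \theta^2, \qquad \theta \in [0,1].$$
It is non-negative, sums to one, and is symmetric
($S_i(\theta) = S_{3-i}(1-\theta)$), so Ball curves interpolate their end
controls, stay in the convex hull of the controls, and satisfy the
variation-diminishing property.  When the two inner controls coincide the
cubic collapses to a quadratic — a convenience the Bernstein basis does not
share.

A boundary piece is modelled as the rational segment
$$s(\theta) = \frac{A(1-\theta)^2 + B(1-\theta)^2\theta
  + C(1-\theta)\theta^2 + D\theta^2}
  {(1-\theta)^2 + a(1-\theta)^2\theta + b(1-\theta)\theta^2 + \theta^2}.$$
$A$ and $D$ are the on-curve endpoints.  $B$ and $C$ are *weighted*
numerator coefficients — the geometric off-curve control pulled toward by
weight $a$ is $B/a$ (and $C/b$ for $b$).  Raising $a$ bends the curve
toward $B/a$; raising $b$ toward $C/b$.  We restrict $a, b > 0$, which
keeps the denominator positive on $[0,1]$.  (Whether negative weights with
a still-positive denominator would be useful is untested; positivity is
also what makes the GC1 joins direction-preserving.)

Pieces are chained through the shared knots $f_i$.  Requiring position
continuity and $s_{i+1}'(0) = \lambda_i s_i'(1)$ with $\lambda_i > 0$
forces
$$B_{i+1} = (a_{i+1} + \lambda_i b_i)\, f_{i+1} - \lambda_i C_i,$$
using the endpoint derivative closed forms $s'(0) = B - aA$ and
$s'(1) = bD - C$.  So within a chain, only the first segment's $B$ is free;
every later $B$ is determined by $(a_{i+1}, \lambda_i)$ and the previous
segment.  Each interior join contributes the three free parameters
$a_i, b_i, \lambda_i$ that the optimizer tunes.

On closed boundaries the chain runs corner-to-corner around the loop and is
**not** closed with a GC1 constraint back at the start knot: the first
segment's $B$ stays free, so the start knot is a potential (usually
invisible) tangent break.  This is a documented limitation.

## Fitting

Data points of one segment are parametrized by chord length
($\theta_k$ proportional to cumulative polyline distance, scaled to
$[0,1]$), and the cost is the normalized mean squares error
$$E^2 = \frac{\sum_k |s(\theta_k) - D_k|^2}{\sum_k |D_k|^2}.$$
The denominator is the raw, uncentred sum of squared data norms, so $E^2$
depends on the coordinate origin; with pixel coordinates the reference is
the image origin.  This is a property of the cost as defined, not a bug,
and the test suite pins it down as such.  No closest-point reprojection is
performed: the curve is compared to each datum at the datum's own
chord-length parameter.

Given weights $(a, b)$, the free coefficients are estimated by the classic
rational-fit linearization: minimize
$\sum_k |P(\theta_k) - D_k Q(\theta_k)|^2$, which is linear in $B$ and $C$
and solves by QR in closed form.  The solution is exact whenever the data
lie on a representable curve at those parameters.  This makes each
candidate evaluation inside the GA a deterministic linear solve.

The remaining parameters are optimized by a real-coded genetic algorithm:

| setting | default | why |
|---|---|---|
| population | 50 | standard for 2–3 genes |
| generations | 200 (fit), 60 (pipeline) | see below |
| selection | tournament, size 3 | standard; stable tie-break by index |
| crossover | BLX-0.5, p = 0.9 | standard real-coded choice |
| mutation | Gaussian, $\sigma$ = 10% of range, p = 0.2/gene | keeps diversity |
| elitism | 1 | makes best fitness non-increasing |
| bounds | $a, b, \lambda \in (0.05, 10]$ | positive denominator, bounded pull |
| stopping | $E^2 \le$ target | classic criterion: $10^{-2}$ |

One individual of the initial population is seeded at the neutral
parameters $a = b = \lambda = 1$, so the first generation already contains
the plain least-squares fit.  The whole run is driven by one integer seed
and restores the caller's RNG state.

Two tolerances appear deliberately.  The *convergence criterion* reported
per slice is the classic $E^2 \le 10^{-2}$.  The *pipeline's fitting
target* defaults to $10^{-6}$ (or 60 generations): on a 50-pixel-radius
quarter arc, stopping at $10^{-2}$ can leave a ~2-pixel bulge, while the
tighter target reaches ~0.1 px in about a second per slice — necessary for
the sub-pixel surface budgets below.

Segments are optimized left to right: segment $i{+}1$'s genes are
$(a_{i+1}, b_{i+1}, \lambda_i)$, with $B_{i+1}$ dictated by the join to the
already-fitted segment $i$.  Whether the original formulation optimized
jointly or per segment is not determinable; per-segment is faster and
deterministic, but greedy: the first segment can reach an extreme-weight
optimum that slightly handicaps its successor.  In shape-recovery tests
most random chains refit to within 1% of the bounding-box diagonal, with
occasional chains at a few percent — the regression suite asserts exactly
that aggregate behaviour rather than pretending uniformity.

`fit_boundary()` never inserts knots on its own.  Long smooth runs between
corners should be cut with `segment_breaks()` (the pipeline does this
automatically, default one break per 90 chain points): a single rational
cubic cannot follow a 300-degree arc.

## Boundary extraction and corners

The object boundary is $\beta(A) = A - (A \ominus B)$ with $B$ the full
3×3 box (a cross is available by flag); pixels beyond the image border
count as background, so objects touching the border keep their border
pixels in $\beta(A)$.  CT bone is bright, so $A$ is the above-threshold
set (Otsu's criterion when no threshold is given); a polarity flag covers
inverted sources.

Two practical consequences of this definition are worth knowing.  On
rectilinear shapes $\beta(A)$ is a one-pixel chain and `trace_contours()`
returns it exactly and completely.  On curved shapes the band is two
pixels thick along diagonal runs; tracing follows the border of the band
(Moore border following with a repeated-state stopping rule), returning an
ordered chain that omits the enclosed duplicates.  Components that cannot
be border-followed at all raise a tracing error naming the component.
Chains are reported counterclockwise in standard orientation, outer
(largest-area) contour first.

Corners use the $k$-cosine measure: at point $p_i$, the cosine of the
angle between $p_{i-k} - p_i$ and $p_{i+k} - p_i$ ($-1$ on straight runs,
$0$ at right angles), thresholded and non-maximum-suppressed along the
chain.  The default threshold is $-0.6$ rather than the superficially
natural $-0.5$: a regular hexagon's 120° vertices sit *exactly* at
$-0.5$, and digitization noise then drops some of them, while at $-0.6$
all $n$-gon vertices for $n \le 6$ are found and smooth arcs
(cosine $\approx -1 + k^2/2r^2$) remain corner-free.  Free endpoints of
open chains are always reported as breaks — on a fractured slice they are
the gap anchors.

A broken annulus traces as a *single* closed loop (outer edge, across the
fracture face, inner edge, back).  The pipeline recognizes this topology
(one closed chain, exactly four corners), splits the loop at the corners
into the two thickness "caps" and the outer/inner open arcs, and takes the
arc endpoints as the recovered gap endpoints; on phantoms they land within
the 1.5-pixel rasterization budget of the analytic truth.

## Bridging the gap

The missing-part curve interpolates the two gap endpoints with tangent
directions taken from the endpoint derivatives of the fitted boundary on
either side, so the repair continues the skull outline GC1-smoothly.  The
bridge is the cubic Hermite interpolant written in Ball form (weights
$a = b = 2$ make the rational denominator identically 1, and
$B = 2A + T_0$, $C = 2D - T_1$).  Tangent magnitudes use a circle-aware
scaling: with $\gamma$ the turning angle between the end tangents,
$|T| = \mathrm{chord} \cdot 4\tan(\gamma/4)/(2\sin(\gamma/2))$, which is
the optimal cubic rendering of a circular arc and tends to plain chord
length as $\gamma \to 0$.  A 90° circular gap is then bridged with
~$3\cdot10^{-4}$ relative radial error.

## Contour blending

With aligned samples $C^i(\psi_j)$ at heights $z^i$, interior contours get
the tangent field
$$v^i(\psi) = \frac{|D_1|\,D_2 + |D_2|\,D_1}
 {|D_1|\,(z^i - z^{i-1}) + |D_2|\,(z^{i+1} - z^i)},
 \qquad D_1 = C^{i+1} - C^i,\; D_2 = C^i - C^{i-1},$$
so $(v^i, 1)$ is tangent to the surface at $(C^i, z^i)$.  The two
degenerate rules fall out exactly: if all three corresponding points
coincide the field is $(0,0)$ by convention (the formula is 0/0 there),
and if $D_1 = \lambda v^*$, $D_2 = \mu v^*$ with $\lambda\mu < 0$ the
numerator cancels identically.  When $\lambda\mu > 0$ the formula reduces
to the comonotone closed form
$v^i = 2\lambda\mu\,/\,(\lambda(z^i - z^{i-1}) + \mu(z^{i+1} - z^i))\,v^*$,
which the tests verify to $10^{-12}$.  First and last contours, which have
a single neighbour, use the one-sided slopes
$v^1 = (C^2 - C^1)/(z^2 - z^1)$ (symmetrically at $i = n$).

Between contours $i$ and $i+1$ the surface band is a cubic Ball blend in
$\theta$ with height $(1-\theta)z^i + \theta z^{i+1}$.  Two readings of
the blend coefficients exist, and the package carries both:

* **hermite** (default): coefficients $C^i$,
  $C^i + \tfrac{\Delta z}{2} v^i$, $C^{i+1} - \tfrac{\Delta z}{2} v^{i+1}$,
  $C^{i+1}$ — the unique cubic Ball form whose $\theta$-derivative at the
  contours equals $\Delta z\,v$, i.e. exactly the stated tangency
  requirement.  It reproduces a stack of identical contours as a perfect
  cylinder and a linear radius profile as a perfect cone (both asserted to
  $10^{-9}$ and $10^{-3}r$ respectively in the suite).
* **literal**: coefficients $C^i$, $\Delta z\,v^i$, $v^{i+1}$, $C^{i+1}$ —
  the inner coefficients carry no position part.  Taken at face value this
  shrinks a cylinder's interior rows by $(1-\theta)^2 + \theta^2$ and
  violates the tangency requirement it accompanies; it is retained behind
  `mode = "literal"` for comparison experiments only.

Because the source formulation is ambiguous about what the $\Delta z$
factor multiplies and whether position terms were dropped, the
tangent-consistent hermite reading is the default.

Sample correspondence across contours (the meaning of a shared $\psi$) is
not prescribed anywhere; the package resamples each contour at $m$ uniform
arc-length fractions and, for closed contours, aligns starts by the cyclic
shift minimizing the squared distance to the previous contour (exhaustive
over all $m$ shifts).  Open fracture arcs align endpoint-to-endpoint.

Meshing splits every grid quad into two triangles, wrapping in $\psi$ for
closed contours; orientation follows the $(\psi, \theta)$ parametrization
so counterclockwise contours with increasing $z$ give outward normals;
zero-area triangles are dropped (with a message), never emitted.

## The phantom generator

Validation uses annular "skull-like" phantoms with fully analytic truth:
outer radius $\rho_i(\psi) = r_{out}(i)\,(1 + a\cos(2\pi h\psi))$, inner
boundary offset inward by a constant thickness, optional angular fracture
interval $[\alpha_1, \alpha_2)$ removed on chosen slices.  Rasterization
is binary-exact (a pixel is foreground iff its centre is inside the
analytic annulus), so recovered contours can be held to a 1.5-pixel
Hausdorff budget against truth, and a reconstructed surface to pixel-scale
radial budgets via `end_to_end_truth_error()`.  Defaults are desk-scale:
0.5 mm pixels, 1 mm slice spacing, 256×256 images.

Phantoms are smooth except at the fracture endpoints by design — corner
detection should find *only* the four gap corners, which is precisely what
the segment-splitting logic needs.  What phantoms do **not** emulate:
CT noise, beam hardening, partial-volume effects, anatomy that deviates
from a perturbed annulus, or non-parallel slice geometries.  Green tests
therefore demonstrate correctness of the geometry pipeline, not clinical
performance on real scans.

Test and example problem sizes are chosen desk-scale on purpose: phantoms
of 3–5 slices at 128–192 px, contours resampled at ~100 samples, blending
grids of 9 $\theta$ rows.  They exercise every code path; production runs
simply scale the same parameters up.

## Numerical conventions

* Parameters outside $[0,1]$ raise errors and are never clamped — silent
  clamping hides parametrization bugs.
* Weight and $\lambda$ bounds default to $(0.05, 10]$.
* GA fitness ties break toward the earlier individual; every stochastic
  step derives from the single configured seed, and runs restore the
  caller's RNG state.
* Geometry is serialized in mm when the pixel spacing is known, else in
  pixels; every JSON artifact records its units.
* Degenerate inputs fail loudly: coincident consecutive data points,
  all-origin NMSE denominators, under-determined least squares (two-point
  segments), constant images without a threshold, empty foregrounds.

## Known limitations

* No GC1 closure at the start knot of closed boundaries (see above).
* Per-segment sequential optimization is greedy (see above).
* Boundary chains on curved shapes omit duplicate pixels of two-pixel
  thick diagonal bands.
* The fracture detector targets broken-ring topologies (one closed chain,
  four gap corners); exotic multi-fragment fractures need manually
  supplied gap endpoints via the contours input path.
* DICOM is not read directly; convert series to numbered PNG/TIFF or
  pre-extracted contour CSV/JSON first.
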