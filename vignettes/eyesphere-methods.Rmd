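---
title: "EyeSphere: model, coordinate systems, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EyeSphere: model, coordinate systems, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EyeSphere)
```

## The geometric model

EyeSphere treats the eye as an ellipsoid with semi-axes $(r_x, r_y, r_z)$
and a circular rim opening. Two conventions describe the opening and are
kept rigorously separate:

* the user-facing **rim-opening angle** (degrees from the optical axis;
  default 53°, typical of an early-postnatal mouse eye), and
* the internal **rim colatitude** $\phi_0 = 180° - \text{opening}$,
  measured from the deepest point of the retinal cup, so a 53° opening
  places the rim at $\phi_0 = 127°$.

The conversion happens exactly once, in `rimColatitude()`. In the eye frame
the deepest point is $(0, 0, -1)$ (unit coordinates) and the opening faces
$+z$; the retina is the surface portion with $z \le -\cos\phi_0$.

Each camera is an orthographic view, related to the eye frame by the rigid
transform $T(a) = R\,a + t$ with $R = R_x(\vartheta_x) R_y(\vartheta_y)
R_z(\vartheta_z)$ (that product order is part of the contract; angles are
degrees at every API boundary and radians internally). The camera looks
along $-z$, so its $x, y$ axes are the image axes and larger camera-$z$ is
nearer the viewer. Image pixels use the usual raster convention (origin
top-left, $y$ down); the pixel-to-camera conversion flips $y$ so the eye
frame stays right-handed, and is confined to `markToCamera()` /
`cameraToPixel()`.

## Localization

A mark $(x, y)$ in one view constrains the injection to the segment between
camera points $(x, y, +r_\max)$ and $(x, y, -r_\max)$, where $r_\max$ is the
largest semi-axis: under orthographic projection depth is unobservable, and
the segment is guaranteed to span the whole eye provided the view transform
carries no $z$-translation (the session schema documents $t_z = 0$). The
two marks give two eye-frame lines; the injection estimate is the midpoint
of their mutual-perpendicular segment, and the segment's length (`rayGap`)
is reported as a residual. This formalizes the interactive workflow in
which the second mark is placed *on* the line projected into the side view:
when the mark lies exactly on that line the gap is zero and the midpoint is
the intersection. Rays closer than 5° to parallel are rejected — a second
view along almost the same axis adds no depth information, and the midpoint
becomes numerically meaningless.

The triangulated point generally sits slightly off the surface; since
injections live on the retina it is snapped by radial rescaling in
semi-axis-normalized coordinates (divide by $(r_x, r_y, r_z)$, renormalize
to unit length). Whether the original interactive tool snapped or reported
the clicked depth is unknown; snapping was chosen because every downstream
coordinate (wedge, polar) is defined on the surface, and the pre-snap point
is still returned in `pointEye`. Points that snap above the rim are
reported (with a warning and flag) at the nearest rim point along their
meridian rather than erroring: a user with a slightly misaligned wire-frame
still gets a usable, flagged answer.

## The wedge coordinate system

For one retinal axis (say nasotemporal), place its two poles on the rim at
$(\pm\sin\phi_0, 0, -\cos\phi_0)$. A plane through both poles tilted $\psi$
from the vertical cuts the unit sphere in a circle of radius
$\rho = \sqrt{\sin^2\phi_0 + \cos^2\phi_0\cos^2\psi}$ centred at
$(0, y_0, z_0)$, $y_0 = -\sin\psi\cos\psi\cos\phi_0$,
$z_0 = -\sin^2\psi\cos\phi_0$. With the angular parameter
$\alpha_0 = \arcsin(\sin\phi_0 / \rho)$ at the first pole, the sub-rim arc
spans $2\pi - 2\alpha_0 < 2\pi$, and a point is addressed by the fraction
$f \in [0, 1]$ along that arc. The forward map is

$$x = \rho\sin a,\quad y = y_0 - \rho\sin\psi\cos a,\quad
  z = z_0 + \rho\cos\psi\cos a,\quad a = \alpha_0 + f(2\pi - 2\alpha_0),$$

and the inverse recovers $\psi = \mathrm{atan2}(y,\, -\cos\phi_0 - z)$,
then $\alpha = \mathrm{atan2}(x, v)$ with
$v = -(y - y_0)\sin\psi + (z - z_0)\cos\psi$, wrapping $\alpha$ by $+2\pi$
whenever $\alpha < \alpha_0$, and $f = (\alpha - \alpha_0)/(2\pi -
2\alpha_0)$. The `atan2` here is the standard two-argument arctangent with
range $(-\pi, \pi]$.

This formulation was cross-checked against an independent construction —
intersect the tilted plane with the sphere numerically, locate both poles
on the resulting circle, and walk the stated fraction of the arc through
the deepest point — and agrees to machine precision; the package's test
suite keeps that oracle. Degeneracies are explicit: on the pole axis the
tilt is undefined and $f$ is 0 or 1 by the sign of $x$; at the deepest
point every arc passes through the point and $(\psi, f)$ is reported as
$(0, 1/2)$; both carry a `degenerate` flag.

The dorsoventral axis is the same construction rotated a quarter turn about
the optical axis (the point is rotated by $-90°$ about $z$ and inverted on
the same grid). For a right eye the DV fraction is mirrored,
$f \mapsto 1 - f$, which is how left/right handedness switches the
dorsoventral axis. The placement of the nasal pole at $+x$ is a pure
internal convention: anatomical orientation is carried entirely by the view
transforms the user aligns.

Wedge coordinates are computed on the unit sphere after semi-axis
normalization. For a true ellipsoid a "tilted plane section" is not a
circle, and no canonical ellipsoidal generalization exists; normalizing
first keeps the coordinates well-defined and reduces to the exact
construction for spherical eyes (mouse eyes are within a few percent of
spherical).

## Area estimation

The injection's extent is estimated from a single view in four steps:

1. **Chroma distance** (`colorDistanceMap`): the RGB image is converted to
   CIELAB (sRGB primaries, D65 white point — the source colour profile of
   the original tool is unstated, so the common default is used) and the
   per-pixel Euclidean distance to the seed pixel is computed in the
   $(a^*, b^*)$ plane only. Discarding lightness makes the measure robust
   to shading across the curved eye.
2. **Threshold** (`thresholdMask`): pixels with distance $\le 5$ (default)
   are kept, restricted to the connected component containing the seed.
   The restriction is a deliberate choice the original leaves open:
   without it, disjoint debris of similar hue inflates the area.
3. **Projection** (`maskToSphere`): each mask pixel back-projects to a ray;
   the residual $v = |x^2/r_x^2 + y^2/r_y^2 + z^2/r_z^2 - 1|$ is sampled at
   2000 points along the segment and the **first local minimum** taken.
   The first-local-minimum rule matters: near both surface crossings the
   sampled residual is almost zero, and a global argmin would land on the
   far side of the eye for roughly half the pixels. A closed-form mode
   solves the quadratic instead and is used as the oracle in tests; the
   sampled mode is the default for fidelity to the published procedure.
   Rays whose best residual exceeds 0.05 are counted and dropped —
   those pixels lie off the eye.
4. **Area** (`injectionAreaFraction`): the surface points are normalized to
   the unit sphere, projected by a Lambert azimuthal equal-area projection
   centred on their mean direction and scaled by the geometric-mean radius
   $(r_x r_y r_z)^{1/3}$, and the area of their alpha shape is computed in
   that plane (Delaunay triangles with circumradius $\le \alpha$; $\alpha$
   defaults to 10× the median nearest-neighbour spacing, with a
   convex-hull fallback when the complex degenerates). The fraction is
   referenced to the retinal surface — the ellipsoid below the rim,
   integrated by quadrature (Simpson in colatitude, trapezoid in the
   periodic azimuth; exact to ~1e-10 relative on spheres) — because
   injection sizes are biologically meaningful relative to the retina; the
   whole ellipsoid is available as an option and differs only by a
   constant factor.

## The synthetic world

`simulateScene()` generates the validation world: semi-axes drawn from
$\mathcal N(1400, 70)$ µm (a P12 mouse eye), rim opening from
$\mathcal N(53°, 3°)$, top-view tilts about $x$ and $y$ from
$\mathcal N(0°, 9°)$ truncated at ±20° with a free $z$-rotation, and the
side view equal to the top view composed with a 90° rotation about $x$
plus its own independent tilts — so the optical axes stay 90° ± 28° apart.
The injection centre is drawn **uniformly by area over the sub-rim
surface**; the alternative of drawing the two spherical angles uniformly
(which concentrates mass at the poles and can land above the rim) is kept
behind `legacyAngles = TRUE`, with above-rim centres rejected so the
ground-truth fractions remain defined. The site is 100 points scattered
with a 6° angular SD — realized as an isotropic normal in the tangent
plane pushed through the exponential map, which is unambiguous at the
poles where "normal in spherical coordinates" is not — and points above
the rim are discarded, exactly as stated.

Scenes are regenerated until the injection is visible in both views (the
centre plus at least 10 scatter points), mirroring the experimental
requirement that the injection appear in both photographs; an eye whose
injection faces away from a camera simply cannot be analysed. Rendering is
opaque and orthographic: the silhouette disc, hidden-line-removed
wire-frame meridians, the rim circle, claret injection dots, and an "M"
glyph at the nasal rim pole. Only the geometry is contractual — colours and
stroke style are fixed palette defaults. What the images do **not** emulate:
tissue deformation, debris, specular highlights, or depth-of-field blur. A
green synthetic validation therefore establishes the correctness of the
geometry and of the marking-to-coordinates pipeline, not robustness to
real-image nuisances; with real data the accuracy bottleneck is the manual
wire-frame alignment, which the synthetic protocol bypasses by using the
true transforms.

`autoMark()` replaces the human observer: each view is marked at the
projected centroid of the visible injection points. Marks are continuous
(sub-pixel); the validation correlations (Pearson $r \ge 0.98$ NT,
$\ge 0.99$ DV over 150 scenes) treat the published human-observer values
as lower bounds, and the automated pipeline clears them by a wide margin
($r \approx 0.9999$), since it has no alignment or perception error.

## Numerical choices

* Tolerances: rotation orthogonality 1e-9; wedge round-trips 1e-8 (point →
  coordinates → point) and 1e-10 (coordinates → point → coordinates);
  degeneracy detection 1e-9 on the distance to the pole axis.
* Sampled line search ties break to the smallest line parameter (nearest
  the viewer); the closed-form solver prefers the smaller root inside the
  segment, falling back to the clamped vertex (and, for a segment entirely
  inside the ellipsoid, the better endpoint).
* $\psi$ is reported in $[-90°, 90°]$; $\psi$ and $\psi \pm 180°$ name the
  same plane.
* The surface-area quadrature uses 2049 Simpson nodes × 512 azimuth nodes;
  against closed-form spheres this is exact to ~1e-10 relative, far below
  the pixelation error of any mask.
* Session JSON stores all numerics at full precision (`digits = NA`);
  round-trips are exact to 1e-12 (limited only by decimal text form).

## Scope and limitations

* Marks are inputs (or auto-generated for synthetic scenes); the package
  does not detect injections in real images, and it tracks a single
  injection — multiple same-dye spots hit the stereo correspondence
  problem.
* Perspective cameras and automatic wire-frame fitting are out of scope;
  view transforms come from the user's alignment.
* Image input is PNG/JPEG; TIFF is not supported in this build because no
  TIFF decoder is available among the package's dependencies.
* The wedge system on strongly eccentric ellipsoids inherits the
  sphere-normalization approximation described above.
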