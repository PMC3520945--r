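---
title: "Measuring terrain complexity on triangulated meshes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring terrain complexity on triangulated meshes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinterrain)
```

## The problem

Structural complexity of the seafloor is one of the strongest correlates of
benthic biodiversity, and ecologists condense it into a handful of indices:
**rugosity** (how contorted the surface is), **slope** and **aspect**. In
the field, rugosity is measured by draping a chain over the substrate and
dividing the chain length by the taped straight-line distance between its
ends — laborious, depth-limited, scale-locked to the chosen chain, and
sensitive to exactly where the chain happens to fall.

Modern stereo-imaging surveys (diver rigs, ROVs, AUVs) produce
centimetre-resolution bathymetric reconstructions as **triangulated
irregular networks** (TINs). `tinterrain` computes the classical indices
virtually on such meshes, at any scale, exhaustively over the whole survey,
and adds the machinery to quantify how trustworthy each index is.

Throughout, coordinates are (Easting, Northing, vertical) in metres with
**up positive** — depth maps that store depth positive-down must be negated
on import. This convention makes "the outward surface normal has an upward
component" literal for overhead-imaged terrain.

## Virtual chain-tape rugosity

A transect is defined by a start point $v_s$ and an end point $v_e$.
Together with a point directly above $v_s$ they span a **vertical slicing
plane** with horizontal unit normal $\hat n$; a point $v$ is at distance
$|\hat n \cdot v + d|$ from it. All mesh vertices within a threshold
$\gamma$ of the plane, lying between the endpoints along the transect, form
the virtual chain. The rugosity is the arc-chord ratio

$$R_c = \frac{L}{D},$$

with $L$ the summed 3D distance along consecutive chain points and $D$ the
straight-line distance from $v_s$ to $v_e$. Flat terrain gives
$R_c = 1$; rough terrain more.

Three places where the construction is genuinely open, and what this
package does:

* **Threshold $\gamma$.** It must scale with mesh resolution. The default
  is half the median edge length: large enough that a near-continuous
  ribbon of vertices is captured, small enough that parallel rows of a
  regular grid are not. On regular grids a transect lying *exactly* halfway
  between two vertex rows captures both (the inclusive boundary), and the
  chain zigzags; this is inherent to threshold selection and disappears on
  irregular meshes.
* **Ordering.** Linking "adjacent" candidates via a Euclidean distance
  matrix (a greedy nearest-unvisited-neighbour walk) can stall or jump on
  noisy ribbons. The default ordering is instead by scalar projection onto
  the horizontal transect direction — a deterministic total order, with
  ties broken by vertical coordinate then candidate index. The greedy walk
  is available as `ordering = "greedy"` for fidelity comparisons; the two
  agree on clean transects (tested).
* **Segment lengths.** Full 3D distances between consecutive selected
  vertices are summed, matching the lay of a physical chain. The
  alternative — projecting the points onto the slicing plane first —
  differs by at most $\gamma$-order terms and is reported alongside as
  `R_c_inplane`.

If the largest along-transect gap between consecutive candidates exceeds
$10\gamma$, the chain is bridging unsampled terrain and a warning is
raised (the result is still returned).

**Convergence behaviour.** Because chain vertices lie *on* the surface,
the traced chain is an inscribed polyline of the terrain profile and its
length error decreases *quadratically* with mesh resolution (halving the
spacing quarters the error). The suite verifies convergence to a numerical
quadrature oracle of the arc length on sinusoids. Vertex noise breaks this
clean rate: on real reconstructions the chain inherits an upward noise
bias, which is exactly the motivation for the area-based measure below.

## Area-based rugosity on a window

For a rectangular window (centre, width, length, orientation) the member
set is every triangle whose three vertices fall inside the closed window
rectangle in the E–N projection. The surface area is

$$A_s = \sum_{i \in \text{window}} A_i, \qquad
A_i = \tfrac12 \left\lVert (b_i - a_i) \times (c_i - a_i) \right\rVert ,$$

and the projected area onto a plane with unit normal $\hat n_p$ is

$$A_p = \sum_i A_i \, \lvert \hat n_i \cdot \hat n_p \rvert ,$$

with $\hat n_i$ the face normal. Rugosity is $R = A_s / A_p$.

The choice of projection plane is the crux:

* **Horizontal projection** ($\hat n_p = (0,0,1)$, giving `R_ne`): the
  raster-DEM convention. A perfectly flat plane tilted at slope $\alpha$
  scores $1/\cos\alpha$ — rugosity is confounded with slope.
* **PCA plane of best fit** (`R_pca`): the eigen-decomposition of the
  covariance of the window vertices gives an orthonormal basis ordered by
  descending variance; the third eigenvector is the normal of the plane
  minimising orthogonal scatter. Projecting onto this plane *decouples
  rugosity from slope*: any planar patch scores exactly 1 at any tilt
  (tested to $10^{-6}$ at 15–60°).

The eigenvector normal is sign-ambiguous; it is oriented upward
($\hat n_z > 0$), the overhead-imaging assumption. An exactly vertical
best-fit plane is oriented towards +Northing with a warning.

Having the fitted normal, slope and aspect are nearly free:

$$\alpha = \arccos(\hat n \cdot \hat k) \in [0°, 90°], \qquad
\psi = \operatorname{atan2}(n_E, n_N) \in (-180°, 180°],$$

with $\psi = 0$ facing North and $+90°$ facing East (compass style, chosen
to match the *northness* $= \cos\psi$ and *eastness* $= \sin\psi$
decomposition that removes the $\pm 180°$ wrap-around). At zero slope the
facing direction is undefined and aspect and its components are returned
as `NA` rather than a fabricated angle.

### Numerical and design choices

* **Absolute value in the projection.** $|\hat n_i \cdot \hat n_p|$ makes
  back-facing (overhang) triangles *add* to the projected area instead of
  cancelling. Where overhanging triangles overlap in projection the
  projected area is double-counted and rugosity is inflated; accepted and
  documented, since overhead-imaged meshes rarely capture overhangs.
* **Window membership** uses the *closed* rectangle: a vertex exactly on
  the boundary is inside. This makes the sliding-window engine bit-for-bit
  consistent with the single-window composition (tested).
* **PCA weighting.** The covariance is computed from the unweighted vertex
  scatter (each window vertex once). An area-weighted variant (triangle
  centroids weighted by area) is available via
  `pca_weighting = "area"`; on near-uniform meshes the two agree closely.
* **`min_triangles = 10`.** Windows with fewer members yield an undefined
  record: a plane fit on fewer vertices is ill-conditioned at typical mesh
  resolutions. Undefined windows (too few triangles, degenerate fit, zero
  projected area) return `NA` with a reason code, never an error, so
  exhaustive maps stay total.
* **Spatial indexing.** `mesh_index()` bins triangle centroids into a
  regular cell grid. A triangle wholly inside a convex window has its
  centroid inside it, so querying the cells overlapping the window yields
  a superset that is then filtered exactly — indexed and exhaustive
  extraction are identical on every tested instance, and queries stop
  scaling with total mesh size.

## Synthetic terrains

`generate_terrain()` builds seeded test bathymetry with known analytic
structure, standing in for field surveys that cannot ship with a package:

* `flat`, `inclined` — the exact identities ($R = 1$;
  $R_{ne} = 1/\cos\alpha$, recovered slope/facing) with closed-form
  oracles.
* `sinusoid` — known arc length by quadrature; used for the chain
  convergence tests.
* `peak_trough` — $z = a \, N' e^{-(E'^2 + N'^2)}$ with $E' = E/w$,
  $N' = N/w$: a peak and a trough separated by an inflection line of high
  slope, the canonical surface for demonstrating slope decoupling. The
  amplitude and width constants default to $a = 1$ m, $w = 1$ m on a
  6 m × 6 m extent at centimetre-scale resolution.
* `noise_field` — white vertical Gaussian noise smoothed to a correlation
  length: generic "rough terrain" for robustness experiments.

Regular grids are triangulated by the diagonal cell split — for square
cells the four corners are cocircular, so this *is* a valid Delaunay
triangulation — which scales to the multi-million-triangle meshes the
correlation experiments need. Jittered grids (`jitter > 0`) go through the
package's incremental Bowyer–Watson `delaunay_triangulate()`, which is
validated against a brute-force empty-circumcircle oracle and intended
for clouds up to a few thousand points. `add_vertex_noise()` adds seeded
i.i.d. vertical Gaussian noise, emulating stereo reconstruction noise.

What these generators deliberately do **not** emulate: spatially varying
mesh density, holes and occlusions, correlated (pose-drift) reconstruction
error, overhangs, and texture. Passing tests on synthetic terrain
demonstrate the *geometry* of the measures is right; they do not certify
behaviour on pathological survey artefacts.

## The validation machinery

**Placement sensitivity.** `translate_placements()` rigidly translates a
transect's endpoints by each radius (default 5, 10, 20, 40 cm) in each of
12 compass directions (angle origin East, counter-clockwise — the origin
is immaterial on statistically isotropic terrain, and fixing it keeps the
experiment deterministic), keeping orientation and length: 49 placements.
`placement_sensitivity()` evaluates either the chain metric or an oriented
window (length equal to the transect, long axis along it) at every
placement and reports mean, min, max and spread. Endpoint verticals are
re-sampled from the nearest mesh vertex at each translated location, since
a displaced chain lies on the terrain. On rough terrain the window
spread is strictly smaller than the chain spread — the area measure is the
more repeatable one — which the suite asserts on a seeded noise field.

**Correlation structure.** `correlation_report()` computes the Pearson
matrix (the regression framing of the validation makes Pearson the right
choice) over per-window slope, `R_pca` and `R_ne`, pairwise-complete with
the dropped-record count reported, plus an ordinary least-squares fit for
any requested pair. On the peak-and-trough surface the suite asserts the
slope-decoupling signature as a strict ordering:

$$\mathrm{corr}(\alpha, R_{ne}) \;>\; \mathrm{corr}(R_{pca}, R_{ne})
\;>\; \mathrm{corr}(\alpha, R_{pca}).$$

The *magnitudes* of these correlations are not invariants: they depend
strongly on the ratio of window size to the surface's feature scale (the
amplitude $a$ and width $w$). With the package defaults ($a = w = 1$ m,
1 m windows, 5 mm mesh) `corr(slope, R_ne)` is ≈ 0.92 while the other two
entries sit near 0.68 and 0.79; smaller features or larger windows pull
them apart further. The constants are deliberately held fixed rather than
tuned, and the ordering — which is scale-robust — is the asserted claim.

## Problem sizes used by the test-suite experiments

The correlation experiment runs on the 6 m × 6 m surface at 5 mm
resolution (2.88 M triangles) with 1 m windows on a 0.15 m grid of
centres (1 681 windows) — dense enough that the correlation estimates are
stable to well under the asserted tolerances, while keeping the whole
suite inside a coffee break on one CPU. Chain convergence uses
resolutions 50/25/12.5 mm; the projection-area oracle rasterises twenty
meshes of ≤ 200 triangles at ~1200² cells. Exhaustive every-vertex maps
of real surveys are supported but naturally take time proportional to
vertex count × window candidates.

## Known limitations

* 2.5D only: triangulation and window membership operate on the E–N
  projection; true 3D reconstruction of overhanging geometry is out of
  scope, and projected overhang area double-counts as described above.
* The Bowyer–Watson triangulator is quadratic-time; use it for point
  clouds, not for gridded megameshes (the grid generator already emits a
  Delaunay-consistent triangulation directly).
* Chain rugosity on regular grids is sensitive to transects falling
  exactly midway between vertex rows; prefer irregular meshes or accept
  the documented jog terms bounded by $2\gamma/D$.
* ESRI ASCII export snaps centres to a regular raster by nearest
  neighbour; strongly irregular centre sets should be exported as CSV.
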