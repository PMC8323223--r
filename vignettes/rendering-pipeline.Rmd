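---
title: "The neurorender software rendering pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neurorender software rendering pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurorender)
```

`neurorender` is a headless CPU re-implementation of the kind of rendering
pipeline that interactive neuroimaging viewers run on a GPU. This vignette
explains the models and procedures it implements, the parameters that
matter, the numerical choices made where a GPU pipeline would leave them to
hardware, and what the synthetic data generators do and do not emulate.

## Data model

Three domain types cover the supported imaging data:

* a **tractography** is an ordered list of fibers, each an `n x 3` matrix of
  world-space millimetre coordinates (at least 2 points, finite), optionally
  partitioned into named bundles — disjoint index sets that, when present,
  cover all fibers. Bundle labels are produced upstream (clustering or
  atlas segmentation); this package only consumes them.
* a **volume** is a 3D scalar array with positive voxel dimensions (mm) and
  an invertible 4×4 voxel-to-world affine; voxel indices are 0-based on the
  file side and map through the affine at voxel centers.
* a **mesh** is a vertex matrix plus a triangle index matrix, with optional
  unit per-vertex normals. Counter-clockwise winding is the outward face
  orientation (right-hand rule).

All binary formats store float32; in-memory objects hold doubles that have
been rounded through float32, which is why round-trips are exact rather than
approximate.

## Fiber display

**Sampling.** Displaying a few hundred thousand polylines is rarely useful
or fast, so a percentage `p` in [1, 100] selects a uniform random subset of
`max(1, floor(p/100 * n))` eligible fibers — floor, because that matches the
counts users expect from a percentage; minimum one, so a 1% sample of a tiny
bundle never renders nothing. The draw is a seeded Fisher–Yates prefix:
fixed seed, fixed selection, regardless of platform.

**Colors.** Bundles get "random" colors that are actually equally spaced
hues after a seeded random rotation, at full saturation and value. Plain
independent draws collide quickly (birthday effect); equal spacing
guarantees pairwise-distinct colors up to 360 bundles, after which hues wrap
and may repeat.

**Line pseudo-normals.** A line has no surface normal, so for Phong shading
each point uses the direction of the next fiber segment as its
pseudo-normal; the last point reuses the preceding segment, and zero-length
segments inherit the previous non-zero direction. This is the standard
illuminated-streamline trick and gives lines a cylinder-like sheen at a
fraction of the cost.

**Cylinders.** True tubes are built by sweeping an `n_sides`-gon along the
fiber. Ring orientation uses parallel transport of an initial perpendicular
frame (each ring's frame is the previous one rotated by the rotation that
maps the previous segment direction onto the next, then re-orthogonalized).
A fixed reference frame would twist the tube at bends; parallel transport
keeps the side walls watertight — every interior edge is shared by exactly
two triangles.

**Equidistant resampling** linearly interpolates along the cumulative arc
length to a fixed point count (whole-brain datasets are commonly stored at
21 points per fiber). Endpoints are preserved exactly; spacings between
consecutive points are uniform in arc length along the *original* polyline.
Note the resampled polyline's chord lengths can be slightly shorter at
corners — the tests measure arc positions on the original curve, not chords.

## Volume display

**Axis slices** are exact voxel planes — no interpolation — normalized to
[0, 1] by the volume-wide affine min–max map (a constant volume maps to
zero). The slice carries its world-plane geometry so the renderer can draw
it as a textured quad, and so `sample_plane()` can reproduce it exactly at
matched resolution: the plane corner sits half a voxel outside the first
voxel center, putting resampled pixel centers exactly on voxel centers.

**Slice-stack volume rendering** draws `n_s` planes perpendicular to the
viewing direction, spanning the volume's world bounding-box diagonal,
composited far to near. The plane count is

```
n_s = ceil(sf * sqrt(n_x^2 + n_y^2 + n_z^2)),    sf = 0.2 by default
```

i.e. a sampling factor times the voxel-grid diagonal. The formula leaves
`n_s` fractional; the ceiling is used so `spacing * n_s` always covers the
diagonal. For a typical 240×256×160 T1 acquisition the default gives 78
planes.

**Opacity model.** Which voxels are "solid" is decided by an Otsu threshold
(below: fully transparent; above: visible). The per-plane alpha is the
object's global alpha divided by `n_s`, so the accumulated opacity after
compositing the whole stack, `1 - (1 - a/n_s)^n_s ≈ 1 - e^{-a}`, is roughly
independent of the sampling factor: doubling `sf` refines the rendering
without darkening it. This per-slice alpha model is a package design choice;
the threshold-gating is the documented behavior being reproduced.

**Otsu thresholding** maximizes the between-class variance over a 256-bin
histogram spanning `[min, max]` — the classic formulation's discretization.
Ties (the variance curve is exactly flat across an empty histogram gap
between well-separated classes) break toward the lowest qualifying bin, and
the returned value is the lower edge of the first foreground bin, in
original intensity units. The test suite checks equivalence against an
exhaustive brute-force maximizer computed directly from the raw values.

**Gradients** for volume shading are central differences in the interior,
one-sided at boundaries, scaled by voxel size (units: intensity per mm), so
anisotropic voxels shade correctly.

**Sampling is nearest-neighbor everywhere** — documented for axis slices,
and extended to view-aligned planes for consistency; positions outside the
volume are a sentinel "empty" (`NA`) that carries zero opacity downstream,
preventing the bounding box from ghosting into the image.

## Mesh display

Missing vertex normals are computed as normalized area-weighted averages of
incident face normals (the cross-product magnitude provides the area
weighting for free; zero-area triangles therefore contribute nothing).
Vertices with no incident triangle get an arbitrary `(0, 0, 1)`.

Transparent meshes are drawn back to front with the painter's algorithm,
sorting by triangle-centroid distance to the eye — the cheap, standard
choice. Its known failure mode is inherited knowingly: mutually intersecting
transparent triangles cannot be ordered correctly by any per-triangle sort.
Sorting is stable, so coincident centroids keep file order and renders stay
deterministic. Transparency is a single per-mesh alpha, not per-vertex.

Mesh shading is two-sided: the interpolated normal is flipped toward the
viewer per pixel, so the inside of an open or clipped surface shades like
the outside instead of rendering black. The Phong *primitive*
(`phong_intensity`) itself is strictly one-sided as specified below.

## Illumination

The Phong model computes, per shaded point,

```
I = L_a K_a + L_d K_d max(0, s.n) + L_s K_s max(0, r.v)^f
```

with all six constants in [0, 1], all vectors unit length, `s` the direction
toward the light, `r` the reflection of `s` about the normal `n`, `v` the
direction toward the viewer, and `f >= 0` the shininess. Two clamps are
applied that the bare formula omits: negative dot products contribute
nothing, and the specular term is gated off when the light is behind the
surface (`s.n <= 0`) — unclamped Phong produces negative light and specular
highlights shining through objects. With `K_d = K_s = 0` the model
degenerates to geometry-free ambient shading, `I = L_a K_a`, which is what
the ambient-only invariance tests exploit.

The default light is a **headlight** (light direction = view direction).
Interactive viewers behave this way, and it keeps tests camera-relative; an
explicit `light_dir` overrides it. Default constants are
`L_a = K_a = 0.5`, `L_d = K_d = 0.5`, `L_s = K_s = 0.3`, `f = 8` — a muted
balance chosen so that all three terms are visible without saturating
white; they are ordinary parameters, not calibrated values.

## Camera

The camera orbits a focus point at radius `r` (mm), its orientation held as
a unit quaternion rather than Euler angles, which avoids gimbal lock and
accumulates less drift under composed increments (the orientation is
re-normalized after every operation; norm drift stays below 1e-9 over 10⁴
operations). The axis binding is a design choice the spherical-coordinate
picture leaves open: at identity the camera sits on +z looking at the focus
with up = +y; azimuth rotates about world-up, elevation about the negative
camera-right axis so positive elevation lifts the eye toward +y. "Rotate" as
a gesture is ambiguous between roll and trackball rotation in touch UIs;
here it is exposed explicitly as `roll()` about the view axis. Zoom divides
`r` (pinch-out magnifies) and clamps to [1e-3, 1e6] mm to prevent degenerate
projections. The view matrix is a standard look-at transform: the eye maps
to the origin, the focus to `(0, 0, -r)`.

## Rasterization and compositing

Projection is a perspective pinhole with a 45° default vertical field of
view; points at or behind the eye plane are flagged and the primitives
touching them are skipped (no near-plane clipping of partial primitives —
acceptable for scenes that sit in front of the camera, and deterministic).

Lines are rasterized with integer Bresenham walks between the floored
projected endpoints, interpolating depth and color linearly along the walk.
Triangles use edge-function barycentric scanning with perspective-correct
attribute interpolation (attributes divided by depth, re-normalized per
pixel). The opaque pass writes front-most-wins into a depth buffer; within
a primitive, duplicate pixels are written farthest-first so the nearest
fragment wins. The transparent pass never writes depth: it composites with
the non-premultiplied "over" operator wherever the fragment is nearer than
the opaque content. There is no anti-aliasing; determinism and testability
are preferred over smooth edges.

## Synthetic data

The generators exist so every code path is exercisable without downloads:

* `synth_tractography()` draws straight chords inside a 100 mm cube (about
  the extent of a human brain) and bows them sinusoidally by 0.5–4 mm —
  smooth, bounded, bundle-labeled curves. Default profiles are small
  (hundreds of fibers); the whole-brain profile used by the acceptance
  script (204,052 fibers, 36 bundles, 21 points) matches a real segmented
  whole-brain dataset's counts. What it does **not** emulate: anatomical
  trajectories, bundle geometry (synthetic "bundles" are index groups, not
  spatially coherent tracts), varying per-fiber point counts, or realistic
  fiber density. Tests passing on these fixtures demonstrate the pipeline's
  correctness, not anatomical fidelity.
* `synth_volume_two_class()` builds a centered ellipsoid of Gaussian
  foreground inside Gaussian background — exactly the bimodal histogram an
  Otsu threshold is designed for, with controllable overlap. It does not
  emulate tissue contrast, bias fields, or noise correlation.
* `synth_icosphere()` is an exact subdivided icosahedron (20·4^level
  triangles, watertight, outward CCW winding) standing in for anatomical
  surfaces.

All generators are pure functions of their seed: repeated calls are
bitwise-identical.

## File-format dialects

Two of the supported formats have no complete public specification, so the
package pins dialects:

* `.bundles` is a text header (`curves_count`, `byte_order`, a flat list
  alternating bundle name and 0-based starting fiber index, the data-file
  name) plus a `.bundlesdata` payload of, per fiber, an int32 point count
  followed by float32 xyz triples. Because the header stores bundles as
  contiguous ranges, the writer reorders fibers bundle-by-bundle (a no-op
  for the package's own generators). A tractography without labels is
  written as a single bundle named `"all"` — the format requires at least
  one label. Big-endian payloads declared in the header are honored on read.
* `.trk` points are stored as-is with an identity voxel-to-RAS matrix on
  write; on read, a valid (non-zero, invertible, non-identity) header matrix
  is applied to the points once, at load time, and kept on the object as
  provenance. Version-1 files carry an all-zero matrix, which is treated as
  "no transform".
* `.mesh` is the BrainVISA binary layout (`binar` magic + byte-order tag,
  `VOID` texture type, polygon dimension 3, one time step) with a minimal
  `.mesh.minf` text companion that must exist.
* GIfTI reading accepts ASCII, Base64Binary and GZipBase64Binary encodings
  and both array orders; writing always emits little-endian Base64Binary
  float32/int32.

Readers never silently drop data: declared counts that exceed the available
bytes raise errors, as do 4D NIfTI inputs (only 3D volumes are in scope).

## Problem sizes

The test-suite fixtures are deliberately small — tens to hundreds of fibers,
8³–32³ volumes, icospheres at subdivision ≤ 2, images of 16–96 pixels per
side — which keeps the full suite under a couple of minutes while covering
every operation, including one whole-brain-scale sampling check (204,052
fibers). The acceptance script uses the same whole-brain profile for
sampling, 50 random volumes for the Otsu rate, and a 64×64 combined render
for the determinism check.

## Known limitations

* No anti-aliasing, no partial-primitive near-plane clipping, no
  order-independent transparency.
* Volume rendering has no transfer function: opacity is a binary Otsu gate
  scaled per-slice, and intensity maps linearly to gray.
* Nearest-neighbor volume sampling shows voxel structure at high zoom (by
  design, but trilinear would look smoother).
* `.bundles` writing reorders fibers into bundle-contiguous order.
* Pure-R rasterization is intended for reproducible figures and tests, not
  interactive frame rates.
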