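# neurorender

A headless CPU renderer for combined neuroimaging scenes, written in R.

Neuroscientists and neurophysicians routinely inspect three kinds of brain
imaging data together: diffusion-MRI **tractography** (hundreds of thousands
of "fibers", each a 3D polyline, often partitioned into named anatomical
bundles), **MRI volumes** (3D voxel grids of scalar intensity), and **surface
meshes** (cortical or anatomical surfaces as vertex/triangle lists). Seeing a
fiber bundle against the slice or volume it threads through, or inside a
semi-transparent head mesh, is what gives the data anatomical context.
`neurorender` loads all of these from their standard on-disk formats and
renders combined scenes to PNG images entirely in software — no GPU, no
display — so that figures are scriptable and bit-reproducible.

## What it does

* **File formats.** TrackVis `.trk` (v2, 1000-byte header) and BrainVISA
  `.bundles`/`.bundlesdata` tractography; NIfTI-1 volumes (`.nii`,
  `.nii.gz`); GIfTI `.gii` and BrainVISA `.mesh`/`.mesh.minf` surfaces.
  Every reader has a matching writer and round-trips at float32 precision.
* **Fiber operations.** Percentage sampling (a uniform draw of
  `max(1, floor(p/100 · n))` fibers, seeded and reproducible), bundle
  selection by name, per-bundle random colors (equally spaced hues after a
  seeded rotation, so up to 360 bundles stay pairwise distinct), equidistant
  arc-length resampling, and polyline→tube expansion for cylinder display.
* **Volume operations.** Exact axis slices, min–max intensity normalization,
  Otsu thresholding (256-bin between-class-variance maximizer), central-
  difference gradients, and the view-aligned slice-stack plan
  `n_s = ceil(sf · sqrt(n_x² + n_y² + n_z²))` with default `sf = 0.2`.
* **Shading.** Phong illumination
  `I = L_a K_a + L_d K_d (s·n) + L_s K_s (r·v)^f`
  with clamped dot products; line fibers use the local fiber direction as a
  pseudo-normal, volumes use gradient normals gated by the Otsu threshold,
  meshes use area-weighted vertex normals.
* **Camera.** Spherical-coordinate pose (focus, radius, azimuth/elevation)
  stored as a unit quaternion, with orbit / roll / pan / zoom operations and
  a look-at view matrix.
* **Compositing.** Opaque geometry is depth-buffered; transparent geometry
  (volume slice stacks far→near, transparent meshes back-to-front by
  centroid distance) is blended with the standard "over" operator.
* **Synthetic data.** Deterministic generators for tractographies (smooth
  perturbed chords in a 100 mm cube), two-class volumes, and icosphere
  meshes, in memory or written to any supported format — the whole package
  is testable with no external data.

## Worked example

```r
library(neurorender)

t <- synth_tractography(n_fibers = 2000, n_bundles = 8,
                        points_per_fiber = 21, seed = 7)
t
#> <tractography> 2000 fibers, 42000 points, 8 bundles
#>   bundles: bundle_001(250), bundle_002(250), bundle_003(250), ...

sel <- sample_fibers(t, percent = 10, seed = 7)
length(sel$indices)
#> [1] 200        # floor(0.10 * 2000), seeded and reproducible

v <- synth_volume_two_class(dims = c(32, 32, 32), means = c(150, 50),
                            sds = c(5, 5), seed = 7)
otsu_threshold(v)
#> [1] 71.44598   # separates the 50-mean background from the 150-mean blob

plan <- plan_view_slices(v, view_dir = c(0, 0, 1), sf = 0.2)
c(plan$n_s, round(plan$spacing, 3))
#> [1] 12.000  2.667   # ceil(0.2 * sqrt(3 * 32^2)) planes, 2.667 mm apart

cam <- make_camera(center = c(50, 50, 50), r = 260, theta = 0.3, phi = 0.6)
sc <- scene(
  scene_tractography(t, percent = 50, seed = 7),
  scene_mesh({ m <- synth_icosphere(2); m$vertices <- m$vertices * 25 + 50; m },
             mat = material(base_color = c(0.8, 0.7, 0.6), alpha = 0.4)),
  background = c(0, 0, 0))
img <- render_scene(sc, cam, width = 320, height = 240)
save_png(img, "demo.png")
```

The sampled count is exact by construction; the Otsu threshold lands between
the two class means; the slice count follows the diagonal formula; rendering
the same scene twice yields byte-identical PNGs.

## Command line

A thin wrapper around the same functions is installed at
`inst/cli/neurorender`:

```sh
neurorender fixtures --out-dir fx --n-fibers 500 --seed 1
neurorender info fx/tract.bundles
neurorender sample --percent 10 --seed 0 --out fx/s.bundles fx/tract.bundles
neurorender slice --axis z --index 16 --out fx/slice.png fx/volume.nii.gz
neurorender render scene.yaml
```

`render` takes a YAML scene configuration (objects, camera, lighting, image
size) and writes the PNG plus a `<output>.yaml` sidecar recording the full
effective configuration; re-rendering a sidecar reproduces the image
bit-exactly.

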