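Package: neurorender
Title: Software Rendering of Tractography, MRI Volumes and Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless CPU renderer for combined neuroimaging scenes. Reads
    diffusion-MRI tractography (TrackVis .trk and BrainVISA .bundles), NIfTI-1
    volumes and surface meshes (GIfTI .gii, BrainVISA .mesh), and renders them
    to raster images with percentage fiber sampling, bundle selection and
    coloring, axis slices, slice-stack volume rendering gated by an Otsu
    threshold, back-to-front transparent mesh compositing, Phong illumination,
    and a quaternion spherical-coordinate camera. Includes deterministic
    synthetic-data generators for every supported format and a command-line
    interface for reproducible scene rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    xml2,
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
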