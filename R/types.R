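#' Construct a tractography object
#'
#' A tractography is an ordered set of fibers (streamlines), each a 3D
#' polyline in world millimetres, optionally partitioned into named bundles
#' and optionally carrying the spatial transform found in its source file.
#'
#' @param fibers list of numeric matrices, each with 3 columns (x, y, z in mm)
#'   and at least 2 rows of finite coordinates.
#' @param bundles named list mapping bundle name to an integer vector of
#'   1-based fiber indices. Bundle index sets must be disjoint and, when any
#'   bundle is present, jointly cover all fibers.
#' @param transform optional 4x4 voxel-to-world affine recorded from the
#'   source file (provenance only; points are already world-space).
#' @param source_format `"trk"`, `"bundles"` or `NA` for in-memory objects.
#' @return An object of class `tractography`.
#' @export
tractography <- function(fibers, bundles = list(), transform = NULL,
                         source_format = NA_character_) {
  if (!is.list(fibers)) stopf("`fibers` must be a list of point matrices")
  for (i in seq_along(fibers)) {
    f <- fibers[[i]]
    if (!is.matrix(f) || ncol(f) != 3L)
      stopf("fiber %d is not an n x 3 matrix", i)
    if (nrow(f) < 2L) stopf("fiber %d has fewer than 2 points", i)
    if (!all(is.finite(f))) stopf("fiber %d contains non-finite coordinates", i)
  }
  n <- length(fibers)
  if (length(bundles)) {
    if (is.null(names(bundles)) || any(names(bundles) == ""))
      stopf("all bundles must be named")
    idx <- unlist(bundles, use.names = FALSE)
    if (anyDuplicated(idx)) stopf("bundle index sets must be disjoint")
    if (length(idx) && (min(idx) < 1L || max(idx) > n))
      stopf("bundle indices out of range [1, %d]", n)
    if (length(idx) != n)
      stopf("bundles must cover all %d fibers (got %d indices)", n, length(idx))
    bundles <- lapply(bundles, function(v) as.integer(sort(v)))
  }
  if (!is.null(transform)) {
    transform <- as.matrix(transform)
    if (!all(dim(transform) == c(4L, 4L)))
      stopf("`transform` must be a 4x4 matrix")
  }
  structure(list(fibers = fibers, bundles = bundles, transform = transform,
                 source_format = source_format),
            class = "tractography")
}

#' @export
print.tractography <- function(x, ...) {
  np <- sum(vapply(x$fibers, nrow, integer(1)))
  cat(sprintf("<tractography> %d fibers, %d points, %d bundles\n",
              length(x$fibers), np, length(x$bundles)))
  if (length(x$bundles)) {
    sizes <- vapply(x$bundles, length, integer(1))
    show <- utils::head(sprintf("%s(%d)", names(sizes), sizes), 8L)
    cat("  bundles:", paste(show, collapse = ", "),
        if (length(sizes) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

n_fibers <- function(t) length(t$fibers)

#' Construct a volume object
#'
#' A scalar 3D image on a regular voxel grid, with voxel dimensions in mm and
#' a voxel-to-world affine (0-based voxel indices map through the affine).
#'
#' @param data 3D numeric array.
#' @param voxel_size length-3 positive numeric, mm per voxel along each axis.
#' @param affine 4x4 invertible voxel-to-world matrix. Defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stopf("volume dims must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 positive lengths in mm")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stopf("`affine` must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stopf("`affine` must be invertible")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, intensity [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a triangle mesh object
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit per-vertex normals.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || !all(is.finite(vertices)))
    stopf("`vertices` must be a finite n x 3 matrix")
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (nrow(triangles) < 1L) stopf("mesh must have at least one triangle")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stopf("triangle indices out of range [1, %d]", nrow(vertices))
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(vertices)))
      stopf("`normals` must match `vertices` in shape")
    nn <- row_norms(normals)
    if (any(abs(nn - 1) > 1e-5))
      stopf("`normals` must be unit length (tolerance 1e-5)")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles, normals: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$normals)) "absent" else "present"))
  invisible(x)
}
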