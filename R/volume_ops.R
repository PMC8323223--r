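# Volume-domain computation: axis slices, intensity normalization, Otsu
# thresholding, gradients, and the view-aligned slicing plan used by the
# slice-stack volume renderer.

#' Extract an axis-aligned slice from a volume
#'
#' Returns the exact voxel plane (nearest-neighbor, no interpolation) at a
#' 0-based index along one of the three volume axes, together with the world
#' geometry of the slice plane.
#'
#' @param v a [brain_volume()].
#' @param axis `"x"`, `"y"` or `"z"` (volume axis 1, 2 or 3).
#' @param index 0-based slice number in `[0, n_axis)`.
#' @return An object of class `axis_slice`: `image` (2D array over the two
#'   remaining axes), `axis`, `index`, and `world_plane` (plane origin, two
#'   in-plane unit axes and in-plane extents in mm, plus the source
#'   resolution), all derived from the volume affine.
#' @export
extract_axis_slice <- function(v, axis, index) {
  stopifnot(inherits(v, "brain_volume"))
  ax <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(ax)) stopf("`axis` must be one of 'x', 'y', 'z'")
  d <- dim(v$data)
  if (!is_scalar_num(index) || index != floor(index) ||
      index < 0 || index >= d[ax])
    stopf("slice index %s out of range [0, %d)", format(index), d[ax])
  i <- as.integer(index) + 1L
  image <- switch(ax,
                  v$data[i, , , drop = TRUE],
                  v$data[, i, , drop = TRUE],
                  v$data[, , i, drop = TRUE])
  if (is.null(dim(image))) dim(image) <- d[-ax]
  inplane <- setdiff(1:3, ax)
  # plane corner at voxel (-0.5, -0.5) of the in-plane axes, so pixel centers
  # of a resolution-matched resample coincide with voxel centers
  vox_origin <- c(0, 0, 0)
  vox_origin[ax] <- index
  vox_origin[inplane] <- -0.5
  origin <- as.numeric(v$affine %*% c(vox_origin, 1))[1:3]
  u_vec <- v$affine[1:3, inplane[1L]]
  v_vec <- v$affine[1:3, inplane[2L]]
  plane <- list(origin = origin,
                u = u_vec / vnorm(u_vec), v = v_vec / vnorm(v_vec),
                width = vnorm(u_vec) * d[inplane[1L]],
                height = vnorm(v_vec) * d[inplane[2L]],
                resolution = d[inplane])
  structure(list(axis = c("x", "y", "z")[ax], index = as.integer(index),
                 image = image, world_plane = plane),
            class = "axis_slice")
}

#' Linearly map intensities to [0, 1]
#'
#' The injective affine map `(x - min) / (max - min)`; a constant input maps
#' to all zeros.
#'
#' @param values numeric vector or array of finite intensities.
#' @return Values rescaled to `[0, 1]`, same shape.
#' @export
normalize_intensity <- function(values) {
  if (!all(is.finite(values))) stopf("intensities must be finite")
  rng <- range(values)
  if (rng[1] == rng[2]) return(values * 0)
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Otsu threshold of a volume
#'
#' Builds an `n_bins` histogram spanning `[min, max]` and returns the
#' threshold maximizing the between-class variance, in original intensity
#' units. Ties break toward the lowest qualifying bin; the returned value is
#' the lower edge of the first above-threshold bin.
#'
#' @param v a [brain_volume()] or numeric array with at least 2 distinct
#'   values.
#' @param n_bins histogram resolution (default 256).
#' @return Scalar threshold; voxels with intensity `>=` the threshold are the
#'   foreground class.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  x <- if (inherits(v, "brain_volume")) v$data else v
  rng <- range(x)
  if (rng[1] == rng[2]) stopf("Otsu threshold undefined for a constant volume")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)                      # class 0 = bins 1..k
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  k <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  best <- which.max(sigma_b)           # lowest bin on ties
  edges[best + 1L]
}

#' Central-difference gradient of a volume
#'
#' Central differences in the interior, one-sided at the boundaries, scaled
#' by the voxel size so the result is in intensity per mm.
#'
#' @param v a [brain_volume()] with at least 2 voxels per axis.
#' @return 4D array `dim(v) x 3` holding the gradient vector at every voxel.
#' @export
central_gradient <- function(v) {
  stopifnot(inherits(v, "brain_volume"))
  d <- dim(v$data)
  if (any(d < 2L)) stopf("gradient needs at least 2 voxels per axis")
  g <- array(0, c(d, 3L))
  for (ax in 1:3) {
    n <- d[ax]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    step <- (hi - lo) * v$voxel_size[ax]
    idx_hi <- idx_lo <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx_hi[[ax]] <- hi; idx_lo[[ax]] <- lo
    diff <- do.call(`[`, c(list(v$data), idx_hi)) -
      do.call(`[`, c(list(v$data), idx_lo))
    step_arr <- switch(ax,
                       array(step, d),
                       aperm(array(step, d[c(2, 1, 3)]), c(2, 1, 3)),
                       aperm(array(step, d[c(3, 1, 2)]), c(2, 3, 1)))
    g[, , , ax] <- diff / step_arr
  }
  g
}

#' Plan view-aligned slicing planes for volume rendering
#'
#' The number of planes is `n_s = ceil(sf * sqrt(n_x^2 + n_y^2 + n_z^2))`,
#' a sampling factor `sf` (default 0.2) times the voxel-grid diagonal. The
#' planes are perpendicular to the viewing direction, uniformly spaced so the
#' stack spans the volume's world bounding-box diagonal, and ordered far to
#' near for back-to-front compositing.
#'
#' @param v a [brain_volume()].
#' @param view_dir non-zero length-3 viewing direction (from the eye toward
#'   the scene).
#' @param sf positive sampling factor.
#' @return An object of class `slicing_plan`: `n_s`, `sf`, `spacing` (mm),
#'   `view_dir` (unit), and `offsets` — signed plane-center distances along
#'   `view_dir`, ordered far to near.
#' @export
plan_view_slices <- function(v, view_dir = c(0, 0, 1), sf = 0.2) {
  stopifnot(inherits(v, "brain_volume"))
  if (!is_scalar_num(sf) || sf <= 0) stopf("`sf` must be positive")
  view_dir <- as.numeric(view_dir)
  if (vnorm(view_dir) == 0) stopf("view direction must be non-zero")
  w <- view_dir / vnorm(view_dir)
  d <- dim(v$data)
  n_s <- as.integer(ceiling(sf * sqrt(sum(as.numeric(d)^2))))
  corners <- volume_corners(v)
  proj <- corners %*% w
  span <- range(proj)
  spacing <- (span[2] - span[1]) / n_s
  # plane centers at mid-spacing, farthest (largest projection) first
  offsets <- span[1] + (seq_len(n_s) - 0.5) * spacing
  offsets <- rev(offsets)
  structure(list(n_s = n_s, sf = sf, spacing = spacing, view_dir = w,
                 offsets = offsets),
            class = "slicing_plan")
}

# world coordinates of the 8 voxel-grid corner positions (voxel centers at
# the extremes extended by half a voxel)
volume_corners <- function(v) {
  d <- dim(v$data)
  g <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5), c(-0.5, d[2] - 0.5),
                             c(-0.5, d[3] - 0.5)))
  t(v$affine %*% t(cbind(g, 1)))[, 1:3, drop = FALSE]
}

#' Sample a world-space plane through a volume
#'
#' Each output pixel holds the nearest-voxel intensity at its world position;
#' positions outside the volume are `NA` (rendered fully transparent
#' downstream).
#'
#' @param v a [brain_volume()].
#' @param plane list with `origin` (a plane corner), unit in-plane axes `u`
#'   and `v`, and extents `width`/`height` in mm — the layout produced by
#'   [extract_axis_slice()].
#' @param resolution length-2 integer pixel grid; defaults to the plane's
#'   source resolution when present.
#' @return 2D numeric array `resolution[1] x resolution[2]`, `NA` where the
#'   plane leaves the volume.
#' @export
sample_plane <- function(v, plane, resolution = NULL) {
  stopifnot(inherits(v, "brain_volume"))
  if (is.null(resolution)) resolution <- plane$resolution
  if (is.null(resolution)) stopf("`resolution` required")
  resolution <- as.integer(resolution)
  nu <- resolution[1L]; nv <- resolution[2L]
  su <- (seq_len(nu) - 0.5) / nu * plane$width
  sv <- (seq_len(nv) - 0.5) / nv * plane$height
  pts <- cbind(rep(su, times = nv), rep(sv, each = nu))
  world <- outer(pts[, 1], plane$u) + outer(pts[, 2], plane$v)
  world <- sweep(world, 2L, plane$origin, `+`)
  vals <- sample_volume_nearest(v, world)
  if (all(is.na(vals))) stopf("plane does not intersect the volume")
  matrix(vals, nrow = nu, ncol = nv)
}

# Nearest-voxel lookup for an n x 3 matrix of world points; NA outside.
sample_volume_nearest <- function(v, world) {
  inv <- solve(v$affine)
  vox <- cbind(world, 1) %*% t(inv)
  i <- as.integer(round(vox[, 1])); j <- as.integer(round(vox[, 2]))
  k <- as.integer(round(vox[, 3]))
  d <- dim(v$data)
  ok <- i >= 0L & i < d[1] & j >= 0L & j < d[2] & k >= 0L & k < d[3]
  out <- rep(NA_real_, nrow(world))
  if (any(ok))
    out[ok] <- v$data[cbind(i[ok] + 1L, j[ok] + 1L, k[ok] + 1L)]
  out
}
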