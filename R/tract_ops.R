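# Fiber-level processing: percentage sampling, bundle selection, bundle
# colors, equidistant resampling, direction pseudo-normals, and polyline to
# tube-mesh expansion.

#' Sample a percentage of fibers
#'
#' Draws a uniform random subset, without replacement, of the eligible fibers
#' (all fibers, or those in the named bundles). The subset size is exactly
#' `floor(percent/100 * n_eligible)`, but never 0 while eligible fibers
#' exist; the draw is a seeded Fisher-Yates prefix, so a fixed seed always
#' reproduces the same selection.
#'
#' @param t a [tractography()].
#' @param percent integer percentage in `[1, 100]`.
#' @param seed PRNG seed.
#' @param within optional character vector of bundle names restricting the
#'   eligible set.
#' @return An object of class `fiber_selection`: sorted `indices` (1-based),
#'   `percent`, `seed`.
#' @export
sample_fibers <- function(t, percent, seed = 0L, within = NULL) {
  stopifnot(inherits(t, "tractography"))
  if (!is_scalar_num(percent) || percent < 1 || percent > 100)
    stopf("`percent` must be in [1, 100] (fiber sampling runs from 1%% to 100%%)")
  eligible <- if (is.null(within)) seq_len(n_fibers(t))
  else select_bundles(t, within)$indices
  n_el <- length(eligible)
  if (n_el == 0L) stopf("no eligible fibers to sample")
  k <- max(1L, as.integer(floor(percent / 100 * n_el)))
  idx <- if (k == n_el) eligible
  else with_seed(seed, eligible[sample.int(n_el, k)])
  structure(list(indices = sort(idx), percent = as.integer(percent),
                 seed = as.integer(seed)),
            class = "fiber_selection")
}

#' Select fibers by bundle name
#'
#' @param t a labeled [tractography()].
#' @param names character vector of bundle names.
#' @return A `fiber_selection` holding the union of the named bundles'
#'   fiber indices, with `percent = 100`.
#' @export
select_bundles <- function(t, names) {
  stopifnot(inherits(t, "tractography"))
  if (!length(t$bundles)) stopf("tractography carries no bundle labels")
  missing <- setdiff(names, base::names(t$bundles))
  if (length(missing))
    stopf("unknown bundle name(s): %s", paste(missing, collapse = ", "))
  idx <- sort(unique(unlist(t$bundles[names], use.names = FALSE)))
  structure(list(indices = as.integer(idx), percent = 100L, seed = NA_integer_),
            class = "fiber_selection")
}

#' Assign a random color to every bundle
#'
#' Colors are hues equally spaced around the color wheel after a seeded
#' random rotation, at full saturation and value — pairwise distinct for up
#' to 360 bundles and deterministic for a fixed seed.
#'
#' @param t a labeled [tractography()].
#' @param seed PRNG seed.
#' @return Named list mapping bundle name to an RGB triple in `[0, 1]`.
#' @export
assign_bundle_colors <- function(t, seed = 0L) {
  stopifnot(inherits(t, "tractography"))
  nb <- length(t$bundles)
  if (nb == 0L) stopf("tractography carries no bundle labels")
  rot <- with_seed(seed, stats::runif(1))
  hues <- (rot + (seq_len(nb) - 1L) / nb) %% 1
  cols <- t(grDevices::col2rgb(grDevices::hsv(hues, 1, 1))) / 255
  palette <- lapply(seq_len(nb), function(i) as.numeric(cols[i, ]))
  names(palette) <- names(t$bundles)
  palette
}

# cumulative arc length of a polyline (n x 3 matrix)
arc_lengths <- function(p) {
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Resample a fiber to equidistant points
#'
#' Linear interpolation along arc length: the result has exactly `n_points`
#' points on the original polyline, keeps both endpoints, and has uniform
#' consecutive spacing.
#'
#' @param f numeric matrix, one fiber (n x 3).
#' @param n_points target point count, at least 2.
#' @return `n_points` x 3 matrix.
#' @export
resample_fiber_equidistant <- function(f, n_points) {
  if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 2L)
    stopf("`f` must be an n x 3 matrix with n >= 2")
  if (!is_scalar_num(n_points) || n_points < 2)
    stopf("`n_points` must be >= 2")
  s <- arc_lengths(f)
  total <- s[length(s)]
  if (total <= 0) stopf("cannot resample a zero-length fiber")
  target <- seq(0, total, length.out = n_points)
  out <- cbind(stats::approx(s, f[, 1L], xout = target, ties = "ordered")$y,
               stats::approx(s, f[, 2L], xout = target, ties = "ordered")$y,
               stats::approx(s, f[, 3L], xout = target, ties = "ordered")$y)
  out[1L, ] <- f[1L, ]
  out[n_points, ] <- f[nrow(f), ]
  out
}

#' Per-point fiber directions (line pseudo-normals)
#'
#' For line rendering the surface normal is emulated by the local fiber
#' direction: point `i` gets the unit direction of segment `i -> i+1`, the
#' last point reuses the preceding segment, and zero-length segments inherit
#' the previous non-zero direction.
#'
#' @param f numeric matrix, one fiber (n x 3, n >= 2).
#' @return n x 3 matrix of unit vectors.
#' @export
fiber_segment_directions <- function(f) {
  if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 2L)
    stopf("`f` must be an n x 3 matrix with n >= 2")
  n <- nrow(f)
  seg <- f[-1L, , drop = FALSE] - f[-n, , drop = FALSE]
  len <- row_norms(seg)
  if (all(len == 0)) stopf("all fiber points coincide")
  dirs <- matrix(NA_real_, n - 1L, 3L)
  last <- NULL
  for (i in seq_len(n - 1L)) {
    if (len[i] > 0) last <- seg[i, ] / len[i]
    if (is.null(last)) next
    dirs[i, ] <- last
  }
  # leading zero-length segments inherit the first non-zero direction
  first_ok <- which(!is.na(dirs[, 1L]))[1L]
  if (first_ok > 1L)
    dirs[seq_len(first_ok - 1L), ] <- rep(dirs[first_ok, ],
                                          each = first_ok - 1L)
  rbind(dirs, dirs[n - 1L, , drop = FALSE])
}

#' Expand a fiber polyline into a tube mesh
#'
#' Builds an open tube of `n_sides`-gon rings, one ring per fiber point,
#' oriented by parallel transport of an initial perpendicular frame along the
#' fiber (which avoids ring twisting at bends). Vertex normals point radially
#' outward.
#'
#' @param f numeric matrix, one fiber (n x 3, n >= 2).
#' @param radius tube radius in mm.
#' @param n_sides ring vertex count, at least 3.
#' @return A [tri_mesh()] with `n * n_sides` vertices and
#'   `(n - 1) * n_sides * 2` triangles.
#' @export
fiber_to_tube_mesh <- function(f, radius = 0.5, n_sides = 6L) {
  if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 2L)
    stopf("`f` must be an n x 3 matrix with n >= 2")
  if (!is_scalar_num(radius) || radius <= 0) stopf("`radius` must be positive")
  if (!is_scalar_num(n_sides) || n_sides < 3) stopf("`n_sides` must be >= 3")
  n_sides <- as.integer(n_sides)
  n <- nrow(f)
  dirs <- fiber_segment_directions(f)
  # initial frame perpendicular to the first direction
  d0 <- dirs[1L, ]
  ref <- if (abs(d0[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize3(cross3(d0, ref))
  w <- cross3(d0, u)
  frames_u <- matrix(0, n, 3L); frames_w <- matrix(0, n, 3L)
  frames_u[1L, ] <- u; frames_w[1L, ] <- w
  for (i in 2:n) {
    a <- dirs[i - 1L, ]; b <- dirs[i, ]
    axis <- cross3(a, b)
    s <- vnorm(axis)
    if (s > 1e-12) {
      ang <- atan2(s, sum(a * b))
      q <- quat_from_axis_angle(axis, ang)
      u <- quat_rotate(q, u)
      w <- quat_rotate(q, w)
    }
    # re-orthogonalize against drift
    u <- normalize3(u - sum(u * b) * b)
    w <- cross3(b, u)
    frames_u[i, ] <- u; frames_w[i, ] <- w
  }
  ang <- 2 * pi * (seq_len(n_sides) - 1L) / n_sides
  ca <- cos(ang); sa <- sin(ang)
  verts <- matrix(0, n * n_sides, 3L)
  norms <- matrix(0, n * n_sides, 3L)
  for (i in seq_len(n)) {
    ring_n <- outer(ca, frames_u[i, ]) + outer(sa, frames_w[i, ])
    rows <- (i - 1L) * n_sides + seq_len(n_sides)
    norms[rows, ] <- ring_n
    verts[rows, ] <- sweep(ring_n * radius, 2L, f[i, ], `+`)
  }
  j <- seq_len(n_sides)
  jn <- c(seq_len(n_sides)[-1L], 1L)
  tri <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_sides + j
    b <- (i - 1L) * n_sides + jn
    c2 <- i * n_sides + j
    d2 <- i * n_sides + jn
    tri[[i]] <- rbind(cbind(a, c2, b), cbind(b, c2, d2))
  }
  tri_mesh(verts, do.call(rbind, tri), normals = norms)
}
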