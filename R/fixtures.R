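# Deterministic synthetic-data generators. These produce valid in-memory
# objects (and, through the io module, files) for every supported format so
# the whole pipeline is testable without any external download. Profiles
# mirror typical whole-brain acquisitions: hundreds of thousands of fibers in
# a ~100 mm field of view, two-class T1-like intensity volumes, icosphere
# meshes standing in for anatomical surfaces.

#' Generate a synthetic tractography
#'
#' `n_fibers` smooth 3D curves — sinusoidal perturbations of straight chords
#' inside a 100 mm cube — evenly assigned to `n_bundles` named bundles.
#' Bitwise-deterministic for a fixed seed.
#'
#' @param n_fibers number of fibers.
#' @param n_bundles number of bundles (0 for an unlabeled tractography).
#' @param points_per_fiber points per fiber (default 21).
#' @param seed PRNG seed.
#' @return A [tractography()].
#' @export
synth_tractography <- function(n_fibers = 100L, n_bundles = 4L,
                               points_per_fiber = 21L, seed = 0L) {
  stopifnot(n_fibers >= 1L, n_bundles >= 0L, points_per_fiber >= 2L)
  n <- as.integer(n_fibers); p <- as.integer(points_per_fiber)
  pts <- with_seed(seed, {
    A <- matrix(stats::runif(n * 3, 0, 100), n, 3L)
    B <- matrix(stats::runif(n * 3, 0, 100), n, 3L)
    amp <- stats::runif(n, 0.5, 4)        # mm bow amplitude
    phase <- stats::runif(n, 0, 2 * pi)
    wdir <- matrix(stats::rnorm(n * 3), n, 3L)
    wdir <- wdir / row_norms(wdir)
    tt <- seq(0, 1, length.out = p)
    bow <- sin(pi * outer(rep(1, n), tt) + phase) * amp  # n x p
    arr <- array(0, c(n, p, 3L))
    for (k in 1:3)
      arr[, , k] <- A[, k] + outer(B[, k] - A[, k], tt) + bow * wdir[, k]
    arr
  })
  pts <- as_float32(pts)
  fibers <- lapply(seq_len(n), function(i) {
    m <- pts[i, , ]
    dim(m) <- c(p, 3L)
    m
  })
  bundles <- list()
  if (n_bundles > 0L) {
    nb <- min(as.integer(n_bundles), n)
    grp <- sort(rep(seq_len(nb), length.out = n))
    bundles <- split(seq_len(n), grp)
    names(bundles) <- sprintf("bundle_%03d", seq_len(nb))
  }
  tractography(fibers, bundles = bundles)
}

#' Generate a synthetic two-class volume
#'
#' A centered ellipsoid of Gaussian-distributed foreground intensity inside a
#' Gaussian background — the classic bimodal histogram an Otsu threshold
#' should split.
#'
#' @param dims length-3 voxel dimensions (each >= 4).
#' @param means length-2 numeric: foreground and background mean intensity.
#' @param sds length-2 numeric standard deviations (0 gives exactly two
#'   distinct values).
#' @param voxel_size voxel dimensions in mm.
#' @param seed PRNG seed.
#' @return A [brain_volume()].
#' @export
synth_volume_two_class <- function(dims = c(32L, 32L, 32L),
                                   means = c(150, 50), sds = c(5, 5),
                                   voxel_size = c(1, 1, 1), seed = 0L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 4L), length(means) == 2L)
  sds <- rep(as.numeric(sds), length.out = 2L)
  cen <- (dims - 1) / 2
  semi <- dims / 3
  i <- (seq_len(dims[1]) - 1 - cen[1]) / semi[1]
  j <- (seq_len(dims[2]) - 1 - cen[2]) / semi[2]
  k <- (seq_len(dims[3]) - 1 - cen[3]) / semi[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  fg <- r2 <= 1
  data <- with_seed(seed, {
    x <- array(stats::rnorm(prod(dims), means[2], sds[2]), dims)
    x[fg] <- stats::rnorm(sum(fg), means[1], sds[1])
    x
  })
  brain_volume(as_float32(data), voxel_size = voxel_size)
}

#' Generate a unit icosphere mesh
#'
#' Subdivides an icosahedron `level` times, projecting every vertex to the
#' unit sphere: 20 * 4^level triangles, watertight, counter-clockwise winding
#' facing outward. No normals are attached (so normal computation can be
#' exercised).
#'
#' @param level subdivision level, >= 0.
#' @return A [tri_mesh()].
#' @export
synth_icosphere <- function(level = 1L) {
  if (!is_scalar_num(level) || level < 0) stopf("`level` must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mids <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      got <- mids[[key]]
      if (!is.null(got)) return(got)
      m <- normalize3((verts[a, ] + verts[b, ]) / 2)
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      assign(key, idx, envir = mids)
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c2 <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c2); ca <- midpoint(c2, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c2, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- nf
  }
  dimnames(v) <- NULL
  tri_mesh(v, f)
}
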