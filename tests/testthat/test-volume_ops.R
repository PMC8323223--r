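test_that("axis slices are exact voxel planes", {
  data <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    data[i, j, k] <- 100 * (i - 1) + 10 * (j - 1) + (k - 1)
  v <- brain_volume(data)
  sz <- extract_axis_slice(v, "z", 1L)
  expect_equal(sz$image,
               outer(100 * (0:2), 10 * (0:2), `+`) + 1)
  sx <- extract_axis_slice(v, "x", 0L)
  expect_equal(sx$image, outer(10 * (0:2), 0:2, `+`))
  expect_error(extract_axis_slice(v, "z", 3L), "out of range")
  expect_error(extract_axis_slice(v, "z", -1L), "out of range")
})

test_that("intensity normalization is the affine min-max map", {
  expect_equal(normalize_intensity(c(0, 50, 100)), c(0, 0.5, 1))
  expect_equal(normalize_intensity(c(7, 7)), c(0, 0))
  expect_equal(normalize_intensity(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_error(normalize_intensity(c(1, NA)), "finite")
})

test_that("Otsu threshold matches the exhaustive between-class-variance scan", {
  # hard two-level volume
  x <- array(c(rep(0, 100), rep(200, 100)), c(10, 5, 4))
  v <- brain_volume(x)
  thr <- otsu_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 200)
  expect_equal(thr, otsu_bruteforce(x))

  # well-separated Gaussian classes: the variance curve plateaus across the
  # empty gap and the lowest-bin tie-break lands at the gap's low edge,
  # strictly between the class means
  set.seed(11)
  y <- array(c(rnorm(500, 50, 5), rnorm(500, 150, 5)), c(10, 10, 10))
  ty <- otsu_threshold(brain_volume(y))
  expect_gt(ty, 50); expect_lt(ty, 150)
  expect_equal(ty, otsu_bruteforce(y))

  # overlapping classes: the maximum is unique and sits mid-way
  set.seed(12)
  z <- array(c(rnorm(500, 50, 15), rnorm(500, 150, 15)), c(10, 10, 10))
  tz <- otsu_threshold(brain_volume(z))
  expect_gt(tz, 90); expect_lt(tz, 110)
  expect_equal(tz, otsu_bruteforce(z))

  expect_error(otsu_threshold(brain_volume(array(5, c(4, 4, 4)))), "constant")
})

test_that("Otsu equals the brute-force oracle across random fixtures", {
  for (s in 1:10) {
    v <- synth_volume_two_class(dims = c(12L, 12L, 12L),
                                means = c(150, 50), sds = c(8, 8), seed = s)
    expect_equal(otsu_threshold(v), otsu_bruteforce(v$data))
  }
})

test_that("central gradients recover affine intensity fields", {
  d <- c(6L, 6L, 6L)
  ramp <- array(0, d)
  for (i in seq_len(d[1])) ramp[i, , ] <- 2 * (i - 1)
  g <- central_gradient(brain_volume(ramp))
  # interior voxels: gradient exactly (2, 0, 0)
  expect_equal(unname(g[2:5, 2:5, 2:5, 1]), array(2, c(4, 4, 4)))
  expect_equal(max(abs(g[, , , 2:3])), 0)
  # one-sided boundary estimates agree for a linear field
  expect_equal(unname(g[1, 3, 3, 1]), 2)

  g0 <- central_gradient(brain_volume(array(7, c(4, 4, 4))))
  expect_equal(max(abs(g0)), 0)

  # anisotropic spacing: f = i + 3j in voxel units, voxel size (1, 2, 1) mm
  f <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    f[i, j, ] <- (i - 1) + 3 * (j - 1)
  ga <- central_gradient(brain_volume(f, voxel_size = c(1, 2, 1)))
  expect_equal(unname(ga[3, 3, 3, ]), c(1, 1.5, 0))
})

test_that("view-slice plans follow the ceiling of the diagonal formula", {
  mk <- function(d) brain_volume(array(0, d))
  expect_equal(plan_view_slices(mk(c(3, 4, 1)), sf = 1)$n_s, 6L)
  expect_equal(plan_view_slices(mk(c(240, 256, 160)), sf = 0.2)$n_s, 78L)
  # doubling sf at most doubles-plus-one (ceiling slack)
  n1 <- plan_view_slices(mk(c(30, 40, 20)), sf = 0.2)$n_s
  n2 <- plan_view_slices(mk(c(30, 40, 20)), sf = 0.4)$n_s
  expect_gte(n2, 2L * n1 - 1L)
  expect_lte(n2, 2L * n1 + 1L)
  expect_error(plan_view_slices(mk(c(4, 4, 4)), view_dir = c(0, 0, 0)),
               "non-zero")
  expect_error(plan_view_slices(mk(c(4, 4, 4)), sf = 0), "positive")
})

test_that("slice-count formula is monotone in dims and sf", {
  base <- c(20L, 30L, 40L)
  n0 <- plan_view_slices(brain_volume(array(0, base)))$n_s
  for (ax in 1:3) {
    d <- base; d[ax] <- d[ax] + 15L
    expect_gte(plan_view_slices(brain_volume(array(0, d)))$n_s, n0)
  }
  expect_gte(plan_view_slices(brain_volume(array(0, base)), sf = 0.5)$n_s, n0)
})

test_that("slicing plans span the bounding-box diagonal far to near", {
  v <- brain_volume(array(0, c(10, 20, 30)), voxel_size = c(1, 1, 2))
  w <- c(1, 1, 1) / sqrt(3)
  plan <- plan_view_slices(v, view_dir = w, sf = 0.5)
  expect_equal(plan$view_dir, w)
  expect_true(all(diff(plan$offsets) < 0))   # far -> near ordering
  corners <- rbind(c(-0.5, -0.5, -0.5), c(9.5, 19.5, 59.5))
  span <- range(corners %*% w)
  expect_equal(plan$spacing * plan$n_s, diff(span))
})

test_that("plane sampling reproduces axis slices and flags empty space", {
  v <- synth_volume_two_class(dims = c(8L, 8L, 8L), seed = 2)
  sl <- extract_axis_slice(v, "y", 3L)
  resampled <- sample_plane(v, sl$world_plane)
  expect_identical(resampled, sl$image)

  # oblique plane through a constant volume: every hit equals the constant
  vc <- brain_volume(array(3, c(8, 8, 8)))
  plane <- list(origin = c(4, 4, 0), u = c(1, 0, 1) / sqrt(2),
                v = c(0, 1, 0), width = 10, height = 8)
  vals <- sample_plane(vc, plane, resolution = c(16L, 16L))
  expect_true(all(is.na(vals) | vals == 3))
  expect_gt(sum(!is.na(vals)), 0L)

  far <- list(origin = c(100, 100, 100), u = c(1, 0, 0), v = c(0, 1, 0),
              width = 5, height = 5)
  expect_error(sample_plane(vc, far, resolution = c(4L, 4L)), "intersect")
})
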