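test_that("fiber sampling obeys the floor count law with a minimum of one", {
  # exhaustive check of |indices| = max(1, floor(percent/100 * n)) on a grid
  for (n in c(1L, 7L, 99L, 1000L)) {
    t <- synth_tractography(n, 0L, 3L, seed = 1)
    for (pct in c(1L, 10L, 33L, 50L, 99L, 100L)) {
      sel <- sample_fibers(t, pct, seed = 5)
      expect_identical(length(sel$indices),
                       max(1L, as.integer(floor(pct / 100 * n))))
      expect_true(all(sel$indices >= 1L & sel$indices <= n))
      expect_false(anyDuplicated(sel$indices) > 0L)
    }
  }
})

test_that("fiber sampling is deterministic and monotone in percent", {
  t <- tiny_tract(n_fibers = 200L)
  s1 <- sample_fibers(t, 37, seed = 9)
  s2 <- sample_fibers(t, 37, seed = 9)
  expect_identical(s1$indices, s2$indices)
  sizes <- vapply(c(1, 5, 25, 50, 75, 100), function(p)
    length(sample_fibers(t, p, seed = 9)$indices), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(sample_fibers(t, 0, seed = 1), "1")
  expect_error(sample_fibers(t, 101, seed = 1), "1")
})

test_that("sampling within bundles restricts the eligible set", {
  t <- tiny_tract(n_bundles = 2L, n_fibers = 10L)
  names(t$bundles) <- c("A", "B")
  sel <- sample_fibers(t, 100, seed = 0, within = "A")
  expect_identical(sel$indices, t$bundles$A)
  expect_error(sample_fibers(t, 50, seed = 0, within = "C"), "unknown")
})

test_that("bundle selection takes unions and rejects unknown names", {
  t <- tiny_tract(n_bundles = 2L, n_fibers = 10L)
  names(t$bundles) <- c("A", "B")
  expect_identical(select_bundles(t, "A")$indices, 1:5)
  expect_identical(select_bundles(t, c("A", "B"))$indices, 1:10)
  expect_error(select_bundles(t, "C"), "unknown")
  plain <- synth_tractography(3, 0L, 3L, seed = 0)
  expect_error(select_bundles(plain, "A"), "no bundle labels")
})

test_that("bundle palettes are deterministic and pairwise distinct", {
  t <- tiny_tract(n_bundles = 2L)
  expect_identical(assign_bundle_colors(t, seed = 0),
                   assign_bundle_colors(t, seed = 0))
  t100 <- synth_tractography(100, 100L, 3L, seed = 1)
  pal <- assign_bundle_colors(t100, seed = 3)
  expect_length(pal, 100L)
  key <- vapply(pal, paste, "", collapse = ",")
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(unlist(pal) >= 0 & unlist(pal) <= 1))
  # beyond the documented 360-hue limit the operation still succeeds
  tbig <- synth_tractography(400, 361L, 3L, seed = 1)
  expect_length(assign_bundle_colors(tbig, seed = 0), 361L)
})

test_that("equidistant resampling subdivides arc length uniformly", {
  straight <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  r <- resample_fiber_equidistant(straight, 21L)
  expect_equal(r[, 1L], 0:20)
  expect_equal(r[, 2L], rep(0, 21L))

  # right-angle polyline: arc-length walk oracle at 0, 0.5, 1.0, 1.5, 2.0
  bend <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  r5 <- resample_fiber_equidistant(bend, 5L)
  expect_equal(r5, rbind(c(0, 0, 0), c(0.5, 0, 0), c(1, 0, 0),
                         c(1, 0.5, 0), c(1, 1, 0)))

  # fixed point: resampling an already-equidistant fiber to its own count
  expect_equal(resample_fiber_equidistant(r, 21L), r)

  expect_error(resample_fiber_equidistant(rbind(c(1, 1, 1), c(1, 1, 1)), 5L),
               "zero-length")
})

test_that("resampling preserves endpoints, spacing and total arc length", {
  # oracle: locate each resampled point's arc coordinate on the original
  # polyline by projecting onto its segments
  arc_position <- function(p, f) {
    s <- c(0, cumsum(sqrt(rowSums(diff(f)^2))))
    best <- Inf; pos <- NA_real_
    for (i in seq_len(nrow(f) - 1L)) {
      a <- f[i, ]; b <- f[i + 1L, ]
      ab <- b - a; L2 <- sum(ab^2)
      tt <- if (L2 == 0) 0 else min(1, max(0, sum((p - a) * ab) / L2))
      d <- sqrt(sum((a + tt * ab - p)^2))
      if (d < best) { best <- d; pos <- s[i] + tt * sqrt(L2) }
    }
    expect_lt(best, 1e-8)   # point lies on the original polyline
    pos
  }
  t <- tiny_tract(n_fibers = 5L, points = 12L, seed = 7)
  for (f in t$fibers) {
    r <- resample_fiber_equidistant(f, 21L)
    expect_equal(r[1L, ], f[1L, ])
    expect_equal(r[21L, ], f[nrow(f), ])
    pos <- vapply(seq_len(21L), function(i) arc_position(r[i, ], f),
                  numeric(1))
    spacings <- diff(pos)
    expect_lt(max(abs(spacings - mean(spacings))) / mean(spacings), 1e-6)
    # dense resampling preserves the total chord-sum arc length
    dense <- resample_fiber_equidistant(f, 200L)
    len0 <- sum(sqrt(rowSums(diff(f)^2)))
    expect_equal(sum(sqrt(rowSums(diff(dense)^2))), len0, tolerance = 1e-4)
  }
})

test_that("segment directions follow the next-segment rule", {
  straight <- rbind(c(0, 0, 0), c(5, 0, 0), c(9, 0, 0))
  expect_equal(fiber_segment_directions(straight),
               matrix(rep(c(1, 0, 0), each = 3L), 3L))
  two <- rbind(c(0, 0, 0), c(0, 3, 4))
  expect_equal(fiber_segment_directions(two),
               matrix(rep(c(0, 0.6, 0.8), each = 2L), 2L))
  bend <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(fiber_segment_directions(bend),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0)))
  # zero-length segment inherits the previous non-zero direction
  dup <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(fiber_segment_directions(dup)[2L, ], c(1, 0, 0))
  expect_error(fiber_segment_directions(rbind(c(1, 2, 3), c(1, 2, 3))),
               "coincide")
})

test_that("tube meshes have the expected geometry and watertight walls", {
  two <- rbind(c(0, 0, 0), c(0, 0, 10))
  tube <- fiber_to_tube_mesh(two, radius = 1, n_sides = 6L)
  expect_equal(nrow(tube$vertices), 12L)
  expect_equal(nrow(tube$triangles), 12L)
  # straight tube along z: every vertex at distance 1 from the z axis
  expect_equal(sqrt(rowSums(tube$vertices[, 1:2]^2)), rep(1, 12L))
  # radial unit normals
  expect_equal(sqrt(rowSums(tube$normals^2)), rep(1, 12L))
  expect_error(fiber_to_tube_mesh(two, radius = 1, n_sides = 2L), "n_sides")

  # interior edges shared by exactly 2 triangles on a longer bent fiber
  bent <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(10, 10, 10))
  tb <- fiber_to_tube_mesh(bent, radius = 0.5, n_sides = 5L)
  tr <- tb$triangles
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  counts <- table(key)
  # boundary edges (first and last ring) appear once; all others twice
  expect_true(all(counts %in% c(1L, 2L)))
  expect_equal(sum(counts == 1L), 2L * 5L)
})
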