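test_that("Phong closed forms hold", {
  n <- c(0, 0, 1)
  # ambient-only: I = K_a * L_a regardless of geometry
  lp <- lighting_params(1, 0, 0, light_dir = c(0, 0, 1))
  mat <- material(K_a = 1, K_d = 0, K_s = 0)
  for (v in list(c(0, 0, 1), c(1, 0, 0), c(0, 0.6, 0.8)))
    expect_equal(phong_intensity(lp, mat, n, v), 1)

  # fully aligned unit configuration: all three terms contribute 1
  lp1 <- lighting_params(1, 1, 1, light_dir = c(0, 0, 1))
  mat1 <- material(K_a = 1, K_d = 1, K_s = 1, f = 1)
  expect_equal(phong_intensity(lp1, mat1, n, c(0, 0, 1)), 3)

  # light orthogonal to the normal: diffuse and specular vanish
  lp2 <- lighting_params(0.5, 1, 1, light_dir = c(1, 0, 0))
  mat2 <- material(K_a = 0.5, K_d = 1, K_s = 1, f = 2)
  expect_equal(phong_intensity(lp2, mat2, n, c(0, 0, 1)), 0.25)

  # light behind the surface: specular gated off, intensity never negative
  lp3 <- lighting_params(0, 1, 1, light_dir = c(0, 0, -1))
  expect_equal(phong_intensity(lp3, mat1, n, c(0, 0, 1)), 0)

  expect_error(phong_intensity(lp1, mat1, c(0, 0, 2), c(0, 0, 1)), "unit")
})

test_that("over-compositing satisfies its identities and arithmetic", {
  f <- c(0.2, 0.4, 0.6, 1)
  b <- c(0.9, 0.1, 0.3, 0.7)
  expect_equal(composite_over(f, b), f)                    # opaque front
  expect_equal(composite_over(c(0, 0, 0, 0), b), b)        # clear front
  expect_equal(composite_over(c(1, 0, 0, 0.5), c(0, 0, 1, 1)),
               c(0.5, 0, 0.5, 1))
  # alpha-channel associativity
  a1 <- c(0.3, 0.3, 0.3, 0.4); a2 <- c(0.6, 0.2, 0.1, 0.5)
  a3 <- c(0.1, 0.9, 0.5, 0.8)
  left <- composite_over(composite_over(a1, a2), a3)
  right <- composite_over(a1, composite_over(a2, a3))
  expect_equal(left[4], right[4], tolerance = 1e-12)
})

test_that("projection centers the focus and mirrors symmetric points", {
  cam <- make_camera(c(0, 0, 0), 50)
  pr <- project_point(c(0, 0, 0), cam, 64, 64)
  expect_equal(c(pr$px, pr$py), c(32, 32), tolerance = 1e-9)
  expect_equal(pr$depth, 50)
  expect_false(pr$behind)
  sym <- project_point(rbind(c(-5, 0, 0), c(5, 0, 0)), cam, 64, 64)
  expect_equal(sym$px[1] - 32, 32 - sym$px[2], tolerance = 1e-9)
  expect_equal(sym$py[1], sym$py[2], tolerance = 1e-9)
  behind <- project_point(c(0, 0, 100), cam, 64, 64)
  expect_true(behind$behind)
  expect_error(project_point(camera_eye(cam), cam, 64, 64), "eye")
})

test_that("an empty scene renders as pure background", {
  img <- render_scene(scene(background = c(0, 0, 0)), make_camera(r = 10),
                      32, 16)
  expect_equal(dim(img$pixels), c(16L, 32L, 4L))
  expect_equal(max(abs(img$pixels[, , 1:3])), 0)
  expect_equal(min(img$pixels[, , 4]), 1)
  blue <- render_scene(scene(background = c(0, 0, 1)), make_camera(r = 10),
                       8, 8)
  expect_equal(mean(blue$pixels[, , 3]), 1)
  expect_error(render_scene(scene(), make_camera(r = 10), 0, 8), "size")
})

test_that("a single line fiber lights exactly the Bresenham pixels", {
  f <- rbind(c(-20, -10, 0), c(25, 15, 0))
  t <- tractography(list(f))
  # ambient-only white: shading cannot darken any pixel
  sc <- scene(scene_tractography(t, mat = material(K_a = 1, K_d = 0, K_s = 0)),
              lighting = lighting_params(1, 0, 0),
              background = c(0, 0, 0))
  cam <- make_camera(c(0, 0, 0), 100)
  img <- render_scene(sc, cam, 64, 64)
  lit <- which(img$pixels[, , 1] > 0, arr.ind = TRUE)
  got <- cbind(x = lit[, 2] - 1L, y = lit[, 1] - 1L)

  pr <- project_point(f, cam, 64, 64)
  expected <- bresenham_oracle(floor(pr$px[1]), floor(pr$py[1]),
                               floor(pr$px[2]), floor(pr$py[2]))
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(got), key(expected))
  expect_equal(max(img$pixels[, , 1:3][img$pixels[, , 1:3] > 0]), 1)
})

test_that("opaque triangles obey the over arithmetic against the background", {
  sq <- square_mesh()
  sq$vertices <- (sq$vertices - 0.5) * 40   # cover the image center
  cam <- make_camera(c(0, 0, 0), 60)
  base <- list(lighting = lighting_params(1, 0, 0), background = c(1, 1, 1))
  mk <- function(alpha)
    scene(scene_mesh(sq, mat = material(K_a = 1, K_d = 0, K_s = 0,
                                        base_color = c(1, 0, 0),
                                        alpha = alpha)),
          lighting = base$lighting, background = base$background)
  opaque <- render_scene(mk(1), cam, 33, 33)
  expect_equal(as.numeric(opaque$pixels[17, 17, 1:3]), c(1, 0, 0))
  half <- render_scene(mk(0.5), cam, 33, 33)
  expect_equal(as.numeric(half$pixels[17, 17, 1:3]), c(1, 0.5, 0.5))
})

test_that("the nearer of two opaque objects owns every contested pixel", {
  near <- square_mesh(z = 10); far <- square_mesh(z = -10)
  near$vertices[, 1:2] <- (near$vertices[, 1:2] - 0.5) * 30
  far$vertices[, 1:2] <- (far$vertices[, 1:2] - 0.5) * 30
  amb <- function(col) material(K_a = 1, K_d = 0, K_s = 0, base_color = col)
  cam <- make_camera(c(0, 0, 0), 100)
  img <- render_scene(
    scene(scene_mesh(far, mat = amb(c(1, 0, 0))),
          scene_mesh(near, mat = amb(c(0, 1, 0))),
          lighting = lighting_params(1, 0, 0)),
    cam, 32, 32)
  reds <- img$pixels[, , 1] > 0 & img$pixels[, , 2] == 0
  greens <- img$pixels[, , 2] > 0
  # the near (green) quad projects larger and must blanket the far quad
  expect_gt(sum(greens), 0)
  expect_equal(sum(reds & greens), 0)
  expect_equal(sum(reds), 0)   # far quad fully occluded here
})

test_that("renders are bitwise deterministic and sampling at 100% is exact", {
  t <- tiny_tract(n_fibers = 30L)
  v <- synth_volume_two_class(dims = c(12L, 12L, 12L), seed = 4)
  sc <- scene(scene_tractography(t, percent = 100, seed = 7),
              scene_volume(v, slices = list(list(axis = "z", index = 6L)),
                           volume_render = TRUE, alpha = 0.6))
  cam <- make_camera(c(50, 50, 50), 220, 0.4, 0.6)
  img1 <- render_scene(sc, cam, 48, 48)
  img2 <- render_scene(sc, cam, 48, 48)
  expect_identical(img1$pixels, img2$pixels)

  # percent = 100 renders independently of the sampling seed (full set)
  plain <- synth_tractography(15L, 0L, 6L, seed = 2)
  sc100 <- scene(scene_tractography(plain, percent = 100, seed = 99))
  scall <- scene(scene_tractography(plain, percent = 100, seed = 7))
  expect_identical(render_scene(sc100, cam, 32, 32)$pixels,
                   render_scene(scall, cam, 32, 32)$pixels)
})

test_that("ambient-only object color is invariant to camera orbits", {
  m <- synth_icosphere(1)
  m$vertices <- m$vertices * 10
  sc <- scene(scene_mesh(m, mat = material(K_a = 1, K_d = 0, K_s = 0,
                                           base_color = c(0.2, 0.7, 0.4))),
              lighting = lighting_params(1, 0, 0))
  set.seed(3)
  for (i in 1:4) {
    cam <- make_camera(c(0, 0, 0), 50, runif(1, -pi, pi), runif(1, -pi, pi))
    img <- render_scene(sc, cam, 24, 24)
    hit <- img$pixels[, , 1] > 0
    expect_gt(sum(hit), 0)
    expect_equal(unique(round(img$pixels[, , 1][hit], 10)), 0.2)
    expect_equal(unique(round(img$pixels[, , 2][hit], 10)), 0.7)
  }
})

test_that("volume rendering draws only above the Otsu gate", {
  v <- synth_volume_two_class(dims = c(12L, 12L, 12L), means = c(200, 10),
                              sds = c(1, 1), seed = 6)
  sc <- scene(scene_volume(v, volume_render = TRUE, alpha = 1),
              background = c(0, 0, 0))
  cam <- make_camera((dim(v$data) - 1) / 2, 60, 0.3, 0.4)
  img <- render_scene(sc, cam, 40, 40)
  hit <- img$pixels[, , 1] > 0
  expect_gt(sum(hit), 0)
  # the bright ellipsoid is centered: the image corner stays background
  expect_equal(as.numeric(img$pixels[1, 1, 1:3]), c(0, 0, 0))
})

test_that("PNG export round-trips pixel data", {
  img <- render_scene(scene(background = c(0.25, 0.5, 0.75)),
                      make_camera(r = 10), 8, 8)
  path <- file.path(withr::local_tempdir(), "x.png")
  save_png(img, path)
  back <- png::readPNG(path)
  expect_equal(back[, , 1:3], img$pixels[, , 1:3], tolerance = 1 / 255)
})
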