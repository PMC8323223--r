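# Software rasterizer. Everything a GPU pipeline would do in shaders is done
# here as plain array passes: opaque geometry (axis slices, opaque meshes,
# fiber lines/tubes) with a depth buffer, then transparent geometry (volume
# slice stacks far-to-near, transparent meshes back-to-front) composited with
# the "over" operator.

#' Lighting parameters
#'
#' Global light components for the Phong model. `light_dir` points from the
#' surface toward the light; `NULL` selects a headlight (light shining along
#' the camera view direction).
#'
#' @param L_a,L_d,L_s ambient, diffuse and specular light components in
#'   `[0, 1]`.
#' @param light_dir unit length-3 vector toward the light, or `NULL`.
#' @return An object of class `lighting_params`.
#' @export
lighting_params <- function(L_a = 0.5, L_d = 0.5, L_s = 0.3,
                            light_dir = NULL) {
  for (v in c(L_a, L_d, L_s))
    if (!is_scalar_num(v) || v < 0 || v > 1)
      stopf("light components must lie in [0, 1]")
  if (!is.null(light_dir)) light_dir <- normalize3(as.numeric(light_dir))
  structure(list(L_a = L_a, L_d = L_d, L_s = L_s, light_dir = light_dir),
            class = "lighting_params")
}

#' Material reflection constants
#'
#' @param K_a,K_d,K_s ambient, diffuse and specular reflection constants in
#'   `[0, 1]`.
#' @param f shininess coefficient, `>= 0`.
#' @param base_color RGB triple in `[0, 1]`.
#' @param alpha opacity in `[0, 1]`.
#' @return An object of class `material`.
#' @export
material <- function(K_a = 0.5, K_d = 0.5, K_s = 0.3, f = 8,
                     base_color = c(1, 1, 1), alpha = 1) {
  for (v in c(K_a, K_d, K_s))
    if (!is_scalar_num(v) || v < 0 || v > 1)
      stopf("reflection constants must lie in [0, 1]")
  if (!is_scalar_num(f) || f < 0) stopf("shininess must be >= 0")
  if (!is_scalar_num(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must lie in [0, 1]")
  structure(list(K_a = K_a, K_d = K_d, K_s = K_s, f = f,
                 base_color = as.numeric(base_color), alpha = alpha),
            class = "material")
}

#' Phong illumination at a surface point
#'
#' `I = L_a K_a + L_d K_d max(0, s.n) + L_s K_s max(0, r.v)^f`, where `s` is
#' the unit direction toward the light, `n` the unit surface normal, `v` the
#' unit direction toward the viewer and `r` the reflection of `s` about `n`.
#' Negative dot products are clamped to zero and the specular term is gated
#' off when the light is behind the surface (`s.n <= 0`), so `I >= 0` always.
#'
#' @param lp a [lighting_params()] with a non-`NULL` `light_dir`.
#' @param mat a [material()].
#' @param n unit surface normal.
#' @param v unit direction toward the viewer.
#' @return Scalar illumination `I`.
#' @export
phong_intensity <- function(lp, mat, n, v) {
  stopifnot(inherits(lp, "lighting_params"), inherits(mat, "material"))
  if (is.null(lp$light_dir))
    stopf("phong_intensity needs an explicit light direction")
  for (vec in list(n, v, lp$light_dir))
    if (abs(vnorm(vec) - 1) > 1e-6)
      stopf("phong vectors must be unit length (within 1e-6)")
  s <- lp$light_dir
  sn <- sum(s * n)
  diffuse <- lp$L_d * mat$K_d * max(0, sn)
  specular <- 0
  if (sn > 0) {
    r <- 2 * sn * n - s
    specular <- lp$L_s * mat$K_s * max(0, sum(r * v))^mat$f
  }
  lp$L_a * mat$K_a + diffuse + specular
}

# Vectorized Phong over rows of unit normals N and view vectors V.
phong_rows <- function(lp, mat, N, V, s) {
  sn <- N[, 1] * s[1] + N[, 2] * s[2] + N[, 3] * s[3]
  snc <- pmax(0, sn)
  R <- 2 * sn * N - matrix(s, nrow(N), 3L, byrow = TRUE)
  rv <- pmax(0, rowSums(R * V))
  spec <- ifelse(sn > 0, lp$L_s * mat$K_s * rv^mat$f, 0)
  lp$L_a * mat$K_a + lp$L_d * mat$K_d * snc + spec
}

#' Composite one RGBA sample over another
#'
#' Standard non-premultiplied "over": `alpha = a_f + (1 - a_f) a_b` and
#' `C = (a_f C_f + (1 - a_f) a_b C_b) / alpha` (color left black when the
#' result is fully transparent).
#'
#' @param front,back length-4 RGBA vectors, channels in `[0, 1]`.
#' @return Length-4 RGBA vector.
#' @export
composite_over <- function(front, back) {
  af <- front[4L]; ab <- back[4L]
  a <- af + (1 - af) * ab
  if (a <= 0) return(c(0, 0, 0, 0))
  c((af * front[1:3] + (1 - af) * ab * back[1:3]) / a, a)
}

#' Project world points to pixel coordinates
#'
#' Perspective projection with a vertical field of view `fov` and aspect
#' ratio `width / height`. Pixel coordinates are continuous with the origin
#' at the top-left corner; `depth` is the positive camera-space distance
#' along the view axis, and points at or behind the eye plane are flagged.
#'
#' @param p length-3 point or n x 3 matrix of world points.
#' @param c a [make_camera()] pose.
#' @param width,height image size in pixels.
#' @param fov vertical field of view in degrees (default 45).
#' @return List with `px`, `py`, `depth`, `behind` (one entry per point).
#' @export
project_point <- function(p, c, width, height, fov = 45) {
  if (!is.matrix(p)) p <- matrix(p, ncol = 3L)
  vm <- view_matrix(c)
  cam <- cbind(p, 1) %*% t(vm)
  depth <- -cam[, 3L]
  if (any(abs(cam[, 1L]) < 1e-12 & abs(cam[, 2L]) < 1e-12 & abs(depth) < 1e-12))
    stopf("cannot project a point located at the eye")
  fscale <- 1 / tan(fov * pi / 360)
  aspect <- width / height
  safe <- ifelse(abs(depth) < 1e-12, 1e-12, depth)
  ndc_x <- (fscale / aspect) * cam[, 1L] / safe
  ndc_y <- fscale * cam[, 2L] / safe
  list(px = (ndc_x + 1) / 2 * width,
       py = (1 - ndc_y) / 2 * height,
       depth = depth,
       behind = depth <= 1e-9)
}

#' Integer Bresenham line walk
#'
#' All integer pixel positions on the Bresenham segment between two integer
#' endpoints, endpoints included.
#'
#' @param x0,y0,x1,y1 integer endpoints.
#' @return Two-column integer matrix of (x, y) pixels.
#' @export
bresenham_line <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  out <- matrix(0L, dx - dy + 1L, 2L)
  i <- 0L
  x <- as.integer(x0); y <- as.integer(y0)
  repeat {
    i <- i + 1L
    out[i, ] <- c(x, y)
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out[seq_len(i), , drop = FALSE]
}

# ---- scene -----------------------------------------------------------------

#' Scene display objects
#'
#' Constructors for the display objects a [scene()] can hold. A tractography
#' can be drawn as `"lines"` (Phong-lit with segment-direction
#' pseudo-normals) or `"cylinders"` (true tube meshes); a volume as any
#' combination of axis slices and a slice-stack volume rendering gated by its
#' Otsu threshold; a mesh with optional wireframe and transparency.
#'
#' @param t,v,m the underlying [tractography()], [brain_volume()] or
#'   [tri_mesh()].
#' @param percent fiber sampling percentage in `[1, 100]`.
#' @param seed sampling / palette seed.
#' @param bundles optional character vector restricting display to named
#'   bundles.
#' @param mode `"lines"` or `"cylinders"`.
#' @param color base RGB for unlabeled tractographies.
#' @param radius,n_sides tube geometry for `"cylinders"` mode.
#' @param mat a [material()].
#' @param slices list of `list(axis =, index =)` axis slices to draw.
#' @param volume_render logical: draw the slice-stack volume rendering.
#' @param sf slicing sampling factor (see [plan_view_slices()]).
#' @param alpha volume-rendering opacity in `[0, 1]`.
#' @param wireframe logical: draw triangle edges.
#' @param wire_color RGB for wireframe edges.
#' @return A scene-object list; pass these to [scene()].
#' @name scene-objects
NULL

#' @rdname scene-objects
#' @export
scene_tractography <- function(t, percent = 100, seed = 0L, bundles = NULL,
                               mode = c("lines", "cylinders"),
                               color = c(1, 1, 1), radius = 0.3, n_sides = 6L,
                               mat = material()) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "tractography"))
  list(kind = "tractography", data = t, percent = percent, seed = seed,
       bundles = bundles, mode = mode, color = as.numeric(color),
       radius = radius, n_sides = as.integer(n_sides), material = mat)
}

#' @rdname scene-objects
#' @export
scene_volume <- function(v, slices = list(), volume_render = FALSE, sf = 0.2,
                         alpha = 0.5, mat = material()) {
  stopifnot(inherits(v, "brain_volume"))
  list(kind = "volume", data = v, slices = slices,
       volume_render = isTRUE(volume_render), sf = sf, alpha = alpha,
       material = mat)
}

#' @rdname scene-objects
#' @export
scene_mesh <- function(m, mat = material(), wireframe = FALSE,
                       wire_color = c(1, 1, 1)) {
  stopifnot(inherits(m, "tri_mesh"))
  list(kind = "mesh", data = m, material = mat, wireframe = isTRUE(wireframe),
       wire_color = as.numeric(wire_color))
}

#' Assemble a renderable scene
#'
#' @param ... display objects from [scene_tractography()], [scene_volume()],
#'   [scene_mesh()].
#' @param lighting a [lighting_params()].
#' @param background RGB background color.
#' @return An object of class `scene`.
#' @export
scene <- function(..., lighting = lighting_params(),
                  background = c(0, 0, 0)) {
  objects <- list(...)
  for (o in objects)
    if (!is.list(o) || is.null(o$kind)) stopf("invalid scene object")
  structure(list(objects = objects, lighting = lighting,
                 background = as.numeric(background)),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  kinds <- vapply(x$objects, `[[`, "", "kind")
  cat(sprintf("<scene> %d object(s): %s\n", length(kinds),
              paste(kinds, collapse = ", ")))
  invisible(x)
}

# ---- frame buffer ----------------------------------------------------------

new_framebuffer <- function(width, height, background) {
  ch <- function(v) matrix(v, height, width)
  list(R = ch(background[1]), G = ch(background[2]), B = ch(background[3]),
       A = ch(1), depth = ch(Inf), width = width, height = height)
}

fb_to_image <- function(fb) {
  img <- array(0, c(fb$height, fb$width, 4L))
  img[, , 1] <- clamp(fb$R, 0, 1); img[, , 2] <- clamp(fb$G, 0, 1)
  img[, , 3] <- clamp(fb$B, 0, 1); img[, , 4] <- clamp(fb$A, 0, 1)
  structure(list(pixels = img, depth = fb$depth), class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d RGBA\n", d[2], d[1]))
  invisible(x)
}

#' Save a rendered image as PNG
#'
#' @param img a `raster_image` from [render_scene()].
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(img$pixels, path)
  invisible(path)
}

# Fragments: parallel vectors of column ix (0-based), row iy (0-based),
# depth, r, g, b, a. Writers clip to the image beforehand.

fb_write_opaque <- function(fb, ix, iy, depth, r, g, b) {
  keep <- ix >= 0L & ix < fb$width & iy >= 0L & iy < fb$height & depth > 0
  if (!any(keep)) return(fb)
  ix <- ix[keep]; iy <- iy[keep]; depth <- depth[keep]
  r <- r[keep]; g <- g[keep]; b <- b[keep]
  idx <- iy + 1L + ix * fb$height
  pass <- depth < fb$depth[idx]
  if (!any(pass)) return(fb)
  idx <- idx[pass]; depth <- depth[pass]
  r <- r[pass]; g <- g[pass]; b <- b[pass]
  # farthest first so the nearest fragment wins on duplicate pixels
  o <- order(-depth)
  idx <- idx[o]
  fb$R[idx] <- r[o]; fb$G[idx] <- g[o]; fb$B[idx] <- b[o]
  fb$A[idx] <- 1; fb$depth[idx] <- depth[o]
  fb
}

fb_composite <- function(fb, ix, iy, depth, r, g, b, a) {
  keep <- ix >= 0L & ix < fb$width & iy >= 0L & iy < fb$height & depth > 0 &
    a > 0
  if (!any(keep)) return(fb)
  ix <- ix[keep]; iy <- iy[keep]; depth <- depth[keep]
  r <- r[keep]; g <- g[keep]; b <- b[keep]; a <- a[keep]
  idx <- iy + 1L + ix * fb$height
  pass <- depth < fb$depth[idx]
  if (!any(pass)) return(fb)
  idx <- idx[pass]; r <- r[pass]; g <- g[pass]; b <- b[pass]; a <- a[pass]
  ab <- fb$A[idx]
  an <- a + (1 - a) * ab
  safe <- ifelse(an > 0, an, 1)
  fb$R[idx] <- (a * r + (1 - a) * ab * fb$R[idx]) / safe
  fb$G[idx] <- (a * g + (1 - a) * ab * fb$G[idx]) / safe
  fb$B[idx] <- (a * b + (1 - a) * ab * fb$B[idx]) / safe
  fb$A[idx] <- an
  fb
}

# Rasterize one screen triangle with perspective-correct attribute
# interpolation. px/py/depth are length 3; attrs is a 3 x k matrix of
# per-vertex attributes. Returns NULL or list(ix, iy, depth, attrs).
raster_triangle <- function(px, py, depth, attrs, width, height) {
  if (any(depth <= 1e-9)) return(NULL)   # near-plane clip: skip
  xmin <- max(0L, floor(min(px))); xmax <- min(width - 1L, ceiling(max(px)))
  ymin <- max(0L, floor(min(py))); ymax <- min(height - 1L, ceiling(max(py)))
  if (xmin > xmax || ymin > ymax) return(NULL)
  xs <- seq.int(xmin, xmax); ys <- seq.int(ymin, ymax)
  cx <- rep(xs + 0.5, times = length(ys))
  cy <- rep(ys + 0.5, each = length(xs))
  e <- function(ax, ay, bx, by) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  w0 <- e(px[2], py[2], px[3], py[3])
  w1 <- e(px[3], py[3], px[1], py[1])
  w2 <- e(px[1], py[1], px[2], py[2])
  area <- (px[2] - px[1]) * (py[3] - py[1]) - (py[2] - py[1]) * (px[3] - px[1])
  if (abs(area) < 1e-12) return(NULL)
  inside <- if (area > 0) w0 >= 0 & w1 >= 0 & w2 >= 0
  else w0 <= 0 & w1 <= 0 & w2 <= 0
  if (!any(inside)) return(NULL)
  b0 <- w0[inside] / area; b1 <- w1[inside] / area; b2 <- w2[inside] / area
  inv_d <- b0 / depth[1] + b1 / depth[2] + b2 / depth[3]
  frag_depth <- 1 / inv_d
  interp <- function(a)
    (b0 * a[1] / depth[1] + b1 * a[2] / depth[2] + b2 * a[3] / depth[3]) /
    inv_d
  out_attrs <- apply(attrs, 2L, interp)
  if (sum(inside) == 1L) out_attrs <- matrix(out_attrs, nrow = 1L)
  list(ix = as.integer(cx[inside] - 0.5), iy = as.integer(cy[inside] - 0.5),
       depth = frag_depth, attrs = out_attrs)
}

# ---- render passes ---------------------------------------------------------

#' Render a scene to a raster image
#'
#' Deterministic software rendering: opaque objects (axis slices, opaque
#' meshes, fiber lines and tubes) are rasterized front-most-wins against a
#' depth buffer; transparent objects (volume slice stacks far-to-near,
#' transparent meshes back-to-front) are then composited with the "over"
#' operator, depth-tested against the opaque pass. Fibers take their color
#' from the bundle palette and are Phong-shaded with segment-direction
#' pseudo-normals (lines) or true tube normals (cylinders); volume stacks
#' gate opacity with the volume's Otsu threshold and shade with
#' gradient-based normals.
#'
#' @param s a [scene()].
#' @param c a [make_camera()] pose.
#' @param width,height image size in pixels, `>= 1`.
#' @param fov vertical field of view in degrees.
#' @return A `raster_image` (RGBA pixel array plus depth buffer).
#' @export
render_scene <- function(s, c, width = 256L, height = 256L, fov = 45) {
  stopifnot(inherits(s, "scene"), inherits(c, "camera_pose"))
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stopf("image size must be >= 1 pixel")
  fb <- new_framebuffer(width, height, s$background)
  eye <- camera_eye(c)
  forward <- normalize3(c$center - eye)
  lp <- s$lighting
  if (is.null(lp$light_dir)) lp$light_dir <- -forward   # headlight
  proj <- function(p) project_point(p, c, width, height, fov)

  # opaque pass
  for (obj in s$objects) {
    if (obj$kind == "volume") fb <- draw_axis_slices(fb, obj, proj)
    else if (obj$kind == "mesh" && obj$material$alpha >= 1)
      fb <- draw_mesh(fb, obj$data, obj$material, lp, eye, proj,
                      wireframe = obj$wireframe, wire_color = obj$wire_color)
    else if (obj$kind == "tractography")
      fb <- draw_tractography(fb, obj, lp, eye, proj)
  }
  # transparent pass
  for (obj in s$objects) {
    if (obj$kind == "volume" && obj$volume_render)
      fb <- draw_volume_stack(fb, obj, lp, eye, forward, proj)
    else if (obj$kind == "mesh" && obj$material$alpha < 1)
      fb <- draw_mesh(fb, obj$data, obj$material, lp, eye, proj,
                      transparent = TRUE, wireframe = obj$wireframe,
                      wire_color = obj$wire_color)
  }
  fb_to_image(fb)
}

# Line fragments for one polyline: Bresenham per segment with linear depth
# and color interpolation along the walked pixels.
polyline_fragments <- function(pr, cols) {
  n <- length(pr$px)
  ix <- iy <- integer(0); dep <- r <- g <- b <- numeric(0)
  for (i in seq_len(n - 1L)) {
    if (pr$behind[i] || pr$behind[i + 1L]) next
    p0 <- c(floor(pr$px[i]), floor(pr$py[i]))
    p1 <- c(floor(pr$px[i + 1L]), floor(pr$py[i + 1L]))
    pix <- bresenham_line(p0[1], p0[2], p1[1], p1[2])
    k <- nrow(pix)
    tt <- if (k == 1L) 0 else (seq_len(k) - 1L) / (k - 1L)
    ix <- c(ix, pix[, 1L]); iy <- c(iy, pix[, 2L])
    dep <- c(dep, (1 - tt) * pr$depth[i] + tt * pr$depth[i + 1L])
    r <- c(r, (1 - tt) * cols[i, 1L] + tt * cols[i + 1L, 1L])
    g <- c(g, (1 - tt) * cols[i, 2L] + tt * cols[i + 1L, 2L])
    b <- c(b, (1 - tt) * cols[i, 3L] + tt * cols[i + 1L, 3L])
  }
  list(ix = ix, iy = iy, depth = dep, r = r, g = g, b = b)
}

draw_tractography <- function(fb, obj, lp, eye, proj) {
  t <- obj$data
  sel <- sample_fibers(t, obj$percent, obj$seed, within = obj$bundles)
  palette <- NULL
  fiber_bundle <- rep(NA_integer_, n_fibers(t))
  if (length(t$bundles)) {
    palette <- assign_bundle_colors(t, obj$seed)
    for (bi in seq_along(t$bundles)) fiber_bundle[t$bundles[[bi]]] <- bi
  }
  for (fi in sel$indices) {
    f <- t$fibers[[fi]]
    col <- if (is.null(palette)) obj$color else palette[[fiber_bundle[fi]]]
    if (obj$mode == "lines") {
      dirs <- fiber_segment_directions(f)
      vvec <- -sweep(f, 2L, eye, `-`)
      vvec <- vvec / row_norms(vvec)
      I <- phong_rows(lp, obj$material, dirs, vvec, lp$light_dir)
      cols <- clamp(outer(I, col), 0, 1)
      pr <- proj(f)
      fr <- polyline_fragments(pr, cols)
      fb <- fb_write_opaque(fb, fr$ix, fr$iy, fr$depth, fr$r, fr$g, fr$b)
    } else {
      tube <- fiber_to_tube_mesh(f, radius = obj$radius,
                                 n_sides = obj$n_sides)
      mat <- obj$material
      mat$base_color <- col
      fb <- draw_mesh(fb, tube, mat, lp, eye, proj)
    }
  }
  fb
}

draw_mesh <- function(fb, m, mat, lp, eye, proj, transparent = FALSE,
                      wireframe = FALSE, wire_color = c(1, 1, 1)) {
  m <- compute_vertex_normals(m)
  pr <- proj(m$vertices)
  tri_order <- if (transparent) depth_sort_triangles(m, eye)$order
  else seq_len(nrow(m$triangles))
  for (ti in tri_order) {
    vid <- m$triangles[ti, ]
    if (any(pr$behind[vid])) next
    rt <- raster_triangle(pr$px[vid], pr$py[vid], pr$depth[vid],
                          cbind(m$vertices[vid, , drop = FALSE],
                                m$normals[vid, , drop = FALSE]),
                          fb$width, fb$height)
    if (is.null(rt)) next
    wpos <- rt$attrs[, 1:3, drop = FALSE]
    nrm <- rt$attrs[, 4:6, drop = FALSE]
    len <- row_norms(nrm)
    nrm <- nrm / ifelse(len > 0, len, 1)
    vvec <- -sweep(wpos, 2L, eye, `-`)
    vvec <- vvec / row_norms(vvec)
    flip <- rowSums(nrm * vvec) < 0    # two-sided shading
    nrm[flip, ] <- -nrm[flip, , drop = FALSE]
    I <- phong_rows(lp, mat, nrm, vvec, lp$light_dir)
    col <- clamp(outer(I, mat$base_color), 0, 1)
    if (transparent)
      fb <- fb_composite(fb, rt$ix, rt$iy, rt$depth,
                         col[, 1], col[, 2], col[, 3],
                         rep(mat$alpha, length(rt$ix)))
    else
      fb <- fb_write_opaque(fb, rt$ix, rt$iy, rt$depth,
                            col[, 1], col[, 2], col[, 3])
  }
  if (wireframe) {
    edges <- extract_wireframe_edges(m)
    for (ei in seq_len(nrow(edges))) {
      vid <- edges[ei, ]
      if (any(pr$behind[vid])) next
      seg <- list(px = pr$px[vid], py = pr$py[vid],
                  depth = pr$depth[vid] * 0.999,  # bias over the faces
                  behind = pr$behind[vid])
      cols <- rbind(wire_color, wire_color)
      fr <- polyline_fragments(seg, cols)
      fb <- fb_write_opaque(fb, fr$ix, fr$iy, fr$depth, fr$r, fr$g, fr$b)
    }
  }
  fb
}

draw_axis_slices <- function(fb, obj, proj) {
  v <- obj$data
  rng <- range(v$data)
  for (sl in obj$slices) {
    slice <- extract_axis_slice(v, sl$axis, sl$index)
    pl <- slice$world_plane
    img <- if (rng[1] == rng[2]) slice$image * 0
    else (slice$image - rng[1]) / (rng[2] - rng[1])
    corners <- rbind(pl$origin,
                     pl$origin + pl$u * pl$width,
                     pl$origin + pl$u * pl$width + pl$v * pl$height,
                     pl$origin + pl$v * pl$height)
    uv <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    pr <- proj(corners)
    if (any(pr$behind)) next
    for (tri in list(c(1L, 2L, 3L), c(1L, 3L, 4L))) {
      rt <- raster_triangle(pr$px[tri], pr$py[tri], pr$depth[tri],
                            uv[tri, , drop = FALSE], fb$width, fb$height)
      if (is.null(rt)) next
      iu <- clamp(ceiling(rt$attrs[, 1L] * nrow(img)), 1L, nrow(img))
      iv <- clamp(ceiling(rt$attrs[, 2L] * ncol(img)), 1L, ncol(img))
      val <- img[cbind(iu, iv)]
      fb <- fb_write_opaque(fb, rt$ix, rt$iy, rt$depth, val, val, val)
    }
  }
  fb
}

draw_volume_stack <- function(fb, obj, lp, eye, forward, proj) {
  v <- obj$data
  plan <- plan_view_slices(v, view_dir = forward, sf = obj$sf)
  thr <- otsu_threshold(v)
  grad <- central_gradient(v)
  d <- dim(v$data)
  rng <- range(v$data)
  alpha_slice <- obj$alpha / plan$n_s
  w <- plan$view_dir
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize3(cross3(w, ref))
  vv <- cross3(w, u)
  corners <- volume_corners(v)
  ctr <- colMeans(corners)
  rel <- sweep(corners, 2L, ctr, `-`)
  half_u <- max(abs(rel %*% u)); half_v <- max(abs(rel %*% vv))
  inv_affine <- solve(v$affine)
  for (off in plan$offsets) {
    pc <- ctr + (off - sum(ctr * w)) * w
    quad <- rbind(pc - half_u * u - half_v * vv,
                  pc + half_u * u - half_v * vv,
                  pc + half_u * u + half_v * vv,
                  pc - half_u * u + half_v * vv)
    pr <- proj(quad)
    if (any(pr$behind)) next
    for (tri in list(c(1L, 2L, 3L), c(1L, 3L, 4L))) {
      rt <- raster_triangle(pr$px[tri], pr$py[tri], pr$depth[tri],
                            quad[tri, , drop = FALSE], fb$width, fb$height)
      if (is.null(rt)) next
      wpos <- rt$attrs
      vox <- cbind(wpos, 1) %*% t(inv_affine)
      i <- as.integer(round(vox[, 1])); j <- as.integer(round(vox[, 2]))
      k <- as.integer(round(vox[, 3]))
      ok <- i >= 0L & i < d[1] & j >= 0L & j < d[2] & k >= 0L & k < d[3]
      if (!any(ok)) next
      lin <- cbind(i[ok] + 1L, j[ok] + 1L, k[ok] + 1L)
      val <- v$data[lin]
      vis <- val >= thr                 # Otsu opacity gate
      if (!any(vis)) next
      sel <- which(ok)[vis]
      lin <- lin[vis, , drop = FALSE]
      N <- cbind(grad[cbind(lin, 1L)], grad[cbind(lin, 2L)],
                 grad[cbind(lin, 3L)])
      len <- row_norms(N)
      N <- N / ifelse(len > 1e-12, len, 1)
      zero <- len <= 1e-12
      if (any(zero)) N[zero, ] <- matrix(-w, sum(zero), 3L, byrow = TRUE)
      vvec <- -sweep(wpos[sel, , drop = FALSE], 2L, eye, `-`)
      vvec <- vvec / row_norms(vvec)
      flip <- rowSums(N * vvec) < 0
      N[flip, ] <- -N[flip, , drop = FALSE]
      I <- phong_rows(lp, obj$material, N, vvec, lp$light_dir)
      shade <- if (rng[1] == rng[2]) val[vis] * 0
      else (val[vis] - rng[1]) / (rng[2] - rng[1])
      col <- clamp(outer(I, obj$material$base_color) *
                     cbind(shade, shade, shade), 0, 1)
      fb <- fb_composite(fb, rt$ix[sel], rt$iy[sel], rt$depth[sel],
                         col[, 1], col[, 2], col[, 3],
                         rep(alpha_slice, length(sel)))
    }
  }
  fb
}
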