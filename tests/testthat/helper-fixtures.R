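# Small in-code fixtures shared across the suite.

tiny_tract <- function(n_bundles = 2L, n_fibers = 10L, points = 5L,
                       seed = 42L) {
  synth_tractography(n_fibers, n_bundles, points, seed = seed)
}

# straight two-triangle square in the xy-plane, CCW winding facing +z
square_mesh <- function(z = 0) {
  tri_mesh(rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

# independent brute-force Otsu: scan every histogram bin edge, computing the
# between-class variance directly from the raw values
otsu_bruteforce <- function(x, n_bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best_s <- -Inf
  best_t <- NA_real_
  for (k in 2:n_bins) {
    t0 <- edges[k]
    lo <- x[x < t0]; hi <- x[x >= t0]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t0 }
  }
  best_t
}

# independent Bresenham walk (re-derivation, kept separate from the package)
bresenham_oracle <- function(x0, y0, x1, y1) {
  pts <- list()
  dx <- abs(x1 - x0); sx <- ifelse(x0 < x1, 1L, -1L)
  dy <- -abs(y1 - y0); sy <- ifelse(y0 < y1, 1L, -1L)
  err <- dx + dy
  x <- x0; y <- y0
  repeat {
    pts[[length(pts) + 1L]] <- c(x, y)
    if (x == x1 && y == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  do.call(rbind, pts)
}
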