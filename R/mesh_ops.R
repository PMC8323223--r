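# Mesh preparation for rendering: vertex normals, painter's-algorithm depth
# sorting, wireframe extraction.

#' Compute per-vertex normals
#'
#' Per-vertex normals as the normalized area-weighted average of incident
#' face normals (counter-clockwise winding, right-hand rule). Zero-area
#' triangles contribute nothing; vertices with no incident triangle (or a
#' degenerate neighborhood) get `(0, 0, 1)`. A mesh already carrying normals
#' is returned unchanged.
#'
#' @param m a [tri_mesh()].
#' @return The mesh with unit `normals` populated.
#' @export
compute_vertex_normals <- function(m) {
  stopifnot(inherits(m, "tri_mesh"))
  if (!is.null(m$normals)) return(m)
  v <- m$vertices; tr <- m$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  fn <- cross3_rows(e1, e2)   # magnitude = 2 * triangle area
  acc <- rowsum(rbind(fn, fn, fn), group = c(tr[, 1L], tr[, 2L], tr[, 3L]))
  normals <- matrix(0, nrow(v), 3L)
  normals[as.integer(rownames(acc)), ] <- acc
  len <- row_norms(normals)
  degenerate <- len < 1e-12
  normals[degenerate, ] <- rep(c(0, 0, 1), each = sum(degenerate))
  len[degenerate] <- 1
  m$normals <- normals / len
  m
}

#' Depth-sort triangles back to front
#'
#' Orders triangles by descending centroid distance to the eye point (the
#' painter's algorithm used for transparent meshes); the sort is stable, so
#' equal distances keep their original index order.
#'
#' @param m a [tri_mesh()].
#' @param eye length-3 world eye position.
#' @return An object of class `triangle_order`: `order` (a permutation of
#'   triangle indices, farthest first), `distance` (the matching centroid
#'   distances) and `eye`.
#' @export
depth_sort_triangles <- function(m, eye) {
  stopifnot(inherits(m, "tri_mesh"))
  eye <- as.numeric(eye)
  cen <- triangle_centroids(m)
  d2 <- (cen[, 1] - eye[1])^2 + (cen[, 2] - eye[2])^2 + (cen[, 3] - eye[3])^2
  ord <- order(-d2, seq_along(d2))   # ties keep original index order
  structure(list(order = ord, distance = sqrt(d2[ord]), eye = eye),
            class = "triangle_order")
}

triangle_centroids <- function(m) {
  (m$vertices[m$triangles[, 1L], , drop = FALSE] +
     m$vertices[m$triangles[, 2L], , drop = FALSE] +
     m$vertices[m$triangles[, 3L], , drop = FALSE]) / 3
}

#' Extract unique wireframe edges
#'
#' The undirected edge set of all triangles, each edge listed once with its
#' lower vertex index first.
#'
#' @param m a [tri_mesh()].
#' @return Integer matrix with 2 columns of 1-based vertex indices, ordered
#'   lexicographically.
#' @export
extract_wireframe_edges <- function(m) {
  stopifnot(inherits(m, "tri_mesh"))
  tr <- m$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}
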