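#' Triangle mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` matrix of
#' vertex coordinates in millimetres and an `m x 3` matrix of 1-based
#' vertex indices per face.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates (mm).
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param validate check invariants (finite coordinates, index range, no
#'   degenerate faces). Defaults to `TRUE`.
#' @return An object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (validate) {
    stopifnot_finite(vertices, "vertex coordinates")
    if (nrow(faces) > 0) {
      if (max(faces) > nrow(vertices) || min(faces) < 1L)
        cs_abort("face indices out of range", "cranioshape_input_error")
      if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
        cs_abort("faces with repeated vertex indices", "cranioshape_input_error")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Face areas, centroids and normals
#'
#' @param mesh a [triangle_mesh()].
#' @return `face_areas`: numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @return `face_centroids`: `m x 3` matrix of triangle centroids.
#' @export
face_centroids <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @return `face_normals`: `m x 3` matrix of unit face normals (orientation
#'   as stored in the face winding).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.xmin)
}

#' @rdname face_areas
#' @return `vertex_normals`: `n x 3` matrix of area-weighted average unit
#'   vertex normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  idx <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  s <- rowsum(rbind(fn, fn, fn), idx)
  n[as.integer(rownames(s)), ] <- s
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Mesh edge list and vertex adjacency
#'
#' @param mesh a [triangle_mesh()].
#' @return `mesh_edges`: 2-column matrix of unique undirected edges
#'   (1-based, first column < second).
#' @export
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' @keywords internal
#' @noRd
mesh_adjacency_csr <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L))
}

#' @keywords internal
#' @noRd
mesh_boundary_vertices <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_keys <- names(cnt)[cnt == 1L]
  out <- logical(nrow(mesh$vertices))
  if (length(open_keys)) {
    ij <- do.call(rbind, strsplit(open_keys, " ", fixed = TRUE))
    out[as.integer(ij)] <- TRUE
  }
  out
}

#' Per-vertex surface area weights
#'
#' One third of the summed areas of the faces incident to each vertex, so
#' that vertex weights partition the total mesh area.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of length `nrow(mesh$vertices)` (mm^2).
#' @export
vertex_area_weights <- function(mesh) {
  fa <- face_areas(mesh) / 3
  w <- numeric(nrow(mesh$vertices))
  idx <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  s <- rowsum(c(fa, fa, fa), idx)
  w[as.integer(rownames(s))] <- s
  w
}

#' Connected components of a mesh
#'
#' Labels each vertex with the id of its edge-connected component.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer vector of component labels (1-based), with attribute
#'   `n_components`.
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  g <- igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  cm <- igraph::components(g)
  structure(as.integer(cm$membership), n_components = as.integer(cm$no))
}

#' Is every edge of the mesh shared by exactly two faces?
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Signed volume enclosed by a closed, outward-oriented mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return scalar (mm^3); positive when faces wind outwards.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}
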