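#' Ring partition of a vertex neighbourhood
#'
#' Breadth-first rings by edge-graph distance: ring 0 is the centre
#' vertex, ring `k` contains the vertices at graph distance exactly `k`.
#' Near a mesh boundary rings are simply partial.
#'
#' @param mesh a [triangle_mesh()].
#' @param vertex_index 1-based centre vertex.
#' @param n_rings number of rings (default 8).
#' @return An object of class `ring_partition`: list `rings` of integer
#'   vertex-index vectors (ring 0 .. `n_rings`), and `vertex_index`.
#' @export
ring_partition <- function(mesh, vertex_index, n_rings = 8) {
  if (n_rings < 1)
    cs_abort("n_rings must be >= 1", "cranioshape_input_error")
  if (vertex_index < 1 || vertex_index > nrow(mesh$vertices))
    cs_abort("vertex index out of range", "cranioshape_input_error")
  adj <- mesh_adjacency_csr(mesh)
  if (adj$ptr[vertex_index] == adj$ptr[vertex_index + 1L])
    cs_abort("isolated vertex has no rings", "cranioshape_input_error")
  d <- .ring_distances_cpp(adj$ptr, adj$idx, vertex_index - 1L,
                           as.integer(n_rings))
  rings <- lapply(0:n_rings, function(k) which(d == k))
  structure(list(vertex_index = vertex_index, rings = rings,
                 n_rings = as.integer(n_rings)),
            class = "ring_partition")
}

#' Build the curvature map of one vertex
#'
#' Entry `k` summarises ring `k`: the mean Gaussian curvature over the
#' ring's vertices normalised to the surface of the ring (each vertex
#' weighted by one third of its incident face areas), then log-scaled
#' exactly as in [scale_curvature()] with the ring's area-weighted
#' majority orientation sign. Empty rings yield entry 0 and are flagged
#' partial, as are rings touching a mesh boundary.
#'
#' @param mesh a [triangle_mesh()].
#' @param field a [curvature_field()] on `mesh`.
#' @param partition a [ring_partition()] on `mesh`.
#' @return An object of class `curvature_map`: `centre`, numeric
#'   `entries` (length `n_rings + 1`), logical `partial` per ring.
#' @export
build_curvature_map <- function(mesh, field, partition) {
  w <- vertex_area_weights(mesh)
  bnd <- mesh_boundary_vertices(mesh)
  n1 <- partition$n_rings + 1L
  entries <- numeric(n1)
  partial <- logical(n1)
  for (k in seq_len(n1)) {
    ring <- partition$rings[[k]]
    if (!length(ring) || sum(w[ring]) <= 0) {
      partial[k] <- TRUE
      next
    }
    sw <- sum(w[ring])
    kbar <- sum(w[ring] * field$kappa_g[ring]) / sw
    sg <- if (sum(w[ring] * field$orientation_sign[ring]) >= 0) 1 else -1
    rs <- sg / sqrt(max(abs(kbar), field$kappa_min))
    entries[k] <- sign(rs) * log1p(abs(rs))
    partial[k] <- any(bnd[ring])
  }
  structure(list(centre = partition$vertex_index, entries = entries,
                 partial = partial),
            class = "curvature_map")
}

#' L1 distance between curvature maps
#'
#' @param a,b [build_curvature_map()] results (or bare numeric vectors)
#'   of equal length.
#' @return non-negative scalar, `sum(abs(a - b))`.
#' @export
map_distance <- function(a, b) {
  ea <- if (inherits(a, "curvature_map")) a$entries else as.numeric(a)
  eb <- if (inherits(b, "curvature_map")) b$entries else as.numeric(b)
  if (length(ea) != length(eb))
    cs_abort("curvature maps have different lengths", "cranioshape_input_error")
  sum(abs(ea - eb))
}

#' @keywords internal
#' @noRd
all_curvature_maps <- function(mesh, field, n_rings, centres = NULL) {
  adj <- mesh_adjacency_csr(mesh)
  w <- vertex_area_weights(mesh)
  bnd <- mesh_boundary_vertices(mesh)
  if (is.null(centres)) centres <- seq_len(nrow(mesh$vertices))
  res <- .ring_maps_all_cpp(adj$ptr, adj$idx, w, field$kappa_g,
                            as.integer(field$orientation_sign), bnd,
                            as.integer(centres - 1L), as.integer(n_rings),
                            field$kappa_min)
  res
}

#' Locate the best-matching region on a target surface
#'
#' Builds the reference curvature map once, builds a map at every target
#' vertex, and ranks all target vertices by ascending L1 distance. When
#' more than the best match is reported, vertices within
#' `exclusion_rings` graph rings of any better-ranked reported vertex are
#' suppressed (non-maximum suppression), which yields a spatially
#' distinct second-best match. Maps with more than `max_partial_frac`
#' partial rings (mesh rim artefacts) are excluded from the search.
#' Ties are broken by the lower vertex index.
#'
#' @param reference_mesh,reference_field the reference surface and its
#'   [curvature_field()].
#' @param reference_vertex 1-based centre of the reference area.
#' @param target_mesh,target_field the searched surface and its field.
#' @param n_rings ring count (default 8).
#' @param exclusion_rings non-maximum suppression radius in rings
#'   (default 0: report the raw ranking).
#' @param n_report number of matches to report (default 5).
#' @param max_partial_frac exclude target maps with a larger fraction of
#'   partial rings (default 0.3).
#' @return An object of class `match_result`: `ranked` data frame
#'   (`vertex`, `distance`), `reference_centre`, `reference_map`, and the
#'   parameters used.
#' @export
find_matches <- function(reference_mesh, reference_field, reference_vertex,
                         target_mesh, target_field, n_rings = 8,
                         exclusion_rings = 0, n_report = 5,
                         max_partial_frac = 0.3) {
  ref <- all_curvature_maps(reference_mesh, reference_field, n_rings,
                            centres = reference_vertex)
  ref_entries <- as.numeric(ref$entries[1, ])
  tg <- all_curvature_maps(target_mesh, target_field, n_rings)
  partial_frac <- rowMeans(tg$partial)
  eligible <- which(partial_frac <= max_partial_frac)
  if (!length(eligible))
    cs_abort("target mesh is too small (all maps are rim-partial)",
             "cranioshape_input_error")
  d <- rowSums(abs(sweep(tg$entries[eligible, , drop = FALSE], 2,
                         ref_entries)))
  perm <- order(d, eligible)
  ord <- eligible[perm]
  d_sorted <- d[perm]
  if (exclusion_rings > 0) {
    adj <- mesh_adjacency_csr(target_mesh)
    kept <- integer(0)
    kept_d <- numeric(0)
    suppressed <- logical(nrow(tg$entries))
    for (i in seq_along(ord)) {
      v <- ord[i]
      if (suppressed[v]) next
      kept <- c(kept, v)
      kept_d <- c(kept_d, d_sorted[i])
      if (length(kept) >= n_report) break
      dd <- .ring_distances_cpp(adj$ptr, adj$idx, v - 1L,
                                as.integer(exclusion_rings))
      suppressed[dd >= 0L] <- TRUE
    }
    ranked <- data.frame(vertex = kept, distance = kept_d)
  } else {
    take <- seq_len(min(n_report, length(ord)))
    ranked <- data.frame(vertex = ord[take], distance = d_sorted[take])
  }
  structure(list(ranked = ranked, reference_centre = reference_vertex,
                 reference_map = ref_entries, n_rings = as.integer(n_rings),
                 exclusion_rings = as.integer(exclusion_rings)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: reference vertex %d, %d reported matches\n",
              x$reference_centre, nrow(x$ranked)))
  print(utils::head(x$ranked, 5))
  invisible(x)
}

#' Write a match result as JSON
#'
#' Records the reference centre, the ranked `(vertex, distance)` list and
#' the parameters used. Vertex indices are written 0-based for viewer
#' interoperability.
#'
#' @param match a [find_matches()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_result <- function(match, path) {
  jsonlite::write_json(
    list(reference_centre = match$reference_centre - 1L,
         ranked = data.frame(vertex = match$ranked$vertex - 1L,
                             distance = match$ranked$distance),
         n_rings = match$n_rings,
         exclusion_rings = match$exclusion_rings),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Outline of an n-ring region for overlay display
#'
#' The vertex indices of ring `n_rings` around a centre: the border of
#' the matched area, suitable for marking on a rendered mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param vertex_index 1-based centre.
#' @param n_rings ring radius (default 8).
#' @return integer vector of 1-based vertex indices on the region border.
#' @export
region_outline <- function(mesh, vertex_index, n_rings = 8) {
  rp <- ring_partition(mesh, vertex_index, n_rings)
  rp$rings[[n_rings + 1L]]
}
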