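#' Icosphere construction
#'
#' Builds a unit icosphere by repeated 4-to-1 triangle subdivision of a
#' regular icosahedron with re-projection of every new vertex onto the
#' unit sphere. Level `L` has `10 * 4^L + 2` vertices and `20 * 4^L`
#' faces.
#'
#' @param subdivision_level integer >= 0.
#' @return a [triangle_mesh()] with unit-norm vertices and outward faces.
#' @export
icosphere <- function(subdivision_level) {
  if (subdivision_level < 0)
    cs_abort("subdivision level must be >= 0", "cranioshape_input_error")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision_level)) {
    nv <- nrow(V)
    edge_key <- function(a, b) ifelse(a < b, a * (nv + 1) + b, b * (nv + 1) + a)
    mids <- new.env(parent = emptyenv())
    newV <- list()
    midpoint <- function(a, b) {
      key <- as.character(edge_key(a, b))
      id <- mids[[key]]
      if (!is.null(id)) return(id)
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1L]] <<- p
      id <- nv + length(newV)
      mids[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF[(f - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c_, ca, bc), c(ab, bc, ca))
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  triangle_mesh(V, F, validate = FALSE)
}

#' Hemi-icosphere direction set for raycast resampling
#'
#' The fixed set of ray directions on which registered skulls are
#' resampled. A full icosphere is built at the requested subdivision
#' level; the superior hemisphere is kept (directions with
#' `z >= -epsilon`, `epsilon` = half the minimal vertex spacing, so that
#' equatorial vertices survive rounding) together with the faces whose
#' three corners are kept. Level 6 gives 20481 directions over the
#' cranial vault.
#'
#' @param subdivision_level integer >= 0 (default 6).
#' @param origin ray origin in mm (default the canonical origin, i.e. the
#'   sella centre).
#' @return An object of class `spherical_sampling` with elements
#'   `directions` (unit vectors, `n x 3`), `faces`, `origin`,
#'   `subdivision_level`.
#' @export
build_hemisphere_sampling <- function(subdivision_level = 6, origin = c(0, 0, 0)) {
  ico <- icosphere(subdivision_level)
  e <- mesh_edges(ico)
  elen <- sqrt(rowSums((ico$vertices[e[, 1], ] - ico$vertices[e[, 2], ])^2))
  eps <- min(elen) / 2
  keep <- ico$vertices[, 3] >= -eps
  idx <- cumsum(keep)
  fkeep <- keep[ico$faces[, 1]] & keep[ico$faces[, 2]] & keep[ico$faces[, 3]]
  faces <- matrix(idx[ico$faces[fkeep, ]], ncol = 3)
  structure(list(directions = ico$vertices[keep, , drop = FALSE],
                 faces = faces, origin = as.numeric(origin),
                 subdivision_level = as.integer(subdivision_level)),
            class = "spherical_sampling")
}

#' @export
print.spherical_sampling <- function(x, ...) {
  cat(sprintf("spherical_sampling: level %d, %d directions, %d faces\n",
              x$subdivision_level, nrow(x$directions), nrow(x$faces)))
  invisible(x)
}

#' Ray-triangle intersection (Moller-Trumbore)
#'
#' Returns the smallest `t >= 0` such that
#' `ray_origin + t * ray_direction` lies inside the triangle (barycentric
#' `u, v >= 0`, `u + v <= 1`), or `NA` for a miss or a degenerate
#' triangle.
#'
#' @param ray_origin,ray_direction numeric length-3; the direction must
#'   be unit length.
#' @param triangle_vertices 3x3 matrix, one triangle vertex per row.
#' @return scalar distance `t` in mm, or `NA_real_`.
#' @export
ray_triangle_intersect <- function(ray_origin, ray_direction, triangle_vertices) {
  if (abs(sqrt(sum(ray_direction^2)) - 1) > 1e-6)
    cs_abort("ray direction must be unit length", "cranioshape_input_error")
  .ray_triangle_cpp(as.numeric(ray_origin), as.numeric(ray_direction),
                    matrix(as.numeric(triangle_vertices), 3, 3))
}

#' Resample a registered mesh by raycasting
#'
#' Casts one ray per sampling direction from the sampling origin, collects
#' every intersection with the mesh (Moller-Trumbore, duplicate hits
#' within 1e-9 mm collapsed), and stores the nearest hit as the inner
#' radius and the farthest as the outer radius. Directions with no hit
#' are marked invalid (holes, fontanelles, mesh openings).
#'
#' @param mesh a [triangle_mesh()] in the canonical frame.
#' @param sampling a [build_hemisphere_sampling()] result.
#' @return An object of class `sampled_surface`: `sampling`, `inner`
#'   and `outer` per-direction radii (mm, `NA` where invalid), `valid`
#'   logical.
#' @export
resample_surface <- function(mesh, sampling) {
  if (nrow(mesh$faces) == 0L)
    cs_abort("mesh has no faces", "cranioshape_input_error")
  hits <- .raycast_all_cpp(sampling$directions, sampling$origin,
                           mesh$vertices, mesh$faces)
  sampled_surface(sampling, hits$inner, hits$outer, hits$valid)
}

#' @rdname resample_surface
#' @param inner,outer per-direction radii (mm); `NA` where invalid.
#' @param valid per-direction logical.
#' @export
sampled_surface <- function(sampling, inner, outer, valid = NULL) {
  n <- nrow(sampling$directions)
  inner <- as.numeric(inner)
  outer <- as.numeric(outer)
  if (is.null(valid)) valid <- is.finite(inner) & is.finite(outer)
  if (length(inner) != n || length(outer) != n || length(valid) != n)
    cs_abort("radii must have one entry per sampling direction",
             "cranioshape_input_error")
  bad <- valid & (!is.finite(inner) | !is.finite(outer) |
                    inner <= 0 | inner > outer + 1e-12)
  if (any(bad))
    cs_abort("valid entries require 0 < inner <= outer",
             "cranioshape_input_error")
  structure(list(sampling = sampling, inner = inner, outer = outer,
                 valid = as.logical(valid)),
            class = "sampled_surface")
}

#' @export
print.sampled_surface <- function(x, ...) {
  cat(sprintf("sampled_surface: %d rays, %d valid\n",
              length(x$inner), sum(x$valid)))
  invisible(x)
}

#' Fill invalid rays by harmonic extrapolation
#'
#' Invalid directions (holes in the skull surface) receive the harmonic
#' (Laplacian) interpolation of their valid neighbours' radii over the
#' sampling mesh graph: Jacobi iteration of the neighbour mean until the
#' largest update falls below `tol` mm. Valid entries are unchanged.
#'
#' @param sampled a [sampled_surface()] with at least one valid direction.
#' @param tol convergence tolerance in mm (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @return a fully valid [sampled_surface()].
#' @export
fill_missing <- function(sampled, tol = 1e-6, max_iter = 10000) {
  if (!any(sampled$valid))
    cs_abort("no valid directions to extrapolate from",
             "cranioshape_input_error")
  if (all(sampled$valid)) return(sampled)
  adj <- mesh_adjacency_csr(
    triangle_mesh(sampled$sampling$directions, sampled$sampling$faces,
                  validate = FALSE))
  nbr <- lapply(seq_along(sampled$inner), function(i)
    adj$idx[(adj$ptr[i] + 1L):adj$ptr[i + 1L]] + 1L)
  fill_one <- function(values) {
    miss <- which(!sampled$valid)
    values[miss] <- mean(values[sampled$valid])
    for (it in seq_len(max_iter)) {
      upd <- vapply(miss, function(i) mean(values[nbr[[i]]]), 0)
      delta <- max(abs(upd - values[miss]))
      values[miss] <- upd
      if (delta < tol) break
    }
    values
  }
  sampled_surface(sampled$sampling, fill_one(sampled$inner),
                  fill_one(sampled$outer), rep(TRUE, length(sampled$inner)))
}

#' Serialize a sampled surface
#'
#' CSV columns: `index, dx, dy, dz, inner_mm, outer_mm, valid`, plus a
#' JSON header sidecar (`<path>.json`) with the subdivision level and
#' origin; the sampling topology can be saved as PLY with
#' [write_ply()].
#'
#' @param sampled a [sampled_surface()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sampled_surface <- function(sampled, path) {
  d <- sampled$sampling$directions
  df <- data.frame(index = seq_len(nrow(d)) - 1L,
                   dx = d[, 1], dy = d[, 2], dz = d[, 3],
                   inner_mm = sampled$inner, outer_mm = sampled$outer,
                   valid = as.integer(sampled$valid))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(subdivision_level = sampled$sampling$subdivision_level,
         origin = sampled$sampling$origin),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sampled_surface
#' @export
read_sampled_surface <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sampling <- build_hemisphere_sampling(hdr$subdivision_level, hdr$origin)
  df <- utils::read.csv(path)
  if (nrow(df) != nrow(sampling$directions))
    cs_abort("CSV rows do not match the sampling resolution",
             "cranioshape_format_error")
  sampled_surface(sampling, df$inner_mm, df$outer_mm, df$valid == 1L)
}
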