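#' Anatomical landmark set for the canonical skull frame
#'
#' Four skull-base landmarks fix the canonical coordinate frame: the
#' centre of the sella turcica (origin), the nasion (the sella-nasion line
#' becomes the +y axis) and the two anterior clinoid processes (rotated
#' into the x,y-plane, right clinoid at x > 0).
#'
#' @param sella,nasion,clinoid_left,clinoid_right numeric length-3
#'   coordinates in mm.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(sella, nasion, clinoid_left, clinoid_right) {
  lm <- list(sella = as.numeric(sella), nasion = as.numeric(nasion),
             clinoid_left = as.numeric(clinoid_left),
             clinoid_right = as.numeric(clinoid_right))
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L || any(!is.finite(lm[[nm]])))
      cs_abort(sprintf("landmark '%s' must be 3 finite coordinates", nm),
               "cranioshape_input_error")
  }
  if (sqrt(sum((lm$sella - lm$nasion)^2)) < 1e-9)
    cs_abort("sella and nasion coincide", "cranioshape_degeneracy_error")
  if (sqrt(sum((lm$clinoid_left - lm$clinoid_right)^2)) < 1e-9)
    cs_abort("clinoid landmarks coincide", "cranioshape_degeneracy_error")
  structure(lm, class = "landmark_set")
}

#' Read landmarks from a JSON sidecar file
#'
#' Expects keys `sella`, `nasion`, `clinoid_left`, `clinoid_right` (each a
#' 3-array) and `units` (must be `"mm"`).
#'
#' @param path path to the JSON file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$units) || !identical(j$units, "mm"))
    cs_abort("landmark file must declare units \"mm\"",
             "cranioshape_format_error")
  landmark_set(j$sella, j$nasion, j$clinoid_left, j$clinoid_right)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(sella = landmarks$sella, nasion = landmarks$nasion,
         clinoid_left = landmarks$clinoid_left,
         clinoid_right = landmarks$clinoid_right, units = "mm"),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation numeric length-3 (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    cs_abort("rotation must be orthonormal with determinant +1",
             "cranioshape_input_error")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param a,b `rigid_transform`s; the result applies `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @rdname rigid_transform
#' @param points `n x 3` matrix of points (mm).
#' @export
transform_points <- function(points, transform) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' Derive the canonical skull transform from landmarks
#'
#' Maps the landmark frame to the canonical pose: sella at the origin,
#' nasion on the +y axis, and the residual rotation about y chosen so the
#' summed squared z-coordinates of the two clinoid processes is minimal
#' (least-squares flattening into the x,y-plane), with the right clinoid
#' at x > 0. Skulls registered this way sit in a symmetrical straight-up
#' position with +z superior.
#'
#' @param landmarks a [landmark_set()].
#' @return a [rigid_transform()] mapping input coordinates to the
#'   canonical frame.
#' @export
derive_canonical_transform <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set"))
    cs_abort("landmarks must be a landmark_set", "cranioshape_input_error")
  yv <- landmarks$nasion - landmarks$sella
  cl <- landmarks$clinoid_right - landmarks$clinoid_left
  cr <- c(yv[2] * cl[3] - yv[3] * cl[2],
          yv[3] * cl[1] - yv[1] * cl[3],
          yv[1] * cl[2] - yv[2] * cl[1])
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(yv^2)) * sqrt(sum(cl^2)))
    cs_abort("sella-nasion line parallel to the inter-clinoid line",
             "cranioshape_degeneracy_error")
  # rotation taking the unit sella->nasion direction onto e_y
  R1 <- rotation_between(yv / sqrt(sum(yv^2)), c(0, 1, 0))
  # clinoids in the intermediate frame
  c1 <- as.numeric(R1 %*% (landmarks$clinoid_left - landmarks$sella))
  c2 <- as.numeric(R1 %*% (landmarks$clinoid_right - landmarks$sella))
  sxx <- c1[1]^2 + c2[1]^2
  szz <- c1[3]^2 + c2[3]^2
  sxz <- c1[1] * c1[3] + c2[1] * c2[3]
  # minimise sum of squared z over rotations about y (period pi) ...
  theta <- 0.5 * atan2(2 * sxz, sxx - szz)
  best <- NULL
  for (cand in c(theta, theta + pi / 2, theta + pi, theta + 3 * pi / 2)) {
    z2 <- (cos(cand) * c1[3] - sin(cand) * c1[1])^2 +
      (cos(cand) * c2[3] - sin(cand) * c2[1])^2
    if (is.null(best) || z2 < best$z2 - 1e-12) best <- list(th = cand, z2 = z2)
  }
  th <- best$th
  # ... and resolve the period-pi ambiguity with clinoid_right at x > 0
  xr <- cos(th) * c2[1] + sin(th) * c2[3]
  if (xr < 0) th <- th + pi
  Ry <- matrix(c(cos(th), 0, sin(th),
                 0, 1, 0,
                 -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  R <- Ry %*% R1
  rigid_transform(R, -as.numeric(R %*% landmarks$sella))
}

#' @keywords internal
#' @noRd
rotation_between <- function(a, b) {
  # minimal rotation taking unit vector a onto unit vector b (Rodrigues)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex `v` is mapped to `rotation %*% v + translation`; faces are
#' unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed [triangle_mesh()].
#' @export
apply_rigid <- function(mesh, transform) {
  if (!inherits(transform, "rigid_transform"))
    cs_abort("transform must be a rigid_transform", "cranioshape_input_error")
  triangle_mesh(transform_points(mesh$vertices, transform), mesh$faces,
                validate = FALSE)
}

#' Register a mesh into the canonical frame from its landmarks
#'
#' Convenience wrapper: derives the canonical transform from the
#' landmarks and applies it to the mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param landmarks a [landmark_set()] in the same coordinates as `mesh`.
#' @return the registered [triangle_mesh()], with the derived transform in
#'   attribute `transform`.
#' @export
register_mesh <- function(mesh, landmarks) {
  tf <- derive_canonical_transform(landmarks)
  out <- apply_rigid(mesh, tf)
  attr(out, "transform") <- tf
  out
}
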