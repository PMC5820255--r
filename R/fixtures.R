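#' Specification of the artificial test object
#'
#' A sphere carrying five spherical bulges with pairwise distinct radii,
#' a torus-shaped bulge, and a spherical hole whose radius equals the
#' second-largest bulge radius (so the interior surface of the hole
#' mirrors the exterior of that bulge). Feature centres sit on the base
#' sphere surface along the given unit directions; directions must be
#' separated enough that features do not overlap.
#'
#' @param base_radius base sphere radius (mm), default 50.
#' @param bulge_radii five pairwise distinct radii (mm), default
#'   `c(4, 6, 8, 10, 12)`.
#' @param bulge_directions 5x3 matrix of unit directions.
#' @param torus_ring_radius,torus_tube_radius torus geometry (mm),
#'   defaults 10 and 3.
#' @param torus_direction,hole_direction unit 3-vectors.
#' @param hole_radius must equal the second-largest bulge radius.
#' @param mesh_resolution grid points per axis for iso-surfacing
#'   (default 98, a ~1.35 mm grid step; about 75k mesh vertices, enough
#'   that 5 mm quadric patches resolve the smallest bulge without bias).
#' @return An object of class `test_object_spec`.
#' @export
test_object_spec <- function(base_radius = 50,
                             bulge_radii = c(4, 6, 8, 10, 12),
                             bulge_directions = default_bulge_directions(),
                             torus_ring_radius = 10, torus_tube_radius = 3,
                             torus_direction = dir_sph(36, -40),
                             hole_direction = dir_sph(216, -40),
                             hole_radius = sort(bulge_radii, decreasing = TRUE)[2],
                             mesh_resolution = 98) {
  if (length(bulge_radii) != 5L || anyDuplicated(bulge_radii))
    cs_abort("exactly 5 pairwise distinct bulge radii are required",
             "cranioshape_spec_error")
  if (abs(hole_radius - sort(bulge_radii, decreasing = TRUE)[2]) > 1e-12)
    cs_abort("hole radius must equal the second-largest bulge radius",
             "cranioshape_spec_error")
  dirs <- rbind(bulge_directions, torus_direction, hole_direction)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ang <- acos(pmin(pmax(tcrossprod(dirs), -1), 1))
  sep <- min(ang[upper.tri(ang)]) * 180 / pi
  if (sep < 40)
    cs_abort("feature directions closer than 40 degrees would overlap",
             "cranioshape_spec_error")
  structure(list(base_radius = base_radius, bulge_radii = bulge_radii,
                 bulge_directions = dirs[1:5, , drop = FALSE],
                 torus_ring_radius = torus_ring_radius,
                 torus_tube_radius = torus_tube_radius,
                 torus_direction = dirs[6, ], hole_direction = dirs[7, ],
                 hole_radius = hole_radius,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "test_object_spec")
}

#' @rdname test_object_spec
#' @param azimuth_deg,elevation_deg spherical angles in degrees.
#' @export
dir_sph <- function(azimuth_deg, elevation_deg) {
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

#' @keywords internal
#' @noRd
default_bulge_directions <- function() {
  rbind(dir_sph(0, 25), dir_sph(72, 25), dir_sph(144, 25),
        dir_sph(216, 25), dir_sph(288, 25))
}

#' Signed-distance iso-surfacing of a solid
#'
#' Evaluates a signed-distance function (negative inside) on a regular
#' grid and extracts the zero level set by marching tetrahedra. Boolean
#' solids are composed as `min` (union) / `max(f, -g)` (difference) of
#' component distances before iso-surfacing, which is robust and avoids
#' exact mesh booleans.
#'
#' @param sdf function taking an `n x 3` matrix of points (mm) and
#'   returning `n` signed distances.
#' @param lower,upper numeric length-3 corners of the evaluation box (mm).
#' @param n grid points per axis (scalar or length-3).
#' @return a [triangle_mesh()] with outward-oriented faces.
#' @export
mesh_from_sdf <- function(sdf, lower, upper, n) {
  n <- rep(as.integer(n), length.out = 3)
  xs <- seq(lower[1], upper[1], length.out = n[1])
  ys <- seq(lower[2], upper[2], length.out = n[2])
  zs <- seq(lower[3], upper[3], length.out = n[3])
  pts <- cbind(rep(xs, times = n[2] * n[3]),
               rep(rep(ys, each = n[1]), times = n[3]),
               rep(zs, each = n[1] * n[2]))
  f <- sdf(pts)
  iso <- .mt_isosurface(as.numeric(f), n, 0)
  V <- iso$vertices
  sp <- c(xs[2] - xs[1], ys[2] - ys[1], zs[2] - zs[1])
  for (d in 1:3) V[, d] <- lower[d] + V[, d] * sp[d]
  drop_degenerate_faces(triangle_mesh(V, iso$faces, validate = FALSE))
}

#' @keywords internal
#' @noRd
sdf_sphere <- function(centre, radius) {
  force(centre); force(radius)
  function(p) sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2 +
                     (p[, 3] - centre[3])^2) - radius
}

# torus with axis `axis` through `centre`
#' @keywords internal
#' @noRd
sdf_torus <- function(centre, axis, ring_radius, tube_radius) {
  axis <- axis / sqrt(sum(axis^2))
  function(p) {
    q <- sweep(p, 2, centre)
    z <- q %*% axis
    rho2 <- rowSums(q^2) - z^2
    sqrt((sqrt(pmax(rho2, 0)) - ring_radius)^2 + z^2) - tube_radius
  }
}

#' Generate the artificial test object
#'
#' Builds the closed, outward-oriented mesh of the base sphere with its
#' five bulges, torus bulge and spherical hole by signed-distance
#' union/difference and iso-surfacing. Bulge and hole spheres are
#' centred on the base surface, so each bulge protrudes by its radius
#' and the hole carves an equally deep spherical dimple. Feature centre
#' vertices (bulge apexes, hole bottom, torus crest) are reported in the
#' `features` attribute, keyed for downstream tests: the second-largest
#' bulge is the reference area of the rotation experiment.
#'
#' @param spec a [test_object_spec()].
#' @return a [triangle_mesh()] with attribute `features`: a data frame
#'   with `name`, `radius`, target point coordinates and the nearest
#'   mesh `vertex` (1-based).
#' @export
make_test_object <- function(spec = test_object_spec()) {
  if (!inherits(spec, "test_object_spec"))
    cs_abort("spec must be a test_object_spec", "cranioshape_spec_error")
  R0 <- spec$base_radius
  parts <- list(sdf_sphere(c(0, 0, 0), R0))
  for (i in 1:5)
    parts[[length(parts) + 1L]] <-
      sdf_sphere(R0 * spec$bulge_directions[i, ], spec$bulge_radii[i])
  parts[[length(parts) + 1L]] <-
    sdf_torus(R0 * spec$torus_direction, spec$torus_direction,
              spec$torus_ring_radius, spec$torus_tube_radius)
  hole <- sdf_sphere(R0 * spec$hole_direction, spec$hole_radius)
  sdf <- function(p) {
    f <- parts[[1]](p)
    for (k in seq_along(parts)[-1]) f <- pmin(f, parts[[k]](p))
    pmax(f, -hole(p))
  }
  ext <- R0 + max(spec$bulge_radii) + 4
  mesh <- mesh_from_sdf(sdf, rep(-ext, 3), rep(ext, 3), spec$mesh_resolution)
  targets <- rbind(
    t(vapply(1:5, function(i) (R0 + spec$bulge_radii[i]) *
               spec$bulge_directions[i, ], numeric(3))),
    (R0 - spec$hole_radius) * spec$hole_direction)
  nm <- c(sprintf("bulge_r%g", spec$bulge_radii), "hole")
  vid <- vapply(seq_len(nrow(targets)), function(i)
    which.min(colSums((t(mesh$vertices) - targets[i, ])^2)), 0L)
  feats <- data.frame(name = nm,
                      radius = c(spec$bulge_radii, spec$hole_radius),
                      x = targets[, 1], y = targets[, 2], z = targets[, 3],
                      vertex = vid)
  attr(mesh, "features") <- feats
  attr(mesh, "spec") <- spec
  mesh
}

#' Specification of a skull-like shell phantom
#'
#' An ellipsoidal bone shell with labelled skull-base landmarks standing
#' in for a patient CT: bone voxels at `bone_hu` between the outer
#' ellipsoid and the outer ellipsoid shrunk by the shell thickness,
#' background at `background_hu`. An optional asymmetry bulge fuses a
#' spherical boss onto the shell.
#'
#' @param outer_semi_axes ellipsoid semi-axes (mm), default
#'   `c(60, 75, 55)` (x lateral, y anterior, z superior).
#' @param shell_thickness bone thickness (mm), default 4.
#' @param bone_hu,background_hu intensities (HU), defaults 1000 and 0.
#' @param voxel_spacing mm per voxel, default `c(1.5, 1.5, 1.5)`.
#' @param centre ellipsoid centre in physical mm (default places the
#'   volume corner at the origin).
#' @param asymmetry_bulge optional `list(direction =, radius =,
#'   amplitude =)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_semi_axes = c(60, 75, 55), shell_thickness = 4,
                         bone_hu = 1000, background_hu = 0,
                         voxel_spacing = c(1.5, 1.5, 1.5),
                         centre = outer_semi_axes + 4 * voxel_spacing,
                         asymmetry_bulge = NULL) {
  if (shell_thickness >= min(outer_semi_axes))
    cs_abort("shell thickness must be below the smallest semi-axis",
             "cranioshape_spec_error")
  if (!(bone_hu >= 167 && 167 > background_hu))
    cs_abort("bone must be >= 167 HU and background below it",
             "cranioshape_spec_error")
  if (shell_thickness < max(voxel_spacing))
    cs_abort("shell thinner than one voxel cannot be resolved",
             "cranioshape_resolution_error")
  structure(list(outer_semi_axes = as.numeric(outer_semi_axes),
                 shell_thickness = shell_thickness, bone_hu = bone_hu,
                 background_hu = background_hu,
                 voxel_spacing = as.numeric(voxel_spacing),
                 centre = as.numeric(centre),
                 asymmetry_bulge = asymmetry_bulge),
            class = "phantom_spec")
}

#' Voxel phantom with landmarks
#'
#' Rasterises the phantom of a [phantom_spec()] onto a voxel grid and
#' returns the volume together with its landmark set: the sella sits
#' inside the cavity below the ellipsoid centre, the nasion anterior on
#' the sella-nasion axis, and the clinoids symmetric about the
#' mid-sagittal plane, so registration puts the phantom in the canonical
#' symmetric straight-up pose.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [intensity_volume()]) and `landmarks`
#'   (a [landmark_set()] in the volume's physical frame).
#' @export
make_phantom_volume <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    cs_abort("spec must be a phantom_spec", "cranioshape_spec_error")
  a <- spec$outer_semi_axes
  sp <- spec$voxel_spacing
  ext <- a + 4 * sp
  dims <- ceiling(2 * ext / sp) + 1L
  xs <- spec$centre[1] + (seq_len(dims[1]) - 1) * sp[1] - ext[1]
  ys <- spec$centre[2] + (seq_len(dims[2]) - 1) * sp[2] - ext[2]
  zs <- spec$centre[3] + (seq_len(dims[3]) - 1) * sp[3] - ext[3]
  origin <- c(xs[1], ys[1], zs[1])
  X <- (xs - spec$centre[1])
  Y <- (ys - spec$centre[2])
  Z <- (zs - spec$centre[3])
  q_out <- outer(outer((X / a[1])^2, (Y / a[2])^2, "+"), (Z / a[3])^2, "+")
  ai <- a - spec$shell_thickness
  q_in <- outer(outer((X / ai[1])^2, (Y / ai[2])^2, "+"), (Z / ai[3])^2, "+")
  shell <- q_out <= 1 & q_in > 1
  if (!is.null(spec$asymmetry_bulge)) {
    b <- spec$asymmetry_bulge
    d <- b$direction / sqrt(sum(b$direction^2))
    surf <- 1 / sqrt(sum((d / a)^2)) # radius of the ellipsoid along d
    cb <- d * (surf + b$amplitude - b$radius)
    D2 <- outer(outer((X - cb[1])^2, (Y - cb[2])^2, "+"), (Z - cb[3])^2, "+")
    shell <- shell | (D2 <= b$radius^2 & q_in > 1)
  }
  vox <- array(spec$background_hu, dims)
  vox[shell] <- spec$bone_hu
  lm <- landmark_set(
    sella = spec$centre + c(0, 0, -15),
    nasion = spec$centre + c(0, a[2] - spec$shell_thickness, -15),
    clinoid_left = spec$centre + c(-12, 8, -12),
    clinoid_right = spec$centre + c(12, 8, -12))
  list(volume = intensity_volume(vox, sp, origin), landmarks = lm)
}

#' Bilaterally symmetric skull mesh with temple bulges
#'
#' Direct mesh analogue of a registered healthy skull: an ellipsoidal
#' outer surface in the canonical frame (sella at the origin, +y
#' anterior, +z superior) with two mirrored temple-like bulges at +x and
#' -x. Used for the within-skull symmetry experiment: the right temple
#' serves as reference shape and its mirror is the expected second
#' match.
#'
#' @param spec a [phantom_spec()] without asymmetry bulge.
#' @param temple_radius bulge sphere radius (mm), default 14.
#' @param mesh_resolution grid points per axis (default 97; odd counts
#'   keep the grid mirror-symmetric in x).
#' @return a [triangle_mesh()] with attributes `apex_vertex` (right
#'   temple) and `mirror_vertex` (left temple).
#' @export
make_symmetric_skull_mesh <- function(spec = phantom_spec(),
                                      temple_radius = 14,
                                      mesh_resolution = 97) {
  if (!inherits(spec, "phantom_spec"))
    cs_abort("spec must be a phantom_spec", "cranioshape_spec_error")
  if (!is.null(spec$asymmetry_bulge))
    cs_abort("symmetric skull mesh requires a spec without asymmetry",
             "cranioshape_spec_error")
  a <- spec$outer_semi_axes
  centre <- c(0, 0, 15) # sella 15 mm below the ellipsoid centre -> origin
  cr <- centre + c(a[1] - temple_radius / 2, 8, 0)
  cl <- cr * c(-1, 1, 1)
  sdf_ell <- function(p) {
    q <- sweep(p, 2, centre)
    # approximate ellipsoid distance: scaled-space distance renormalised
    s <- sqrt((q[, 1] / a[1])^2 + (q[, 2] / a[2])^2 + (q[, 3] / a[3])^2)
    (s - 1) * min(a)
  }
  sr <- sdf_sphere(cr, temple_radius)
  sl <- sdf_sphere(cl, temple_radius)
  sdf <- function(p) pmin(sdf_ell(p), sr(p), sl(p))
  ext <- max(a) + temple_radius / 2 + 6
  mesh <- mesh_from_sdf(sdf, centre - ext, centre + ext,
                        mesh_resolution)
  apex_r <- cr + c(temple_radius, 0, 0)
  apex_l <- apex_r * c(-1, 1, 1)
  av <- which.min(colSums((t(mesh$vertices) - apex_r)^2))
  mv <- which.min(colSums((t(mesh$vertices) - apex_l)^2))
  attr(mesh, "apex_vertex") <- av
  attr(mesh, "mirror_vertex") <- mv
  mesh
}

#' Rotated rigid copy of a mesh
#'
#' Rotates the mesh about an axis through the origin by the given angle,
#' anti-clockwise when viewed from the axis tip (right-hand rule).
#' Vertex ordering is preserved, so ground-truth correspondence between
#' original and copy is index identity.
#'
#' @param mesh a [triangle_mesh()].
#' @param axis unit 3-vector.
#' @param angle_degrees rotation angle.
#' @return the rotated [triangle_mesh()] (attributes preserved).
#' @export
rigid_copy <- function(mesh, axis = c(0, 0, 1), angle_degrees = 45) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    cs_abort("axis must be unit length", "cranioshape_input_error")
  th <- angle_degrees * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  out <- mesh
  out$vertices <- mesh$vertices %*% t(R)
  colnames(out$vertices) <- c("x", "y", "z")
  out
}
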