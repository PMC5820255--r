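#' CT intensity volume
#'
#' A 3D scalar grid of CT intensities in Hounsfield units (HU) together
#' with its physical voxel spacing and origin. Voxel index `(i, j, k)`
#' (1-based in R) maps to the physical point
#' `origin + (i - 1, j - 1, k - 1) * spacing` in millimetres.
#'
#' @param voxels 3D numeric array of intensities (HU).
#' @param spacing numeric length-3, voxel size along each axis (mm),
#'   strictly positive.
#' @param origin numeric length-3, physical position of voxel (1,1,1) (mm).
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    cs_abort("voxels must be a 3D array", "cranioshape_input_error")
  if (any(dim(voxels) < 2L))
    cs_abort("grid dimensions must be >= 2 on each axis", "cranioshape_input_error")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    cs_abort("spacing must be 3 strictly positive finite values",
             "cranioshape_input_error")
  stopifnot_finite(voxels, "voxel intensities")
  stopifnot_finite(origin, "origin")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("intensity_volume: %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary voxel mask
#'
#' Boolean grid on the same lattice as the [intensity_volume()] it was
#' derived from.
#'
#' @param voxels 3D logical array.
#' @param spacing,origin as in [intensity_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    cs_abort("voxels must be a 3D array", "cranioshape_input_error")
  storage.mode(voxels) <- "logical"
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels, %d set\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Threshold segmentation of bone
#'
#' Marks every voxel at or above the bone threshold. The default of
#' 167 HU segments infant cranial bone against soft tissue.
#'
#' @param volume an [intensity_volume()].
#' @param threshold_hu scalar threshold (HU); default 167.
#' @return a [binary_mask()] on the same grid; an all-false mask is legal.
#' @export
segment_bone <- function(volume, threshold_hu = 167) {
  if (!inherits(volume, "intensity_volume"))
    cs_abort("volume must be an intensity_volume", "cranioshape_input_error")
  if (!is.finite(threshold_hu))
    cs_abort("threshold must be finite", "cranioshape_input_error")
  binary_mask(volume$voxels >= threshold_hu, volume$spacing, volume$origin)
}

#' @keywords internal
#' @noRd
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable Gaussian on a 3D array, zero-padded borders
#' @keywords internal
#' @noRd
gaussian_smooth_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    if (length(k) == 1) next
    r <- (length(k) - 1L) / 2L
    out <- array(0, d)
    for (s in seq_along(k)) {
      off <- s - r - 1L
      src <- seq_len(d[axis]) + off
      keep <- src >= 1L & src <= d[axis]
      if (!any(keep)) next
      di <- which(keep)
      si <- src[keep]
      if (axis == 1) out[di, , ] <- out[di, , ] + k[s] * a[si, , ]
      else if (axis == 2) out[, di, ] <- out[, di, ] + k[s] * a[, si, ]
      else out[, , di] <- out[, , di] + k[s] * a[, , si]
    }
    a <- out
  }
  a
}

#' Remove speckles and smooth a segmentation mask
#'
#' Connected components (6-connectivity) smaller than
#' `min_component_voxels` are removed, then the 0/1 indicator is smoothed
#' with a Gaussian of width `smoothing_sigma_mm` (converted to voxels per
#' axis through the spacing) and re-thresholded at 0.5.
#'
#' @param mask a [binary_mask()].
#' @param min_component_voxels drop components with fewer voxels
#'   (default 50; 0 keeps everything).
#' @param smoothing_sigma_mm Gaussian sigma in millimetres (default 0.5;
#'   0 skips smoothing).
#' @return a [binary_mask()] on the same grid.
#' @export
denoise <- function(mask, min_component_voxels = 50, smoothing_sigma_mm = 0.5) {
  if (!inherits(mask, "binary_mask"))
    cs_abort("mask must be a binary_mask", "cranioshape_input_error")
  if (min_component_voxels < 0 || smoothing_sigma_mm < 0)
    cs_abort("component size and sigma must be non-negative",
             "cranioshape_input_error")
  v <- mask$voxels
  if (min_component_voxels > 0 && any(v)) {
    lab <- .label_components_3d(as.logical(v), dim(v))
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component_voxels)
    v <- array(lab %in% keep & lab > 0L, dim(v))
  }
  if (smoothing_sigma_mm > 0) {
    sig <- smoothing_sigma_mm / mask$spacing
    sm <- gaussian_smooth_3d(array(as.numeric(v), dim(v)), sig)
    v <- sm >= 0.5
  }
  binary_mask(array(v, dim(mask$voxels)), mask$spacing, mask$origin)
}

#' Extract the iso-surface of a mask as a triangle mesh
#'
#' The 0/1 indicator of the mask is lightly smoothed in voxel space
#' (anti-aliasing; `presmooth_sigma_vox = 0` disables it and places all
#' crossings at edge midpoints) and the 0.5 iso-level is triangulated by
#' marching tetrahedra with linear interpolation along grid edges. Output
#' vertices are in physical millimetres (spacing and origin applied) and
#' faces are consistently oriented with outward normals.
#'
#' @param mask a [binary_mask()] containing at least one set and one
#'   unset voxel.
#' @param presmooth_sigma_vox anti-aliasing sigma in voxels (default 0.8).
#' @return a [triangle_mesh()].
#' @export
extract_surface <- function(mask, presmooth_sigma_vox = 0.8) {
  if (!inherits(mask, "binary_mask"))
    cs_abort("mask must be a binary_mask", "cranioshape_input_error")
  v <- mask$voxels
  if (all(v) || !any(v))
    cs_abort("mask has no surface (all-true or all-false)",
             "cranioshape_nosurface_error")
  f <- array(as.numeric(v), dim(v))
  if (presmooth_sigma_vox > 0)
    f <- gaussian_smooth_3d(f, rep(presmooth_sigma_vox, 3))
  if (all(f < 0.5) || all(f >= 0.5))
    cs_abort("mask has no surface after smoothing",
             "cranioshape_nosurface_error")
  # the iso-surfacer orients normals towards increasing field values;
  # the object is where the indicator is high, so invert for outward
  iso <- .mt_isosurface(as.numeric(1 - f), dim(f), 0.5)
  V <- iso$vertices
  for (d in 1:3)
    V[, d] <- mask$origin[d] + V[, d] * mask$spacing[d]
  drop_degenerate_faces(triangle_mesh(V, iso$faces, validate = FALSE))
}

# merge vertices closer than tol (iso-surfacing emits near-coincident
# points where the field vanishes exactly at a grid node), then drop the
# collapsed faces; keeps watertight meshes watertight
#' @keywords internal
#' @noRd
weld_vertices <- function(mesh, tol = 1e-6) {
  key <- paste(round(mesh$vertices[, 1] / tol),
               round(mesh$vertices[, 2] / tol),
               round(mesh$vertices[, 3] / tol))
  first <- match(key, key)
  keep <- which(first == seq_along(first))
  remap <- match(first, keep)
  triangle_mesh(mesh$vertices[keep, , drop = FALSE],
                matrix(remap[mesh$faces], ncol = 3), validate = FALSE)
}

#' @keywords internal
#' @noRd
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  mesh <- weld_vertices(mesh)
  keep <- face_areas(mesh) > tol &
    mesh$faces[, 1] != mesh$faces[, 2] &
    mesh$faces[, 1] != mesh$faces[, 3] &
    mesh$faces[, 2] != mesh$faces[, 3]
  triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
}
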