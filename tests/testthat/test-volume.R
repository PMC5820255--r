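test_that("DICOM series assemble in slice order with metadata intact", {
  vol <- intensity_volume(array(seq_len(4 * 4 * 3), c(4, 4, 3)),
                          spacing = c(1, 1, 2), origin = c(5, -3, 10))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_dicom_series(dir)
  expect_identical(dim(back$voxels), c(4L, 4L, 3L))
  expect_equal(back$spacing, c(1, 1, 2))
  expect_equal(back$origin, vol$origin)
  expect_equal(back$voxels, vol$voxels)
})

test_that("stored values are rescaled to HU through slope and intercept", {
  # stored 1191 with slope 1, intercept -1024 must read back as 167 HU
  vol <- intensity_volume(array(167, c(4, 4, 2)))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir, slope = 1, intercept = -1024)
  slice <- cranioshape:::read_dicom_slice(file.path(dir, "slice0001.dcm"))
  expect_equal(slice$pixels[1], 1191)
  expect_equal(load_dicom_series(dir)$voxels[1, 1, 1], 167)
})

test_that("inconsistent slices are rejected", {
  dir <- withr::local_tempdir()
  write_dicom_series(intensity_volume(array(0, c(4, 4, 2))), dir)
  cranioshape:::write_dicom_slice(
    file.path(dir, "slice0099.dcm"), matrix(0, 6, 6), rows = 6, cols = 6,
    pixel_spacing = c(1, 1), thickness = 1, position = c(0, 0, 9),
    instance = 9, slope = 1, intercept = 0,
    series_uid = "1.2.826.0.1.3680043.9999.1")
  expect_error(load_dicom_series(dir), class = "cranioshape_format_error")
  expect_error(load_dicom_series(file.path(dir, "no-such-dir")),
               class = "cranioshape_input_error")
})

test_that("segment_bone thresholds exactly at the given HU", {
  ph <- fx_small_phantom()
  mask <- segment_bone(ph$volume, 167)
  expect_identical(mask$voxels, ph$volume$voxels >= 167)
  zero <- intensity_volume(array(0, c(4, 4, 4)))
  expect_false(any(segment_bone(zero, 167)$voxels))
  expect_true(all(segment_bone(zero, min(zero$voxels))$voxels))
})

test_that("segmentation is idempotent on its own re-cast output", {
  ph <- fx_small_phantom()
  m1 <- segment_bone(ph$volume, 167)
  recast <- intensity_volume(array(ifelse(m1$voxels, 1000, 0), dim(m1$voxels)),
                             m1$spacing, m1$origin)
  expect_identical(segment_bone(recast, 167)$voxels, m1$voxels)
})

test_that("denoise removes speckles and keeps the shell", {
  ph <- fx_small_phantom()
  mask <- segment_bone(ph$volume, 167)
  v <- mask$voxels
  set.seed(7)
  for (k in 1:5) v[sample.int(3, 1), sample.int(3, 1), sample.int(3, 1)] <- TRUE
  noisy <- binary_mask(v, mask$spacing, mask$origin)
  lab0 <- cranioshape:::.label_components_3d(as.logical(noisy$voxels),
                                             dim(noisy$voxels))
  clean <- denoise(noisy, min_component_voxels = 10, smoothing_sigma_mm = 0)
  lab1 <- cranioshape:::.label_components_3d(as.logical(clean$voxels),
                                             dim(clean$voxels))
  expect_gt(attr(lab0, "n_components"), 1L)
  expect_identical(attr(lab1, "n_components"), 1L)
  expect_identical(clean$voxels, mask$voxels)
})

test_that("denoise with zero parameters is the identity", {
  ph <- fx_small_phantom()
  mask <- segment_bone(ph$volume, 167)
  out <- denoise(mask, min_component_voxels = 0, smoothing_sigma_mm = 0)
  expect_identical(out$voxels, mask$voxels)
})

test_that("Gaussian smoothing preserves a solid ball as one component", {
  n <- 25
  xs <- seq(-12, 12, length.out = n)
  g <- expand.grid(x = xs, y = xs, z = xs)
  ball <- array(sqrt(g$x^2 + g$y^2 + g$z^2) <= 8, c(n, n, n))
  out <- denoise(binary_mask(ball), min_component_voxels = 0,
                 smoothing_sigma_mm = 1)
  lab <- cranioshape:::.label_components_3d(as.logical(out$voxels), dim(ball))
  expect_identical(attr(lab, "n_components"), 1L)
  expect_true(out$voxels[13, 13, 13])
})

test_that("extract_surface recovers a ball surface to within 5% area", {
  n <- 49
  xs <- seq(-24, 24, length.out = n)
  g <- expand.grid(x = xs, y = xs, z = xs)
  ball <- array(sqrt(g$x^2 + g$y^2 + g$z^2) <= 20, c(n, n, n))
  mesh <- extract_surface(binary_mask(ball, spacing = c(1, 1, 1),
                                      origin = c(-24, -24, -24)))
  expect_lt(abs(sum(face_areas(mesh)) - 4 * pi * 400) / (4 * pi * 400), 0.05)
  expect_true(is_closed_mesh(mesh))
  expect_gt(mesh_volume(mesh), 0) # outward orientation
})

test_that("a spherical shell yields exactly two surface components", {
  n <- 41
  xs <- seq(-20, 20, length.out = n)
  g <- expand.grid(x = xs, y = xs, z = xs)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  shell <- array(r <= 16 & r >= 10, c(n, n, n))
  mesh <- extract_surface(binary_mask(shell))
  expect_identical(attr(mesh_components(mesh), "n_components"), 2L)
})

test_that("degenerate masks raise a no-surface error", {
  expect_error(extract_surface(binary_mask(array(FALSE, c(4, 4, 4)))),
               class = "cranioshape_nosurface_error")
  expect_error(extract_surface(binary_mask(array(TRUE, c(4, 4, 4)))),
               class = "cranioshape_nosurface_error")
})

test_that("vertex coordinates scale linearly with voxel spacing", {
  n <- 21
  xs <- seq_len(n) - 11
  g <- expand.grid(x = xs, y = xs, z = xs)
  ball <- array(sqrt(g$x^2 + g$y^2 + g$z^2) <= 7, c(n, n, n))
  m1 <- extract_surface(binary_mask(ball, spacing = c(1, 1, 1)))
  m2 <- extract_surface(binary_mask(ball, spacing = c(2, 2, 2)))
  expect_equal(m2$vertices, 2 * m1$vertices, tolerance = 1e-12)
  expect_identical(m2$faces, m1$faces)
})
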