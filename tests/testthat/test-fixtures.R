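test_that("test-object specs enforce their geometric invariants", {
  expect_error(test_object_spec(bulge_radii = c(4, 6, 8, 10, 10)),
               class = "cranioshape_spec_error")
  expect_error(test_object_spec(hole_radius = 7),
               class = "cranioshape_spec_error")
  expect_error(
    test_object_spec(bulge_directions = rbind(
      dir_sph(0, 25), dir_sph(10, 25), dir_sph(144, 25),
      dir_sph(216, 25), dir_sph(288, 25))),
    class = "cranioshape_spec_error")
})

test_that("the test object is watertight and outward-oriented", {
  obj <- fx_test_object()
  expect_true(is_closed_mesh(obj))
  expect_gt(mesh_volume(obj), 4 / 3 * pi * 50^3) # base sphere plus bulges
  expect_true(all(face_areas(obj) > 0))
})

test_that("bulge apexes carry sphere curvature of their own radius", {
  obj <- fx_test_object()
  f <- fx_test_object_field()
  feats <- attr(obj, "features")
  for (i in which(feats$name != "hole")) {
    k <- f$kappa_g[feats$vertex[i]]
    expect_lt(abs(k - 1 / feats$radius[i]^2) * feats$radius[i]^2, 0.1)
    expect_identical(f$orientation_sign[feats$vertex[i]], 1L)
  }
})

test_that("the hole is concave where the equal bulge is convex", {
  obj <- fx_test_object()
  f <- fx_test_object_field()
  hole <- fx_feature("hole")
  bulge <- fx_feature("bulge_r10")
  expect_identical(f$orientation_sign[hole], -1L)
  expect_identical(f$orientation_sign[bulge], 1L)
  expect_lt(abs(f$kappa_g[hole] - 0.01) / 0.01, 0.1)
  expect_equal(f$scaled_value[hole], -f$scaled_value[bulge], tolerance = 0.1)
})

test_that("phantom volumes match the analytic ellipsoid shell", {
  spec <- fx_small_phantom_spec()
  ph <- make_phantom_volume(spec)
  mask <- segment_bone(ph$volume, 167)
  d <- dim(mask$voxels)
  pts <- cbind(
    ph$volume$origin[1] + (rep(seq_len(d[1]), times = d[2] * d[3]) - 1) * spec$voxel_spacing[1],
    ph$volume$origin[2] + (rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 1) * spec$voxel_spacing[2],
    ph$volume$origin[3] + (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) * spec$voxel_spacing[3])
  q <- sweep(pts, 2, spec$centre)
  a <- spec$outer_semi_axes
  ai <- a - spec$shell_thickness
  inside_out <- rowSums(sweep(q, 2, a, "/")^2) <= 1
  inside_in <- rowSums(sweep(q, 2, ai, "/")^2) <= 1
  expect_identical(as.vector(mask$voxels), inside_out & !inside_in)
  # voxelized shell volume close to the analytic one
  vol_analytic <- 4 / 3 * pi * (prod(a) - prod(ai))
  vol_mask <- sum(mask$voxels) * prod(spec$voxel_spacing)
  expect_lt(abs(vol_mask - vol_analytic) / vol_analytic, 0.05)
})

test_that("phantom landmarks sit inside the cavity, symmetric in x", {
  ph <- fx_small_phantom()
  spec <- fx_small_phantom_spec()
  q <- function(p) sum(((p - spec$centre) /
                          (spec$outer_semi_axes - spec$shell_thickness))^2)
  expect_lt(q(ph$landmarks$sella), 1)
  expect_equal((ph$landmarks$clinoid_left - spec$centre) * c(-1, 1, 1),
               ph$landmarks$clinoid_right - spec$centre)
})

test_that("the symmetric skull mesh mirrors about the y-z plane", {
  sk <- fx_skull()
  expect_true(is_closed_mesh(sk))
  refl <- sk$vertices %*% diag(c(-1, 1, 1))
  idx <- seq(1, nrow(refl), by = 37)
  d <- vapply(idx, function(i)
    sqrt(min(colSums((t(sk$vertices) - refl[i, ])^2))), 0)
  expect_lt(max(d), 2 * 1.9) # two grid steps
  av <- attr(sk, "apex_vertex")
  mv <- attr(sk, "mirror_vertex")
  expect_lt(max(abs(sk$vertices[av, ] * c(-1, 1, 1) - sk$vertices[mv, ])), 2)
})

test_that("curvature agrees between the temple apex and its mirror", {
  sk <- fx_skull()
  f <- fx_skull_field()
  av <- attr(sk, "apex_vertex")
  mv <- attr(sk, "mirror_vertex")
  expect_lt(abs(f$kappa_g[av] - f$kappa_g[mv]) / abs(f$kappa_g[mv]), 0.05)
})

test_that("asymmetric specs are rejected for the symmetric skull", {
  spec <- phantom_spec(asymmetry_bulge = list(direction = c(1, 0, 0),
                                              radius = 10, amplitude = 5))
  expect_error(make_symmetric_skull_mesh(spec),
               class = "cranioshape_spec_error")
})

test_that("rigid_copy is an exact rotation with index identity", {
  obj <- icosphere(2)
  full <- rigid_copy(obj, c(0, 0, 1), 360)
  expect_lt(max(abs(full$vertices - obj$vertices)), 1e-9)
  twice <- rigid_copy(rigid_copy(obj, c(0, 0, 1), 45), c(0, 0, 1), 45)
  once <- rigid_copy(obj, c(0, 0, 1), 90)
  expect_lt(max(abs(twice$vertices - once$vertices)), 1e-9)
  rot <- rigid_copy(obj, c(1, 0, 0), 33)
  expect_lt(max(abs(sqrt(rowSums(rot$vertices^2)) - 1)), 1e-12)
  expect_identical(rot$faces, obj$faces)
  # anti-clockwise seen from +z: +x goes towards +y
  ex <- rigid_copy(triangle_mesh(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                                 matrix(c(1, 2, 3), 1)), c(0, 0, 1), 90)
  expect_equal(as.numeric(ex$vertices[1, ]), c(0, 1, 0), tolerance = 1e-12)
})

test_that("fixture generation is deterministic", {
  spec <- test_object_spec(mesh_resolution = 40)
  a <- make_test_object(spec)
  b <- make_test_object(spec)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  p1 <- make_phantom_volume(fx_small_phantom_spec())
  p2 <- make_phantom_volume(fx_small_phantom_spec())
  expect_identical(p1$volume$voxels, p2$volume$voxels)
})

test_that("meshes round-trip through PLY and OBJ", {
  mesh <- icosphere(2)
  q <- seq_len(nrow(mesh$vertices)) / 10
  ply_bin <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, ply_bin, binary = TRUE, quality = q)
  back <- read_ply(ply_bin)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(back$faces, mesh$faces)
  expect_equal(attr(back, "quality"), q, tolerance = 1e-6)
  ply_asc <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, ply_asc, binary = FALSE)
  expect_equal(read_ply(ply_asc)$vertices, mesh$vertices, tolerance = 1e-6)
  obj_path <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, obj_path)
  expect_equal(read_obj(obj_path)$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(read_obj(obj_path)$faces, mesh$faces)
})
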