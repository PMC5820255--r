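test_that("gather_patch matches a brute-force centroid scan", {
  mesh <- icosphere(3)
  cen <- face_centroids(mesh)
  set.seed(2)
  for (v in sample.int(nrow(mesh$vertices), 5)) {
    got <- gather_patch(mesh, v, 0.2)
    want <- which(sqrt(colSums((t(cen) - mesh$vertices[v, ])^2)) <= 0.2)
    expect_identical(sort(got), want)
  }
  expect_identical(sort(gather_patch(mesh, 1, 10)),
                   seq_len(nrow(mesh$faces)))
  expect_error(gather_patch(mesh, 1, 1e-9),
               class = "cranioshape_support_error")
})

test_that("fit_quadric recovers an exact sphere", {
  # a patch whose face centroids lie exactly on the sphere |x| = 2:
  # one tiny tangent triangle centred on each sample point
  set.seed(8)
  pts <- matrix(stats::rnorm(120), ncol = 3)
  pts <- 2 * pts / sqrt(rowSums(pts^2))
  V <- NULL
  F <- NULL
  e <- 0.01
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    u <- c(-p[2], p[1], 0)
    if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
    u <- u / sqrt(sum(u^2))
    v <- c(p[2] * u[3] - p[3] * u[2], p[3] * u[1] - p[1] * u[3],
           p[1] * u[2] - p[2] * u[1])
    v <- v / sqrt(sum(v^2))
    V <- rbind(V, p + e * u, p - e * (u / 2) + e * v * sqrt(3) / 2,
               p - e * (u / 2) - e * v * sqrt(3) / 2)
    F <- rbind(F, 3 * (i - 1) + 1:3)
  }
  mesh <- triangle_mesh(V, F)
  q <- fit_quadric(mesh, seq_len(nrow(F)))
  held <- matrix(stats::rnorm(300), ncol = 3)
  held <- 2 * held / sqrt(rowSums(held^2))
  scale_ref <- sqrt(sum(q$coef^2)) # unit by construction
  resid <- vapply(seq_len(nrow(held)), function(i) {
    p <- held[i, ]
    abs(as.numeric(p %*% q$A %*% p + sum(q$b * p) + q$c)) / scale_ref
  }, 0)
  expect_lt(max(resid), 1e-6)
  expect_equal(gaussian_curvature_at(q, c(0, 0, 2)), 1 / 4, tolerance = 1e-6)
})

test_that("a planar patch degenerates to a plane, collinear data errors", {
  plane <- graph_mesh(function(x, y) 0 * x, n = 15)
  q <- fit_quadric(plane, seq_len(nrow(plane$faces)))
  expect_lt(norm(q$A, "F"), 1e-6 * sqrt(sum(q$b^2)))
  line <- triangle_mesh(
    cbind(c(0, 1, 2, 3, 0, 1, 2, 3), c(0, 0, 0, 0, 0, 0, 0, 0),
          c(0, 0, 0, 0, 1e-12, 1e-12, 1e-12, 1e-12)),
    rbind(c(1, 2, 5), c(2, 3, 6), c(3, 4, 7)))
  expect_error(fit_quadric(line, 1:3),
               class = "cranioshape_ambiguity_error")
})

test_that("Goldman's formula gives closed-form curvatures", {
  sphere_q <- structure(list(A = diag(3), b = c(0, 0, 0), c = -1),
                        class = "quadric_coefficients")
  expect_equal(gaussian_curvature_at(sphere_q, c(0, 0, 1)), 1)
  plane_q <- structure(list(A = matrix(0, 3, 3), b = c(0, 0, 1), c = 0),
                       class = "quadric_coefficients")
  expect_equal(gaussian_curvature_at(plane_q, c(3, -2, 0)), 0)
  # saddle z = x^2 - y^2 as F = z - x^2 + y^2: K = -4 at the origin
  saddle_q <- structure(list(A = diag(c(-1, 1, 0)), b = c(0, 0, 1), c = 0),
                        class = "quadric_coefficients")
  expect_equal(gaussian_curvature_at(saddle_q, c(0, 0, 0)), -4)
  centre_q <- structure(list(A = diag(3), b = c(0, 0, 0), c = 0),
                        class = "quadric_coefficients")
  expect_error(gaussian_curvature_at(centre_q, c(0, 0, 0)),
               class = "cranioshape_singular_error")
})

test_that("scale_curvature maps curvature to signed log radius", {
  sc <- scale_curvature(1, 1)
  expect_equal(sc$signed_radius, 1)
  expect_equal(sc$scaled_value, log(2))
  expect_equal(scale_curvature(0.01, 1)$signed_radius, 10)
  concave <- scale_curvature(1, -1)
  expect_equal(concave$signed_radius, -1)
  expect_equal(concave$scaled_value, -log(2))
  # odd in the orientation sign, for any curvature
  for (k in c(1e-12, 0.04, 3)) {
    expect_equal(scale_curvature(k, -1)$scaled_value,
                 -scale_curvature(k, 1)$scaled_value)
  }
  # flooring bounds the radius at flat points
  expect_equal(scale_curvature(0, 1)$signed_radius, 1e4)
  # monotone increasing in signed radius
  ks <- c(4, 1, 0.25, 0.01)
  sv <- scale_curvature(ks, rep(1, 4))$scaled_value
  expect_true(all(diff(sv) > 0))
})

test_that("sphere fields are accurate at 15 mm patches for R in 20..80", {
  for (R in c(20, 50, 80)) {
    sph <- icosphere(4)
    sph$vertices <- sph$vertices * R
    f <- curvature_field(sph, 15)
    ok <- abs(f$kappa_g - 1 / R^2) < 0.05 / R^2
    expect_gt(mean(ok), 0.95)
    expect_true(all(f$orientation_sign == 1))
    expect_true(all(f$signed_radius > 0))
  }
})

test_that("curvature is invariant to rigid rotation", {
  sph <- icosphere(3)
  sph$vertices <- sph$vertices * 50
  f0 <- curvature_field(sph, 15)
  f1 <- curvature_field(rigid_copy(sph, c(1, 1, 1) / sqrt(3), 71), 15)
  expect_lt(max(abs(f0$kappa_g - f1$kappa_g)), 1e-6)
})

test_that("torus sign pattern: positive outside, negative inside", {
  tor <- torus_mesh(R = 40, r = 15)
  f <- curvature_field(tor, 6)
  rho <- sqrt(tor$vertices[, 1]^2 + tor$vertices[, 2]^2)
  outer_eq <- which(rho > 54.5)
  inner_eq <- which(rho < 25.5)
  expect_gt(length(outer_eq), 0)
  expect_gt(length(inner_eq), 0)
  expect_true(all(f$kappa_g[outer_eq] > 0))
  expect_true(all(f$kappa_g[inner_eq] < 0))
})

test_that("estimated curvature scales as 1/s^2 under mesh scaling", {
  sph <- icosphere(4)
  sph$vertices <- sph$vertices * 40
  f1 <- curvature_field(sph, 10)
  sph2 <- sph
  sph2$vertices <- sph2$vertices * 2
  f2 <- curvature_field(sph2, 20)
  ratio <- median(f1$kappa_g / f2$kappa_g)
  expect_lt(abs(ratio - 4) / 4, 0.05)
})

test_that("larger patches damp noise on a noisy sphere", {
  set.seed(77)
  sph <- icosphere(4)
  noise <- 1 + stats::rnorm(nrow(sph$vertices), sd = 0.004)
  sph$vertices <- sph$vertices * 50 * noise
  err <- vapply(c(5, 15), function(r) {
    f <- curvature_field(sph, r)
    mean(abs(f$kappa_g - 1 / 2500)) * 2500
  }, 0)
  expect_lte(err[2], err[1])
})

test_that("unsupported vertices inherit their nearest supported neighbour", {
  # two components: a fine sphere and a tiny far-away triangle patch that
  # cannot support a fit
  sph <- icosphere(3)
  tiny <- triangle_mesh(rbind(c(100, 0, 0), c(101, 0, 0), c(100, 1, 0),
                              c(101, 1, 0), c(100, 0, 1), c(101, 0, 1)),
                        rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 5),
                              c(3, 6, 5), c(2, 6, 4), c(1, 5, 2)))
  both <- triangle_mesh(rbind(sph$vertices, tiny$vertices),
                        rbind(sph$faces, tiny$faces + nrow(sph$vertices)))
  f <- curvature_field(both, 0.4)
  expect_true(any(!f$supported))
  expect_false(any(is.na(f$kappa_g)))
})

test_that("curvature fields serialize through CSV unchanged", {
  sph <- icosphere(2)
  f <- curvature_field(sph, 0.8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curvature_field(f, path)
  back <- read_curvature_field(path, radius_mm = 0.8)
  expect_equal(back$kappa_g, f$kappa_g, tolerance = 1e-12)
  expect_equal(back$scaled_value, f$scaled_value, tolerance = 1e-12)
  expect_identical(back$supported, f$supported)
})
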