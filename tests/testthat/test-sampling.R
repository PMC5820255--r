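test_that("icosphere subdivision has the closed-form vertex counts", {
  for (L in 0:4) {
    s <- icosphere(L)
    expect_identical(nrow(s$vertices), as.integer(10 * 4^L + 2))
    expect_identical(nrow(s$faces), as.integer(20 * 4^L))
    expect_lt(max(abs(sqrt(rowSums(s$vertices^2)) - 1)), 1e-12)
    expect_true(is_closed_mesh(s))
  }
  expect_gt(mesh_volume(icosphere(2)), 0) # outward orientation
  expect_error(icosphere(-1), class = "cranioshape_input_error")
})

test_that("hemisphere sampling keeps the equator and unit directions", {
  h <- build_hemisphere_sampling(3)
  expect_lt(max(abs(sqrt(rowSums(h$directions^2)) - 1)), 1e-12)
  expect_false(anyDuplicated(round(h$directions, 12)) > 0)
  expect_true(all(h$faces >= 1 & h$faces <= nrow(h$directions)))
  # equatorial directions (z == 0) must survive the epsilon cut
  full <- icosphere(3)
  n_eq <- sum(abs(full$vertices[, 3]) < 1e-12)
  expect_gt(n_eq, 0)
  expect_identical(sum(abs(h$directions[, 3]) < 1e-12), n_eq)
  expect_true(all(h$directions[, 3] > -0.05))
})

test_that("Moller-Trumbore resolves hits, misses and degenerate input", {
  tri <- rbind(c(-1, -1, 5), c(1, -1, 5), c(0, 2, 5))
  expect_equal(ray_triangle_intersect(c(0, 0, 0), c(0, 0, 1), tri), 5)
  # parallel to the triangle plane, offset
  expect_true(is.na(ray_triangle_intersect(c(0, 0, 0), c(1, 0, 0), tri)))
  # behind the origin
  expect_true(is.na(ray_triangle_intersect(c(0, 0, 10), c(0, 0, 1), tri)))
  degen <- rbind(c(0, 0, 1), c(1, 1, 1), c(2, 2, 1))
  expect_true(is.na(ray_triangle_intersect(c(0, 0, 0), c(0, 0, 1), degen)))
})

test_that("rays from the centre of a fine sphere return t near 1", {
  # rotate so mesh vertices do not coincide with sampling directions
  sph <- rigid_copy(icosphere(5), c(1, 0, 0), 10)
  samp <- build_hemisphere_sampling(3)
  rs <- resample_surface(sph, samp)
  expect_true(all(rs$valid))
  expect_lt(max(abs(c(rs$inner, rs$outer) - 1)), 1e-3)
})

test_that("concentric shells resolve into inner and outer radii", {
  s1 <- icosphere(4)
  s2 <- icosphere(4)
  shell <- triangle_mesh(rbind(0.9 * s1$vertices, 1.0 * s2$vertices),
                         rbind(s1$faces, s2$faces + nrow(s1$vertices)))
  rs <- resample_surface(shell, build_hemisphere_sampling(3))
  expect_true(all(rs$valid))
  expect_lt(max(abs(rs$inner - 0.9)), 1e-2)
  expect_lt(max(abs(rs$outer - 1.0)), 1e-2)
})

test_that("a single-layer sphere gives inner == outer", {
  rs <- resample_surface(icosphere(4), build_hemisphere_sampling(2))
  expect_true(all(rs$valid))
  expect_equal(rs$inner, rs$outer, tolerance = 1e-9)
})

test_that("rays through an opening are flagged invalid", {
  sph <- icosphere(5)
  apex_face <- sph$vertices[sph$faces[, 1], 3] > 0.98 &
    sph$vertices[sph$faces[, 2], 3] > 0.98 &
    sph$vertices[sph$faces[, 3], 3] > 0.98
  holed <- triangle_mesh(sph$vertices, sph$faces[!apex_face, , drop = FALSE])
  rs <- resample_surface(holed, build_hemisphere_sampling(3))
  expect_gt(sum(!rs$valid), 0)
  # invalid rays all point into the polar opening
  expect_true(all(rs$sampling$directions[!rs$valid, 3] > 0.97))
})

test_that("round trip: outer-layer points lie on the input surface", {
  sph <- icosphere(4)
  sph$vertices <- sph$vertices * 80
  rs <- resample_surface(sph, build_hemisphere_sampling(3))
  pts <- rs$sampling$directions * rs$outer
  d <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min(colSums((t(sph$vertices) - pts[i, ])^2))), 0)
  edge <- 80 * 1.05 / 2^4 # approximate level-4 edge length
  expect_lt(max(d), edge)
})

test_that("resampling is deterministic", {
  sph <- icosphere(3)
  samp <- build_hemisphere_sampling(2)
  a <- resample_surface(sph, samp)
  b <- resample_surface(sph, samp)
  expect_identical(a$inner, b$inner)
  expect_identical(a$outer, b$outer)
})

test_that("fill_missing is the identity on complete data", {
  rs <- resample_surface(icosphere(3), build_hemisphere_sampling(2))
  expect_identical(fill_missing(rs)$outer, rs$outer)
})

test_that("fill_missing interpolates constants exactly", {
  samp <- build_hemisphere_sampling(2)
  n <- nrow(samp$directions)
  valid <- rep(TRUE, n)
  valid[17] <- FALSE
  inner <- outer <- rep(1, n)
  inner[17] <- outer[17] <- NA
  filled <- fill_missing(sampled_surface(samp, inner, outer, valid))
  expect_equal(filled$outer[17], 1, tolerance = 1e-6)
  expect_true(all(filled$valid))
})

test_that("fill_missing obeys the discrete maximum principle", {
  samp <- build_hemisphere_sampling(3)
  n <- nrow(samp$directions)
  radii <- 80 + 10 * samp$directions[, 1] # linear field across the dome
  gap <- order(colSums((t(samp$directions) - samp$directions[100, ])^2))[1:10]
  valid <- rep(TRUE, n)
  valid[gap] <- FALSE
  inner <- outer <- radii
  inner[gap] <- outer[gap] <- NA
  filled <- fill_missing(sampled_surface(samp, inner, outer, valid))
  expect_true(all(filled$outer[gap] >= min(radii[-gap]) - 1e-9))
  expect_true(all(filled$outer[gap] <= max(radii[-gap]) + 1e-9))
  expect_error(fill_missing(sampled_surface(samp, rep(NA_real_, n),
                                            rep(NA_real_, n),
                                            rep(FALSE, n))),
               class = "cranioshape_input_error")
})

test_that("sampled surfaces serialize through CSV + JSON unchanged", {
  rs <- resample_surface(icosphere(3), build_hemisphere_sampling(2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sampled_surface(rs, path)
  back <- read_sampled_surface(path)
  expect_equal(back$inner, rs$inner, tolerance = 1e-12)
  expect_equal(back$outer, rs$outer, tolerance = 1e-12)
  expect_identical(back$valid, rs$valid)
})
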