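# Shared fixtures, built once per test run. The heavy meshes and their
# curvature fields are memoized because several files exercise the same
# objects.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_test_object <- function() fx("obj", function() make_test_object())

fx_test_object_field <- function()
  fx("obj_field", function() curvature_field(fx_test_object(), radius_mm = 5))

fx_rotated_object <- function()
  fx("rot", function() rigid_copy(fx_test_object(), c(0, 0, 1), 45))

fx_rotated_field <- function()
  fx("rot_field", function() curvature_field(fx_rotated_object(), radius_mm = 5))

fx_skull <- function() fx("skull", function() make_symmetric_skull_mesh())

fx_skull_field <- function()
  fx("skull_field", function() curvature_field(fx_skull(), radius_mm = 15))

fx_feature <- function(name) {
  feats <- attr(fx_test_object(), "features")
  feats$vertex[feats$name == name]
}

# small, fast phantom for the CT pipeline tests
fx_small_phantom_spec <- function()
  phantom_spec(outer_semi_axes = c(30, 37, 27), shell_thickness = 6,
               voxel_spacing = c(2, 2, 2))

fx_small_phantom <- function()
  fx("phantom", function() make_phantom_volume(fx_small_phantom_spec()))

# sphere mesh from the signed-distance iso-surfacer, element size ~h
sdf_sphere_mesh <- function(radius, h = 1.35) {
  sdf <- function(p) sqrt(rowSums(p^2)) - radius
  mesh_from_sdf(sdf, rep(-radius - 3, 3), rep(radius + 3, 3),
                ceiling(2 * (radius + 3) / h))
}

# parametric torus mesh: ring radius R in the x,y-plane, tube radius r
torus_mesh <- function(R = 40, r = 15, nu = 72, nv = 36) {
  us <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  vs <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  g <- expand.grid(u = us, v = vs)
  V <- cbind((R + r * cos(g$v)) * cos(g$u),
             (R + r * cos(g$v)) * sin(g$u),
             r * sin(g$v))
  id <- function(i, j) (j - 1L) * nu + i
  F <- matrix(0L, 2L * nu * nv, 3L)
  row <- 1L
  for (j in seq_len(nv)) {
    jn <- if (j == nv) 1L else j + 1L
    for (i in seq_len(nu)) {
      inx <- if (i == nu) 1L else i + 1L
      F[row, ] <- c(id(i, j), id(inx, j), id(inx, jn)); row <- row + 1L
      F[row, ] <- c(id(i, j), id(inx, jn), id(i, jn)); row <- row + 1L
    }
  }
  triangle_mesh(V, F)
}

# square-grid graph mesh of z = f(x, y) over [-1, 1]^2
graph_mesh <- function(f, n = 41, half_width = 1) {
  xs <- seq(-half_width, half_width, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  V <- cbind(g$x, g$y, f(g$x, g$y))
  id <- function(i, j) (j - 1L) * n + i
  F <- matrix(0L, 2L * (n - 1L)^2, 3L)
  row <- 1L
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    F[row, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)); row <- row + 1L
    F[row, ] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)); row <- row + 1L
  }
  triangle_mesh(V, F)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

ring_distance_between <- function(mesh, from, to, max_depth = 20L) {
  adj <- cranioshape:::mesh_adjacency_csr(mesh)
  d <- cranioshape:::.ring_distances_cpp(adj$ptr, adj$idx, from - 1L,
                                         as.integer(max_depth))
  d[to]
}

azimuth_deg <- function(p) atan2(p[2], p[1]) * 180 / pi
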