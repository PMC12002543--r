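test_that("discrete curvatures vanish on a plane and match a sphere", {
  g <- grid_mesh(nx = 15, ny = 15, spacing = 0.2)
  dc <- discrete_curvatures(g)
  interior <- grid_interior(15, 15)
  expect_lt(max(abs(dc$mean_H[interior])), 1e-6)
  expect_lt(max(abs(dc$gauss_K[interior])), 1e-6)

  sph <- icosphere(4, r = 5)
  dc <- discrete_curvatures(sph)
  expect_rel(median(dc$mean_H), 0.2, 0.15)
  expect_rel(median(dc$gauss_K), 0.04, 0.15)
})

test_that("angle-deficit total satisfies Gauss-Bonnet on closed meshes", {
  for (m in list(icosphere(3, r = 2), cube_mesh())) {
    nv <- nrow(m$vertices); nf <- nrow(m$faces)
    ne <- nrow(mesh_edges(m))
    chi <- nv - ne + nf                      # Euler characteristic
    dc <- discrete_curvatures(m)
    total <- sum(dc$gauss_K * dc$voronoi_area)
    expect_rel(total, 2 * pi * chi, 0.01)
  }
})

test_that("quadric-fit principal curvatures match sphere and cylinder", {
  sph <- icosphere(4, r = 10)
  pc <- principal_curvatures_quadric(sph)
  expect_rel(median(pc$k_min), 0.1, 0.15)
  expect_rel(median(pc$k_max), 0.1, 0.15)
  expect_true(all(pc$k_min <= pc$k_max + 1e-12))

  cyl <- cylinder_mesh(r = 5, h = 10, edge = 0.4)
  pc <- principal_curvatures_quadric(cyl)
  interior <- cylinder_interior(cyl, 10, margin = 2)
  expect_lt(abs(median(pc$k_min[interior])), 0.03)       # flat axis
  expect_rel(median(pc$k_max[interior]), 0.2, 0.15)
})

test_that("a Gaussian bump is convex at the apex, concave on the flank", {
  h <- 0.8; sigma <- 1.5
  m <- bump_patch(h = h, sigma = sigma, half = 6, spacing = 0.2)
  pc <- principal_curvatures_quadric(m)
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  apex <- which.min(r)
  # closed form at the apex: both curvatures h / sigma^2
  expect_rel(pc$k_min[apex], h / sigma^2, 0.2)
  expect_gt(pc$k_min[apex], 0)
  flank <- which(abs(r - 2 * sigma) < 0.2)
  expect_lt(median(pc$k_min[flank]), 0)
})

test_that("principal curvatures are rigid-invariant and scale as 1/s", {
  set.seed(5)
  sph <- icosphere(3, r = 5)
  pc0 <- principal_curvatures_quadric(sph)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rot <- sph; rot$vertices <- sph$vertices %*% q + 1.5
  pc1 <- principal_curvatures_quadric(rot)
  expect_equal(pc1$k_min, pc0$k_min, tolerance = 1e-6)

  big <- sph; big$vertices <- sph$vertices * 2
  pc2 <- principal_curvatures_quadric(big, neighborhood_scale = 3)
  pc0s <- principal_curvatures_quadric(sph, neighborhood_scale = 3)
  expect_equal(median(pc2$k_max), median(pc0s$k_max) / 2, tolerance = 0.01)
})

test_that("quadric curvature error shrinks with resolution (scaled support)", {
  # spheres sampled from the true surface at ~0.66 and ~0.16 mm edges
  err <- vapply(c(3, 5), function(subdiv) {
    m <- icosphere(subdiv, r = 5)
    pc <- principal_curvatures_quadric(m, neighborhood_scale = 3)
    median(abs(pc$k_max - 0.2))
  }, 0.0)
  expect_lt(err[2], err[1])
})

test_that("equalization follows the mid-rank formula and its invariances", {
  expect_equal(equalize_field(c(3, 1, 2)), c(5, 1, 3) / 6)
  expect_equal(equalize_field(rep(7, 5)), rep(0.5, 5))
  x <- c(0.3, -2, 5, 1.1, 0.2)
  expect_equal(equalize_field(x), equalize_field(exp(x)))   # monotone map
  eq <- equalize_field(x)
  expect_equal(equalize_field(eq), eq)                      # idempotent
  expect_true(all(eq >= 0 & eq <= 1))
  expect_error(equalize_field(c(1, NA)), "finite")
  expect_error(equalize_field(numeric(0)), "empty")
})

test_that("the quality ramp hits its red / green / blue anchors", {
  m <- grid_mesh(3, 3, 1)
  out <- colorize_field(m, c(0, 0.5, 1, rep(0.5, 6)), map = "quality_ramp")
  expect_equal(out$color[1, ], c(1, 0, 0))
  expect_equal(out$color[2, ], c(0, 1, 0))
  expect_equal(out$color[3, ], c(0, 0, 1))
  qc <- colorize_field(m, c(-2, 0, 2, rep(0, 6)), map = "curvature_qc")
  expect_equal(qc$color[1, ], c(1, 0, 0))    # strong depression
  expect_equal(qc$color[2, ], c(0, 1, 0))    # flat
  expect_equal(qc$color[3, ], c(0, 0, 1))    # strong projection
})
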