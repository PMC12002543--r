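test_that("clean_mesh welds duplicates, drops degenerate faces, is idempotent", {
  m <- cube_mesh()
  # explode: each face gets its own three vertices (24 pre-weld for 12 tris
  # is the textbook case; here 36 corners)
  v <- m$vertices[t(m$faces), ]
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  exploded <- triangle_mesh(v, f)
  cleaned <- clean_mesh(exploded)
  expect_equal(nrow(cleaned$vertices), 8L)
  expect_equal(measure_area(cleaned), measure_area(m), tolerance = 1e-12)

  # repeated-index face is removed
  bad <- triangle_mesh(m$vertices, rbind(m$faces, c(1L, 1L, 2L)))
  expect_equal(nrow(clean_mesh(bad)$faces), 12L)

  # idempotence
  again <- clean_mesh(cleaned)
  expect_equal(again$vertices, cleaned$vertices)
  expect_equal(again$faces, cleaned$faces)
})

test_that("resolution report flags the 0.3 / 0.2 mm gates correctly", {
  g <- grid_mesh(spacing = 0.2)
  r <- estimate_resolution(g)
  expect_equal(r$median_edge_length, 0.2, tolerance = 1e-9)
  expect_true(r$passes_min)
  expect_true(r$passes_recommended)

  g2 <- g; g2$vertices <- g2$vertices * 2
  r2 <- estimate_resolution(g2)
  expect_equal(r2$median_edge_length, 0.4, tolerance = 1e-9)
  expect_false(r2$passes_min)
  expect_true(r$median_edge_length <= r$p95_edge_length)
})

test_that("resolution median matches a brute-force edge enumeration", {
  m <- icosphere(2, r = 3)
  # independent enumeration: every face edge as a sorted pair
  pairs <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                        pmax(pairs[, 1], pairs[, 2])))
  lens <- sqrt(rowSums((m$vertices[pairs[, 1], ] -
                          m$vertices[pairs[, 2], ])^2))
  expect_equal(estimate_resolution(m)$median_edge_length, median(lens))
})

test_that("measure_area matches closed forms and is additive", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  expect_equal(measure_area(tri), 0.5, tolerance = 1e-15)

  sph <- icosphere(4, r = 1)
  expect_rel(measure_area(sph), 4 * pi, 0.01)

  m <- cube_mesh()
  half <- seq_len(6)
  expect_equal(measure_area(m, half) + measure_area(m, 7:12),
               measure_area(m), tolerance = 1e-12)
  expect_equal(measure_area(m, half), measure_area(m) / 2,
               tolerance = 1e-12)
  expect_error(measure_area(m, 13L), "range")
})

test_that("area is invariant under rigid motion", {
  set.seed(11)
  m <- icosphere(2, r = 2)
  a0 <- measure_area(m)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    m2 <- m
    m2$vertices <- m$vertices %*% q + matrix(rnorm(3), nrow(m$vertices),
                                             3, byrow = TRUE)
    expect_rel(measure_area(m2), a0, 1e-9)
  }
})

test_that("resample_uniform hits the target band and preserves area", {
  sph <- resample_uniform(icosphere(4, r = 10), 0.5)  # ~0.5 mm start
  med0 <- estimate_resolution(sph)$median_edge_length
  expect_gt(med0, 0.3)
  out <- resample_uniform(sph, 0.2)
  med <- estimate_resolution(out)$median_edge_length
  expect_gt(med, 0.14)
  expect_lt(med, 0.26)
  expect_rel(measure_area(out), 4 * pi * 100, 0.05)

  # near-identity target
  same <- resample_uniform(sph, med0)
  expect_rel(measure_area(same), measure_area(sph), 0.05)

  expect_error(resample_uniform(sph, 0), "positive")
  expect_error(resample_uniform(sph, med0 / 20), "1/10")
})
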