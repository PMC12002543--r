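test_that("a bare phantom has zero true bump area and is reproducible", {
  sp <- phantom_spec(bumps = list(), noise_amplitude = 0,
                     target_edge_length = 0.3, seed = 4)
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$total_true_area_mm2, 0)
  expect_length(ph$truth$bump_vertex_labels, 0)

  ph2 <- generate_phantom(sp)
  expect_identical(ph$mesh$vertices, ph2$mesh$vertices)
  expect_identical(ph$mesh$faces, ph2$mesh$faces)

  # capsule area sanity: 2 pi r L + 4 pi r^2
  r <- 3.5; L <- 20
  expect_rel(measure_area(ph$mesh), 2 * pi * r * L + 4 * pi * r^2, 0.02)
})

test_that("the labeled footprint matches its closed-form area", {
  sigma <- 1.5; h <- 0.8
  sp <- phantom_spec(bumps = list(list(z = 0, theta = 0, sigma = sigma,
                                       height = h)),
                     noise_amplitude = 0, target_edge_length = 0.25,
                     seed = 8)
  ph <- generate_phantom(sp)
  # labels where h exp(-d^2 / 2 sigma^2) > 0.05 h, i.e. a geodesic disc of
  # radius sigma * sqrt(2 log 20); its flat-patch area is pi R^2
  R <- sigma * sqrt(2 * log(20))
  expect_rel(ph$truth$bump_area_mm2[1], pi * R^2, 0.2)
  expect_gt(ph$truth$total_true_area_mm2, 0)
})

test_that("footprint area grows with sigma at fixed height", {
  areas <- vapply(c(1.0, 1.4, 1.8), function(s) {
    sp <- phantom_spec(bumps = list(list(z = 0, theta = 0, sigma = s,
                                         height = 0.6)),
                       noise_amplitude = 0, target_edge_length = 0.3,
                       seed = 2)
    generate_phantom(sp)$truth$bump_area_mm2[1]
  }, 0.0)
  expect_true(all(diff(areas) > 0))
})

test_that("phantom noise perturbs geometry at the requested amplitude", {
  sp0 <- phantom_spec(noise_amplitude = 0, target_edge_length = 0.3, seed = 6)
  sp1 <- phantom_spec(noise_amplitude = 0.02, target_edge_length = 0.3, seed = 6)
  m0 <- generate_phantom(sp0)$mesh
  m1 <- generate_phantom(sp1)$mesh
  d <- sqrt(rowSums((m1$vertices - m0$vertices)^2))
  expect_rel(sqrt(mean(d^2)), 0.02, 0.2)   # rms displacement = amplitude
})

test_that("the standard battery has the documented structure", {
  batt <- standard_battery(10, seed = 2)
  expect_length(batt, 10L)
  counts <- vapply(batt, function(p) length(p$spec$bumps), 0L)
  expect_equal(counts, rep(c(0L, 1L, 2L, 3L, 4L), 2))
  expect_gte(sum(counts == 0L), 1L)       # at least one control
  res <- vapply(batt, function(p) p$spec$target_edge_length, 0.0)
  expect_length(unique(res), 2L)
  hs <- unlist(lapply(batt, function(p)
    vapply(p$spec$bumps, `[[`, 0.0, "height")))
  expect_true(all(hs >= 0.3 & hs <= 1.0))

  again <- standard_battery(10, seed = 2)
  expect_identical(batt[[4]]$mesh$vertices, again[[4]]$mesh$vertices)

  other <- standard_battery(10, seed = 6)
  expect_equal(vapply(other, function(p) length(p$spec$bumps), 0L), counts)
  expect_false(identical(other[[4]]$mesh$vertices, batt[[4]]$mesh$vertices))
})

test_that("phantom truth labels live inside the bump footprints", {
  ph <- small_phantom(bumps = list(
    list(z = -3, theta = 0.5, sigma = 1.2, height = 0.7),
    list(z = 3.5, theta = 3.5, sigma = 1.2, height = 0.7)), seed = 9)
  expect_false(ph$truth$overlapping)
  centres <- rbind(c(3 * cos(0.5), 3 * sin(0.5), -3),
                   c(3 * cos(3.5), 3 * sin(3.5), 3.5))
  for (b in 1:2) {
    lab <- ph$truth$bump_vertex_labels[[b]]
    d <- sqrt(colSums((t(ph$mesh$vertices[lab, ]) - centres[b, ])^2))
    expect_lt(max(d), 1.2 * sqrt(2 * log(20)) + 1.5)
  }
  expect_length(intersect(ph$truth$bump_vertex_labels[[1]],
                          ph$truth$bump_vertex_labels[[2]]), 0)
})
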