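test_that("selections round-trip through JSON and guard their mesh", {
  m <- icosphere(2, r = 3)
  sel <- vertex_selection(m, sample(seq_len(nrow(m$vertices)), 100),
                          label = "BSR-test")
  path <- file.path(tempdir(), "sel.json")
  write_selection(sel, path)
  sel2 <- read_selection(path)
  expect_equal(sel2$indices, sel$indices)
  expect_equal(sel2$label, "BSR-test")
  expect_equal(sel2$fingerprint, sel$fingerprint)

  other <- icosphere(1, r = 3)
  expect_error(extract_submesh(other, sel2), "fingerprint")

  empty <- vertex_selection(m, integer(0))
  expect_length(empty$indices, 0)
  write_selection(empty, path)
  expect_length(read_selection(path)$indices, 0)
})

test_that("brush selection honours its limits and matches Dijkstra", {
  g <- grid_mesh(nx = 11, ny = 11, spacing = 0.2)
  centre <- which(g$vertices[, 1] == 1 & g$vertices[, 2] == 1)

  tiny <- brush_select(g, centre, radius = 0.19)
  expect_equal(tiny$indices, centre)

  all_sel <- brush_select(g, centre, radius = 100)
  expect_equal(all_sel$indices, seq_len(nrow(g$vertices)))

  # oracle: igraph shortest paths over the same weighted edge graph
  e <- mesh_edges(g)
  w <- sqrt(rowSums((g$vertices[e[, 1], ] - g$vertices[e[, 2], ])^2))
  gr <- igraph::graph_from_edgelist(e, directed = FALSE)
  d <- igraph::distances(gr, v = centre, weights = w)[1, ]
  expect_equal(brush_select(g, centre, radius = 1.0)$indices,
               sort(which(d <= 1.0)))

  expect_error(brush_select(g, integer(0), 1), "seed")
  expect_error(brush_select(g, centre, 0), "positive")
})

test_that("brush selection is monotone in radius", {
  g <- grid_mesh(nx = 11, ny = 11, spacing = 0.2)
  prev <- integer(0)
  for (r in c(0.3, 0.6, 0.9, 1.5)) {
    cur <- brush_select(g, 61L, r)$indices
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("selection combination is set algebra", {
  m <- icosphere(2, r = 3)
  n <- nrow(m$vertices)
  set.seed(42)
  for (i in 1:5) {
    a <- vertex_selection(m, sample(n, 80))
    b <- vertex_selection(m, sample(n, 80))
    u <- combine_selections(a, b, "union")
    i2 <- combine_selections(a, b, "intersect")
    s <- combine_selections(a, b, "subtract")
    expect_equal(u$indices, combine_selections(b, a, "union")$indices)
    expect_equal(i2$indices, combine_selections(b, a, "intersect")$indices)
    expect_true(all(s$indices %in% a$indices))
    expect_false(any(s$indices %in% b$indices))
    expect_equal(length(u$indices),
                 length(a$indices) + length(b$indices) - length(i2$indices))
  }
  a <- vertex_selection(m, 1:50)
  expect_length(combine_selections(a, a, "subtract")$indices, 0)
  disj <- combine_selections(vertex_selection(m, 1:30),
                             vertex_selection(m, 31:60), "union")
  expect_length(disj$indices, 60)
})

test_that("submesh extraction keeps fully selected faces and fields", {
  m <- icosphere(2, r = 3)
  m$field <- seq_len(nrow(m$vertices)) / 10

  all_sel <- vertex_selection(m, seq_len(nrow(m$vertices)))
  sub <- extract_submesh(m, all_sel)
  expect_equal(nrow(sub$faces), nrow(m$faces))
  expect_equal(measure_area(sub), measure_area(m))

  one <- vertex_selection(m, m$faces[7, ])
  tri <- extract_submesh(m, one)
  expect_equal(nrow(tri$faces), 1L)
  expect_equal(tri$field, m$field[sort(m$faces[7, ])])

  half <- vertex_selection(m, which(m$vertices[, 3] > 0))
  subh <- extract_submesh(m, half)
  inside <- rep(FALSE, nrow(m$vertices)); inside[half$indices] <- TRUE
  fkeep <- which(inside[m$faces[, 1]] & inside[m$faces[, 2]] &
                 inside[m$faces[, 3]])
  expect_equal(measure_area(subh), measure_area(m, fkeep))

  lonely <- vertex_selection(m, 1L)
  expect_error(extract_submesh(m, lonely), "grow the selection")
})

test_that("lesion-sized components are flagged, never removed", {
  # one broad bump (footprint ~ 6 mm) -> one flag of about that size
  ph <- small_phantom(bumps = list(list(z = 0, theta = 0, sigma = 1.25,
                                        height = 0.9)), seed = 21)
  curv <- principal_curvatures_quadric(ph$mesh)
  bsr <- small_bsr(ph$mesh)
  flags <- flag_lesion_candidates(ph$mesh, bsr, curv)
  expect_equal(sum(flags$flagged), 1L)
  expect_gt(flags$diameter_mm[1], 4)
  expect_lt(flags$diameter_mm[1], 9)

  # smooth control -> nothing lesion-sized
  ctrl <- small_phantom(seed = 22)
  curv <- principal_curvatures_quadric(ctrl$mesh)
  flags <- flag_lesion_candidates(ctrl$mesh, small_bsr(ctrl$mesh), curv)
  expect_equal(sum(flags$flagged), 0L)

  # one small and one lesion-sized structure -> exactly one flag
  two <- small_phantom(bumps = list(
    list(z = -3.5, theta = 0, sigma = 0.6, height = 0.6),
    list(z = 3.5, theta = pi, sigma = 1.6, height = 0.8)), seed = 23)
  curv <- principal_curvatures_quadric(two$mesh)
  flags <- flag_lesion_candidates(two$mesh, small_bsr(two$mesh), curv)
  expect_equal(sum(flags$flagged), 1L)
})
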