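# Geometric fixtures built in code: cube, planar grid, icosphere,
# open cylinder, Gaussian bump patch.  All in mm.

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  dimnames(v) <- NULL
  f <- matrix(c(
    1, 3, 2,  2, 3, 4,    # z = 0
    5, 6, 7,  6, 8, 7,    # z = side
    1, 2, 5,  2, 6, 5,    # y = 0
    3, 7, 4,  4, 7, 8,    # y = side
    1, 5, 3,  3, 5, 7,    # x = 0
    2, 4, 6,  4, 8, 6     # x = side
  ), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

# regular triangulated grid in the z = 0 plane
grid_mesh <- function(nx = 11, ny = 11, spacing = 0.2) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- list()
  for (j in seq_len(ny - 1))
    for (i in seq_len(nx - 1)) {
      f[[length(f) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
      f[[length(f) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
    }
  triangle_mesh(v, do.call(rbind, f))
}

grid_interior <- function(nx = 11, ny = 11) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  which(g$x > 0 & g$x < nx - 1 & g$y > 0 & g$y < ny - 1)
}

# icosphere: subdivided icosahedron projected to radius r
icosphere <- function(subdiv = 3, r = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, t, 0,  1, t, 0,  -1, -t, 0,  1, -t, 0,
                0, -1, t,  0, 1, t,  0, -1, -t,  0, 1, -t,
                t, 0, -1,  t, 0, 1,  -t, 0, -1,  -t, 0, 1),
              ncol = 3, byrow = TRUE)
  f <- matrix(c(1, 12, 6,  1, 6, 2,  1, 2, 8,  1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3,  11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,  4, 3, 7,  4, 7, 9,  4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,  10, 9, 2),
              ncol = 3, byrow = TRUE)
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    edge_mid <- new.env()
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      m <- edge_mid[[key]]
      if (is.null(m)) {
        vlist[[length(vlist) + 1]] <<- (vlist[[a]] + vlist[[b]]) / 2
        m <- length(vlist)
        edge_mid[[key]] <- m
      }
      m
    }
    fnew <- matrix(0L, nf * 4, 3)
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      fnew[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- fnew
  }
  v <- v / sqrt(rowSums(v^2)) * r
  triangle_mesh(v, f)
}

# open cylinder (no caps) of radius r about the z axis
cylinder_mesh <- function(r = 5, h = 10, edge = 0.5) {
  nth <- max(8L, round(2 * pi * r / edge))
  nz <- max(2L, round(h / edge))
  zs <- seq(0, h, length.out = nz + 1)
  v <- NULL
  for (j in seq_along(zs)) {
    th <- 2 * pi * (seq_len(nth) - 1) / nth + (j %% 2) * pi / nth
    v <- rbind(v, cbind(r * cos(th), r * sin(th), zs[j]))
  }
  f <- list()
  for (j in seq_len(length(zs) - 1)) {
    o1 <- (j - 1) * nth; o2 <- j * nth
    for (i in seq_len(nth)) {
      i2 <- i %% nth + 1
      f[[length(f) + 1]] <- c(o1 + i, o1 + i2, o2 + i)
      f[[length(f) + 1]] <- c(o1 + i2, o2 + i2, o2 + i)
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

cylinder_interior <- function(mesh, h, margin) {
  which(mesh$vertices[, 3] > margin & mesh$vertices[, 3] < h - margin)
}

# z = h exp(-r^2 / (2 sigma^2)) bump on a plane patch
bump_patch <- function(h = 0.8, sigma = 1.5, half = 6, spacing = 0.2) {
  m <- grid_mesh(nx = 2 * half / spacing + 1, ny = 2 * half / spacing + 1,
                 spacing = spacing)
  v <- m$vertices
  v[, 1] <- v[, 1] - half; v[, 2] <- v[, 2] - half
  r2 <- v[, 1]^2 + v[, 2]^2
  v[, 3] <- h * exp(-r2 / (2 * sigma^2))
  triangle_mesh(v, m$faces)
}

# small fast phantom for module-level pipeline tests
small_phantom <- function(bumps = list(), seed = 1, noise = 0.01,
                          edge = 0.25) {
  generate_phantom(phantom_spec(
    base = list(type = "capsule", length = 14, radius = 3),
    bumps = bumps, noise_amplitude = noise,
    target_edge_length = edge, seed = seed))
}

small_bsr <- function(mesh) shaft_bsr(mesh, shaft_length = 14)

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected), tol * abs(expected))
}
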