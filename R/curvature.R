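# Curvature operators.  Two families are provided, mirroring how surface
# irregularities are found in practice: fast discrete estimates (cotangent
# Laplacian mean curvature and angle-deficit Gaussian curvature) used for
# QC colorization, and principal curvatures from local quadric fitting,
# whose minimum-curvature field drives the segmentation itself.

#' Discrete mean and Gaussian curvature
#'
#' Mean curvature is the half-norm of the cotangent-Laplacian vector over
#' mixed Voronoi areas, signed by agreement with the outward vertex
#' normal (positive = convex). Gaussian curvature is the angle deficit
#' (2\eqn{\pi} interior, \eqn{\pi} on boundary vertices) over the same
#' areas, so that the total over a closed mesh satisfies Gauss-Bonnet
#' exactly up to floating point.
#'
#' @param mesh a clean `vera_mesh`.
#' @return A list of class `vera_curvature` with per-vertex `mean_H`
#'   (1/mm), `gauss_K` (1/mm^2) and `voronoi_area` (mm^2); `k_min`/`k_max`
#'   are `NULL` (use [principal_curvatures_quadric()] for those).
#' @export
discrete_curvatures <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  if (nrow(f) == 0L) stop("mesh has no faces")

  # per-corner geometry
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  e12 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  e13 <- v[i3, , drop = FALSE] - v[i1, , drop = FALSE]
  e23 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE]
  l12 <- rowSums(e12^2); l13 <- rowSums(e13^2); l23 <- rowSums(e23^2)
  cr <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
              e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
              e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  dblA <- sqrt(rowSums(cr^2))
  dblA[dblA < 1e-300] <- 1e-300
  # cotangents of the angle opposite each edge
  cot3 <- rowSums(e12 * e13) / dblA              # angle at v1, opp edge 23
  cot1 <- rowSums(e23 * (-e12)) / dblA           # angle at v2, opp edge 13
  cot2 <- rowSums((-e13) * (-e23)) / dblA        # angle at v3, opp edge 12

  ang1 <- atan2(dblA, rowSums(e12 * e13))
  ang2 <- atan2(dblA, rowSums(e23 * (-e12)))
  ang3 <- atan2(dblA, rowSums((-e13) * (-e23)))

  # mixed Voronoi areas (Meyer et al.): circumcentric for non-obtuse
  # triangles, area/2 at the obtuse corner and area/4 elsewhere
  a_vor1 <- (l12 * cot2 + l13 * cot1) / 8
  a_vor2 <- (l12 * cot2 + l23 * cot3) / 8
  a_vor3 <- (l13 * cot1 + l23 * cot3) / 8
  tri_area <- dblA / 2
  obt1 <- ang1 > pi / 2; obt2 <- ang2 > pi / 2; obt3 <- ang3 > pi / 2
  any_obt <- obt1 | obt2 | obt3
  a1 <- ifelse(any_obt, ifelse(obt1, tri_area / 2, tri_area / 4), a_vor1)
  a2 <- ifelse(any_obt, ifelse(obt2, tri_area / 2, tri_area / 4), a_vor2)
  a3 <- ifelse(any_obt, ifelse(obt3, tri_area / 2, tri_area / 4), a_vor3)

  amix <- as.vector(tapply_sum(c(i1, i2, i3), c(a1, a2, a3), n))
  angsum <- as.vector(tapply_sum(c(i1, i2, i3), c(ang1, ang2, ang3), n))

  # Laplace vector: sum_j (cot_alpha + cot_beta) (v_i - v_j)
  lap <- matrix(0, n, 3)
  for (k in 1:3) {
    lap[, k] <- tapply_sum(i1, cot2 * (v[i1, k] - v[i2, k]) +
                                cot1 * (v[i1, k] - v[i3, k]), n) +
                tapply_sum(i2, cot2 * (v[i2, k] - v[i1, k]) +
                                cot3 * (v[i2, k] - v[i3, k]), n) +
                tapply_sum(i3, cot1 * (v[i3, k] - v[i1, k]) +
                                cot3 * (v[i3, k] - v[i2, k]), n)
  }

  nrm <- cpp_vertex_normals(v, f - 1L)
  lap_norm <- sqrt(rowSums(lap^2))
  sgn <- ifelse(rowSums(lap * nrm) >= 0, 1, -1)

  # boundary vertices close only part of the angle circle
  edges <- mesh_edges(mesh)
  ekey <- paste(edges[, 1], edges[, 2])
  allkey <- paste(pmin(c(i1, i2, i3), c(i2, i3, i1)),
                  pmax(c(i1, i2, i3), c(i2, i3, i1)))
  ecount <- table(factor(allkey, levels = ekey))
  bedges <- edges[as.vector(ecount) == 1L, , drop = FALSE]
  boundary <- rep(FALSE, n)
  boundary[unique(as.vector(bedges))] <- TRUE

  isolated <- amix <= 0
  if (any(isolated)) warning("isolated vertices assigned zero curvature")
  amix_safe <- ifelse(isolated, 1, amix)

  mean_H <- ifelse(isolated, 0, sgn * lap_norm / (4 * amix_safe))
  full <- ifelse(boundary, pi, 2 * pi)
  gauss_K <- ifelse(isolated, 0, (full - angsum) / amix_safe)

  structure(list(k_min = NULL, k_max = NULL, mean_H = mean_H,
                 gauss_K = gauss_K, voronoi_area = amix,
                 boundary = boundary),
            class = "vera_curvature")
}

tapply_sum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Principal curvatures by local quadric fitting
#'
#' For every vertex, neighbours within a geodesic radius of
#' `neighborhood_scale` median edge lengths are gathered (the radius grows
#' until at least 12 samples are available), a quadric height patch is
#' fitted by least squares in the vertex tangent frame, and the
#' eigenvalues of its shape operator give `k_min <= k_max`. Sign
#' convention: outward normals, so a convex projection has positive
#' curvature. Vertices with rank-deficient fits fall back to the discrete
#' mean curvature and are counted in a warning.
#'
#' @param mesh a clean `vera_mesh`.
#' @param neighborhood_radius fitting radius in mm (default 0.6). A fixed
#'   physical radius makes the curvature field - and everything selected
#'   from it - stable across meshes of different resolution, which is
#'   what lets measurements from differently resampled scans agree.
#' @param neighborhood_scale alternatively, a radius in multiples of the
#'   median edge length (minimum 2); overrides `neighborhood_radius`.
#' @return A `vera_curvature` list with `k_min`, `k_max`, `mean_H`,
#'   `gauss_K` populated.
#' @export
principal_curvatures_quadric <- function(mesh, neighborhood_radius = 0.6,
                                         neighborhood_scale = NULL) {
  med <- stats::median(edge_lengths(mesh))
  if (!is.null(neighborhood_scale)) {
    if (neighborhood_scale < 2) stop("`neighborhood_scale` must be >= 2")
    neighborhood_radius <- neighborhood_scale * med
  }
  if (neighborhood_radius <= 0) stop("`neighborhood_radius` must be > 0")
  res <- cpp_quadric_curvatures(mesh$vertices, mesh$faces - 1L,
                                radius = neighborhood_radius,
                                minpts = 12L)
  disc <- discrete_curvatures(mesh)
  bad <- res$fallback | !is.finite(res$k_min)
  if (any(bad)) {
    if (sum(bad) > 0.01 * length(bad))
      warning(sprintf("quadric fit fell back to discrete curvature at %d vertices",
                      sum(bad)))
    res$k_min[bad] <- disc$mean_H[bad]
    res$k_max[bad] <- disc$mean_H[bad]
  }
  structure(list(k_min = res$k_min, k_max = res$k_max,
                 mean_H = disc$mean_H, gauss_K = disc$gauss_K,
                 voronoi_area = disc$voronoi_area,
                 fallback = res$fallback),
            class = "vera_curvature")
}

#' @export
print.vera_curvature <- function(x, ...) {
  cat("<vera_curvature>",
      if (!is.null(x$k_min)) sprintf("k_min [%.4g, %.4g],",
                                     min(x$k_min), max(x$k_min)) else "",
      sprintf("mean_H [%.4g, %.4g]\n", min(x$mean_H), max(x$mean_H)))
  invisible(x)
}

#' Histogram equalization of a scalar field
#'
#' Rank-based transform to the unit interval: the value at mid-rank r of
#' N becomes (r - 0.5)/N, so distinct inputs map to a uniform grid and
#' ties share their mid-rank value (a constant field maps to 0.5). This
#' standardises the minimum-curvature field across specimens so a fixed
#' selection threshold has the same meaning everywhere.
#'
#' @param values finite numeric vector.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
equalize_field <- function(values) {
  if (length(values) < 1L) stop("empty field")
  if (!all(is.finite(values))) stop("field contains non-finite values")
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

#' Colorize a mesh from a scalar field
#'
#' `quality_ramp` maps `[0, 1]` through a linear red-green-blue ramp
#' (0 = red, 0.5 = green, 1 = blue), the rendering used for equalized
#' minimum curvature where the blue band marks projecting irregularities.
#' `curvature_qc` maps a signed field symmetrically about zero through the
#' same ramp (strong depressions red, flat green, strong projections
#' blue), the quick-look scheme used when checking a model before
#' selecting the broad region.
#'
#' @param mesh a `vera_mesh`.
#' @param field numeric per-vertex scalar.
#' @param map `"quality_ramp"` or `"curvature_qc"`.
#' @return The mesh with `color` (and `field`) populated.
#' @export
colorize_field <- function(mesh, field, map = c("quality_ramp", "curvature_qc")) {
  map <- match.arg(map)
  if (length(field) != n_vertices(mesh))
    stop("`field` must have one value per vertex")
  t <- if (map == "quality_ramp") {
    pmin(pmax(field, 0), 1)
  } else {
    mx <- max(abs(field))
    if (mx == 0) mx <- 1
    0.5 + 0.5 * pmin(pmax(field / mx, -1), 1)
  }
  lo <- t < 0.5
  u <- ifelse(lo, t / 0.5, (t - 0.5) / 0.5)
  color <- cbind(ifelse(lo, 1 - u, 0),
                 ifelse(lo, u, 1 - u),
                 ifelse(lo, 0, u))
  mesh$color <- color
  mesh$field <- as.numeric(field)
  mesh
}
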