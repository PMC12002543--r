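#' Triangle surface mesh
#'
#' The basic container of the package: a triangle mesh in millimetre units
#' with an optional per-vertex scalar field (e.g. a curvature value, stored
#' in PLY files as the `quality` property) and optional per-vertex RGB
#' colour in `[0, 1]`.
#'
#' @param vertices numeric N x 3 matrix of coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param field optional numeric vector of length N.
#' @param color optional numeric N x 3 matrix with entries in `[0, 1]`.
#' @return An object of class `vera_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, field = NULL, color = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
  } else {
    faces <- matrix(integer(0), 0L, 3L)
  }
  if (!is.null(field)) {
    field <- as.numeric(field)
    if (length(field) != nrow(vertices))
      stop("`field` must have one value per vertex")
  }
  if (!is.null(color)) {
    color <- as.matrix(color)
    if (nrow(color) != nrow(vertices) || ncol(color) != 3L)
      stop("`color` must be an N x 3 matrix")
  }
  structure(list(vertices = vertices, faces = faces,
                 field = field, color = color),
            class = "vera_mesh")
}

#' @export
print.vera_mesh <- function(x, ...) {
  cat(sprintf("<vera_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.null(x$field)) cat(", scalar field")
  if (!is.null(x$color)) cat(", vertex colors")
  cat("\n")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Unique undirected edges of a mesh
#'
#' @param mesh a `vera_mesh`.
#' @return Integer matrix with two columns (sorted vertex pairs), one row
#'   per unique edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Mesh fingerprint
#'
#' A short deterministic identifier combining vertex/face counts with a
#' hash of the (micron-rounded) coordinates, used to guard that vertex
#' selections are only ever applied to the mesh they were made on.
#'
#' @param mesh a `vera_mesh`.
#' @return A single character string.
#' @export
mesh_fingerprint <- function(mesh) {
  v <- round(mesh$vertices, 6)
  sums <- c(colSums(v), colSums(v * v), sum(v[, 1] * v[, 2] + v[, 3]))
  sprintf("%d-%d-%s", n_vertices(mesh), n_faces(mesh),
          paste(formatC(sums, digits = 10, format = "g"), collapse = ","))
}

#' Measure 3D surface area
#'
#' Sums triangle areas (half cross-product norm) over all faces or a
#' subset. Areas are in square millimetres and additive over disjoint
#' face sets.
#'
#' @param mesh a `vera_mesh`.
#' @param faces optional integer vector of face indices; default all.
#' @return Total area in mm^2.
#' @export
measure_area <- function(mesh, faces = NULL) {
  f <- mesh$faces
  if (!is.null(faces)) {
    faces <- as.integer(faces)
    if (length(faces) == 0L) return(0)
    if (min(faces) < 1L || max(faces) > nrow(f))
      stop("face index out of range")
    f <- f[faces, , drop = FALSE]
  }
  if (nrow(f) == 0L) return(0)
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

face_areas <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Clean a mesh
#'
#' Welds duplicate vertices (1e-6 mm tolerance), removes faces with
#' repeated indices or zero area, and drops unreferenced vertices. The
#' mapping from old to new vertex indices is attached as attribute
#' `vertex_map` (NA for dropped vertices) so existing selections can be
#' carried across.
#'
#' @param mesh a `vera_mesh`.
#' @return A cleaned `vera_mesh`.
#' @export
clean_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  vr <- round(v, 6)
  key <- paste(vr[, 1], vr[, 2], vr[, 3], sep = "/")
  first <- match(key, key)              # representative per coordinate
  keep_order <- which(first == seq_len(n))
  weld <- match(first, keep_order)      # old index -> welded index
  v2 <- v[keep_order, , drop = FALSE]
  f2 <- matrix(weld[f], ncol = 3L)
  fmap <- seq_len(nrow(f2))
  # drop degenerate faces (repeated indices or zero area)
  if (nrow(f2) > 0L) {
    ok <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
    f2 <- f2[ok, , drop = FALSE]
    fmap <- fmap[ok]
    if (nrow(f2) > 0L) {
      tmp <- triangle_mesh(v2, f2)
      pos <- face_areas(tmp) > 1e-14
      f2 <- f2[pos, , drop = FALSE]
      fmap <- fmap[pos]
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f2)))
  if (length(used) == 0L) used <- integer(0)
  newid <- rep(NA_integer_, nrow(v2))
  newid[used] <- seq_along(used)
  v3 <- v2[used, , drop = FALSE]
  f3 <- matrix(newid[f2], ncol = 3L)
  vmap <- newid[weld]
  field <- if (!is.null(mesh$field)) mesh$field[keep_order][used]
  color <- if (!is.null(mesh$color)) mesh$color[keep_order, , drop = FALSE][used, , drop = FALSE]
  out <- triangle_mesh(v3, f3, field = field, color = color)
  attr(out, "vertex_map") <- vmap
  attr(out, "face_map") <- fmap
  out
}

#' Estimate mesh resolution
#'
#' Resolution is summarised as the median unique-edge length, with the two
#' quality gates used for surface scans of bone: at most 0.30 mm (minimum)
#' and at most 0.20 mm (recommended).
#'
#' @param mesh a `vera_mesh` with at least one face.
#' @return A list of class `vera_resolution` with `median_edge_length`,
#'   `mean_edge_length`, `p95_edge_length` (mm) and the logical flags
#'   `passes_min`, `passes_recommended`.
#' @export
estimate_resolution <- function(mesh) {
  if (n_faces(mesh) < 1L) stop("mesh has no faces")
  len <- edge_lengths(mesh)
  med <- stats::median(len)
  out <- list(median_edge_length = med,
              mean_edge_length = mean(len),
              p95_edge_length = unname(stats::quantile(len, 0.95)),
              passes_min = med <= 0.30,
              passes_recommended = med <= 0.20)
  class(out) <- "vera_resolution"
  out
}

#' @export
print.vera_resolution <- function(x, ...) {
  cat(sprintf(
    "<resolution> median %.4f mm (mean %.4f, p95 %.4f) | <=0.30 mm: %s | <=0.20 mm: %s\n",
    x$median_edge_length, x$mean_edge_length, x$p95_edge_length,
    if (x$passes_min) "yes" else "NO", if (x$passes_recommended) "yes" else "no"))
  invisible(x)
}

#' Resample a mesh to a uniform target edge length
#'
#' Isotropic explicit remeshing: long edges are split, short edges
#' collapsed and vertices relaxed tangentially until the edge lengths
#' cluster around the target. Used to homogenise resolution across a
#' sample before curvature-based segmentation. Refuses targets below one
#' tenth of the current median edge length, which would fabricate surface
#' detail that the scan does not contain.
#'
#' @param mesh a `vera_mesh`.
#' @param target_edge_length desired edge length in mm.
#' @param iterations number of split/collapse/relax passes.
#' @return A cleaned `vera_mesh` (scalar field and colours are dropped:
#'   they are not defined on the new vertices).
#' @export
resample_uniform <- function(mesh, target_edge_length, iterations = 6L) {
  if (!is.numeric(target_edge_length) || length(target_edge_length) != 1L ||
      !is.finite(target_edge_length) || target_edge_length <= 0)
    stop("`target_edge_length` must be a positive number")
  med <- stats::median(edge_lengths(mesh))
  if (target_edge_length < med / 10)
    stop(sprintf(paste0("target edge length %.4g mm is below 1/10 of the ",
                        "current median (%.4g mm); refusing to fabricate detail"),
                 target_edge_length, med))
  res <- cpp_isotropic_remesh(mesh$vertices, mesh$faces - 1L,
                              target_edge_length, as.integer(iterations))
  clean_mesh(triangle_mesh(res$vertices, res$faces + 1L))
}
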