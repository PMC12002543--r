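# Vertex selections: the broader selection region (BSR) delineated around
# an enthesis-bearing structure, lesion masks to be subtracted from it,
# and the selections the segmentation derives.  A selection is tied to a
# specific mesh by fingerprint so it can never silently be applied to the
# wrong specimen, and it round-trips through a small JSON file so the one
# manual step of the protocol is auditable and replayable.

#' Create a vertex selection
#'
#' @param mesh the `vera_mesh` the selection refers to.
#' @param indices 1-based vertex indices (deduplicated and sorted).
#' @param label free-text label, e.g. `"BSR-OP-right"` or `"lesion-1"`.
#' @return An object of class `vera_selection`.
#' @export
vertex_selection <- function(mesh, indices, label = "selection") {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) > 0L &&
      (min(indices) < 1L || max(indices) > n_vertices(mesh)))
    stop("selection indices out of range for this mesh")
  structure(list(fingerprint = mesh_fingerprint(mesh),
                 indices = indices, label = label),
            class = "vera_selection")
}

#' @export
print.vera_selection <- function(x, ...) {
  cat(sprintf("<vera_selection> '%s': %d vertices\n", x$label,
              length(x$indices)))
  invisible(x)
}

check_selection <- function(mesh, selection) {
  if (!inherits(selection, "vera_selection"))
    stop("not a vera_selection")
  if (!identical(selection$fingerprint, mesh_fingerprint(mesh)))
    stop("selection fingerprint does not match this mesh; ",
         "it was made on a different (or modified) surface")
  invisible(TRUE)
}

#' Read a vertex selection from JSON
#'
#' @param path path to a selection JSON file.
#' @return A `vera_selection`.
#' @export
read_selection <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$fingerprint) || is.null(doc$indices))
    stop("not a selection file: ", path)
  structure(list(fingerprint = doc$fingerprint,
                 indices = sort(unique(as.integer(doc$indices))),
                 label = if (is.null(doc$label)) "selection" else doc$label),
            class = "vera_selection")
}

#' Write a vertex selection to JSON
#'
#' @param selection a `vera_selection`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(list(format = "vera-selection/1",
                            fingerprint = selection$fingerprint,
                            label = selection$label,
                            indices = selection$indices),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Geodesic brush selection
#'
#' Scripted surrogate for interactive marker-tool painting: selects every
#' vertex within an edge-weighted graph-geodesic distance of any seed.
#'
#' @param mesh a `vera_mesh`.
#' @param seeds 1-based seed vertex indices.
#' @param radius geodesic radius in mm.
#' @param label selection label.
#' @return A `vera_selection`.
#' @export
brush_select <- function(mesh, seeds, radius, label = "brush") {
  if (length(seeds) == 0L) stop("no seed vertices given")
  seeds <- as.integer(seeds)
  if (min(seeds) < 1L || max(seeds) > n_vertices(mesh))
    stop("seed index out of range")
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be positive")
  idx <- cpp_geodesic_ball(mesh$vertices, mesh$faces - 1L, seeds - 1L, radius)
  vertex_selection(mesh, idx, label = label)
}

#' Combine two selections
#'
#' Pure set algebra on the vertex index sets; `subtract` is how lesion
#' masks are removed from a BSR before measurement.
#'
#' @param selection_a,selection_b `vera_selection`s on the same mesh.
#' @param op `"union"`, `"intersect"` or `"subtract"`.
#' @param label label for the result.
#' @return A `vera_selection`.
#' @export
combine_selections <- function(selection_a, selection_b,
                               op = c("union", "intersect", "subtract"),
                               label = NULL) {
  op <- match.arg(op)
  if (!identical(selection_a$fingerprint, selection_b$fingerprint))
    stop("selections refer to different meshes")
  idx <- switch(op,
                union = union(selection_a$indices, selection_b$indices),
                intersect = intersect(selection_a$indices, selection_b$indices),
                subtract = setdiff(selection_a$indices, selection_b$indices))
  structure(list(fingerprint = selection_a$fingerprint,
                 indices = sort(unique(as.integer(idx))),
                 label = if (is.null(label))
                   paste(selection_a$label, op, selection_b$label)
                 else label),
            class = "vera_selection")
}

#' Extract the submesh spanned by a selection
#'
#' Keeps the faces whose three corners are all selected (the conservative
#' membership rule: no face area can leak outside the selected region),
#' reindexes vertices, and carries scalar field and colours through. The
#' original vertex and face indices are attached as attributes
#' `orig_vertices` and `orig_faces`.
#'
#' @param mesh a `vera_mesh`.
#' @param selection a non-empty `vera_selection` on `mesh`.
#' @return A `vera_mesh`.
#' @export
extract_submesh <- function(mesh, selection) {
  check_selection(mesh, selection)
  if (length(selection$indices) == 0L) stop("selection is empty")
  inside <- rep(FALSE, n_vertices(mesh))
  inside[selection$indices] <- TRUE
  fkeep <- which(inside[mesh$faces[, 1]] & inside[mesh$faces[, 2]] &
                 inside[mesh$faces[, 3]])
  if (length(fkeep) == 0L)
    stop("no face has all three vertices selected; ",
         "grow the selection (e.g. larger brush radius)")
  f <- mesh$faces[fkeep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  newid <- rep(NA_integer_, n_vertices(mesh))
  newid[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(newid[f], ncol = 3L),
                       field = if (!is.null(mesh$field)) mesh$field[used],
                       color = if (!is.null(mesh$color))
                         mesh$color[used, , drop = FALSE])
  attr(out, "orig_vertices") <- used
  attr(out, "orig_faces") <- fkeep
  out
}

#' Flag lesion-sized projecting components for operator review
#'
#' Within a selection (typically the BSR), finds connected components of
#' vertices whose equalized minimum curvature reaches the blue-band
#' threshold and reports each component's bounding-box diagonal.
#' Components larger than `flag_diameter` (default 4 mm) are flagged as
#' possible pathological or taphonomic lesions. Nothing is ever removed
#' automatically: the flags are input to operator judgement, and any
#' exclusion must be an explicit, documented decision.
#'
#' @param mesh a `vera_mesh`.
#' @param selection a `vera_selection` on `mesh` (the BSR).
#' @param curvature a `vera_curvature` with `k_min` computed on `mesh`.
#' @param blue_threshold equalized-field threshold (default 0.75).
#' @param flag_diameter diameter above which a component is flagged (mm).
#' @return A data.frame with one row per component: `n_vertices`,
#'   `diameter_mm`, `flagged`, plus a list-column `vertices`.
#' @export
flag_lesion_candidates <- function(mesh, selection, curvature,
                                   blue_threshold = 0.75,
                                   flag_diameter = 4.0) {
  check_selection(mesh, selection)
  if (is.null(curvature$k_min))
    stop("`curvature` has no k_min field; run principal_curvatures_quadric()")
  idx <- selection$indices
  if (length(idx) == 0L)
    return(data.frame(n_vertices = integer(0), diameter_mm = numeric(0),
                      flagged = logical(0)))
  eq <- equalize_field(curvature$k_min[idx])
  hot <- idx[eq >= blue_threshold]
  if (length(hot) == 0L)
    return(data.frame(n_vertices = integer(0), diameter_mm = numeric(0),
                      flagged = logical(0)))
  comps <- vertex_components(mesh, hot)
  diam <- vapply(comps, function(vs) bbox_diagonal(mesh$vertices[vs, , drop = FALSE]),
                 0.0)
  out <- data.frame(n_vertices = lengths(comps), diameter_mm = diam,
                    flagged = diam > flag_diameter)
  out$vertices <- comps
  out[order(-out$diameter_mm), , drop = FALSE]
}

# connected components (by shared mesh edges) of a vertex subset
vertex_components <- function(mesh, vertices) {
  inside <- rep(FALSE, n_vertices(mesh))
  inside[vertices] <- TRUE
  e <- mesh_edges(mesh)
  e <- e[inside[e[, 1]] & inside[e[, 2]], , drop = FALSE]
  ids <- sort(unique(c(vertices, as.vector(e))))
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(e), ids), ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  split(ids, memb[seq_along(ids)])
}

bbox_diagonal <- function(coords) {
  if (nrow(coords) == 0L) return(0)
  rng <- apply(coords, 2L, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}
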