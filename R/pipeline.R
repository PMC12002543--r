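# The segmentation chain: optional Taubin smoothing -> BSR isolation ->
# minimum-curvature field by quadric fitting -> rank equalization ->
# blue-band selection -> small-component removal -> area measurement.
# Everything after the manual BSR is deterministic, so identical inputs
# and parameters give bit-identical results.

#' Segmentation parameters
#'
#' All tunables of the measurement chain with their standard defaults.
#' `min_component_diameter` is the artifact-removal threshold: 2 mm by
#' default, reduced to 1 mm for small, already-smooth models (for which
#' `smooth_enabled = FALSE` is also the documented adaptation).
#'
#' @param smooth_enabled run the initial gentle smoothing pass. Meant for
#'   scans carrying small sharp artifacts; skip it for models that are
#'   already smooth (the documented adaptation for small smooth bones).
#' @param smooth_iterations Taubin passes (default 3).
#' @param neighborhood_radius quadric-fit radius in mm (default 0.6).
#'   Fixed in physical units so the curvature field is comparable across
#'   specimens and resolutions; the default keeps the fit diameter - and
#'   with it the spatial correlation of the curvature field - below the
#'   2 mm artifact-removal threshold, so noise-driven selections stay
#'   removable while bump-scale signal survives.
#' @param neighborhood_scale optional radius in median-edge multiples
#'   (overrides `neighborhood_radius` when set).
#' @param blue_threshold equalized-field selection threshold in (0, 1).
#'   The default 0.75 selects the strictly blue-dominant shades of the
#'   red-green-blue quality ramp: on a linear ramp the blue channel
#'   overtakes green at 3/4, so "select the blue areas" means the top
#'   quarter of the equalized field.
#' @param min_component_diameter components with a smaller bounding-box
#'   diagonal are removed as artifacts (mm).
#' @param lesion_flag_diameter diameter above which a projecting component
#'   is flagged for operator review as a possible lesion (mm).
#' @return A list of class `vera_params`.
#' @export
segmentation_params <- function(smooth_enabled = TRUE,
                                smooth_iterations = 3L,
                                neighborhood_radius = 0.6,
                                neighborhood_scale = NULL,
                                blue_threshold = 0.75,
                                min_component_diameter = 2.0,
                                lesion_flag_diameter = 4.0) {
  if (blue_threshold <= 0 || blue_threshold >= 1)
    stop("`blue_threshold` must be in (0, 1)")
  if (min_component_diameter < 0)
    stop("`min_component_diameter` must be >= 0")
  if (neighborhood_radius <= 0) stop("`neighborhood_radius` must be > 0")
  if (!is.null(neighborhood_scale) && neighborhood_scale < 2)
    stop("`neighborhood_scale` must be >= 2")
  structure(list(smooth_enabled = isTRUE(smooth_enabled),
                 smooth_iterations = as.integer(smooth_iterations),
                 neighborhood_radius = neighborhood_radius,
                 neighborhood_scale = neighborhood_scale,
                 blue_threshold = blue_threshold,
                 min_component_diameter = min_component_diameter,
                 lesion_flag_diameter = lesion_flag_diameter),
            class = "vera_params")
}

params_digest <- function(params) {
  paste(formatC(unlist(params), digits = 10, format = "g"), collapse = "|")
}

#' Gentle surface smoothing
#'
#' Taubin lambda/mu smoothing (lambda = 0.5, mu = -0.53), which damps
#' small sharp scanning artifacts without the global shrinkage of plain
#' Laplacian smoothing, so tubercle volume is essentially preserved.
#' Connectivity is unchanged; boundary vertices are pinned.
#'
#' @param mesh a clean `vera_mesh`.
#' @param iterations number of lambda/mu passes; 0 is the identity.
#' @return The smoothed `vera_mesh`.
#' @export
smooth_surface <- function(mesh, iterations = 3L) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("`iterations` must be >= 0")
  if (iterations == 0L) return(mesh)
  v <- cpp_taubin_smooth(mesh$vertices, mesh$faces - 1L, iterations,
                         0.5, -0.53)
  mesh$vertices <- v
  mesh
}

#' Select projecting areas on a submesh
#'
#' Equalizes the minimum-curvature field over the submesh and selects the
#' vertices whose equalized value reaches `blue_threshold` - the blue band
#' of the quality ramp, i.e. the most convex fraction of the surface.
#'
#' @param submesh the BSR submesh (at least 10 vertices).
#' @param curvature `vera_curvature` with `k_min` computed on `submesh`.
#' @param blue_threshold threshold in (0, 1), default 0.75 (blue-dominant band).
#' @return A `vera_selection` on `submesh`.
#' @export
select_projections <- function(submesh, curvature, blue_threshold = 0.75) {
  if (n_vertices(submesh) < 10L)
    stop("submesh has fewer than 10 vertices; equalization is meaningless")
  if (is.null(curvature$k_min)) stop("`curvature` has no k_min field")
  eq <- equalize_field(curvature$k_min)
  vertex_selection(submesh, which(eq >= blue_threshold),
                   label = sprintf("projections>=%.3f", blue_threshold))
}

#' Remove small outlier components
#'
#' Converts the selection to faces (all three corners selected), groups
#' the faces into edge-connected components, and drops components whose
#' bounding-box diagonal is below `min_diameter`. What remains are the
#' measured surface irregularities.
#'
#' @param submesh the BSR submesh.
#' @param selection a `vera_selection` on `submesh`.
#' @param min_diameter artifact-removal threshold in mm.
#' @return A list of class `vera_segmentation`: `components` (each with
#'   `faces`, `vertices`, `area_mm2`, `diameter_mm`), `total_area_mm2`.
#' @export
remove_small_components <- function(submesh, selection, min_diameter = 2.0) {
  check_selection(submesh, selection)
  inside <- rep(FALSE, n_vertices(submesh))
  inside[selection$indices] <- TRUE
  f <- submesh$faces
  nsel <- inside[f[, 1]] + inside[f[, 2]] + inside[f[, 3]]
  fsel <- which(nsel == 3L)
  comps <- list()
  if (length(fsel) > 0L) {
    groups <- face_components(submesh, fsel)
    areas <- face_areas(submesh)
    # Rim correction: the true selection boundary runs mid-edge between
    # selected and unselected vertices, but strict face membership drops
    # the whole rim band, biasing areas low by ~(edge length x perimeter)
    # - a resolution-dependent bias.  Faces with two selected corners that
    # share an edge with a component contribute half their area, the
    # midpoint-rule estimate of the region they straddle.
    rim_cand <- which(nsel == 2L)
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    rim_edges <- character(0)
    if (length(rim_cand) > 0L) {
      rf <- f[rim_cand, , drop = FALSE]
      # the rim face's selected-selected edge
      rim_edges <- ifelse(inside[rf[, 1]] & inside[rf[, 2]],
                          ekey(rf[, 1], rf[, 2]),
                   ifelse(inside[rf[, 2]] & inside[rf[, 3]],
                          ekey(rf[, 2], rf[, 3]), ekey(rf[, 3], rf[, 1])))
    }
    for (g in groups) {
      vs <- sort(unique(as.vector(f[g, , drop = FALSE])))
      diam <- bbox_diagonal(submesh$vertices[vs, , drop = FALSE])
      if (diam >= min_diameter) {
        gf <- f[g, , drop = FALSE]
        gedges <- unique(c(ekey(gf[, 1], gf[, 2]), ekey(gf[, 2], gf[, 3]),
                           ekey(gf[, 3], gf[, 1])))
        rim <- rim_cand[rim_edges %in% gedges]
        comps[[length(comps) + 1L]] <-
          list(faces = g, vertices = vs,
               area_mm2 = sum(areas[g]) + 0.5 * sum(areas[rim]),
               core_area_mm2 = sum(areas[g]),
               diameter_mm = diam)
      }
    }
  }
  comps <- comps[order(vapply(comps, `[[`, 0.0, "area_mm2"),
                       decreasing = TRUE)]
  structure(list(components = comps,
                 total_area_mm2 = sum(vapply(comps, `[[`, 0.0, "area_mm2")),
                 min_component_diameter = min_diameter),
            class = "vera_segmentation")
}

# edge-connected components of a face subset
face_components <- function(mesh, face_ids) {
  f <- mesh$faces[face_ids, , drop = FALSE]
  m <- nrow(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ekey(f[, 1], f[, 2]), ekey(f[, 2], f[, 3]), ekey(f[, 3], f[, 1]))
  owner <- rep(seq_len(m), 3L)
  ord <- order(keys)
  keys <- keys[ord]; owner <- owner[ord]
  same <- keys[-1] == keys[-length(keys)]
  pairs <- cbind(owner[-length(owner)][same], owner[-1][same])
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(pairs) > 0L) g <- igraph::add_edges(g, t(pairs))
  memb <- igraph::components(g)$membership
  unname(split(face_ids, memb))
}

#' @export
print.vera_segmentation <- function(x, ...) {
  cat(sprintf("<vera_segmentation> %d component(s), total area %.3f mm^2\n",
              length(x$components), x$total_area_mm2))
  for (i in seq_along(x$components))
    cat(sprintf("  #%d: %.3f mm^2, diameter %.2f mm, %d faces\n", i,
                x$components[[i]]$area_mm2, x$components[[i]]$diameter_mm,
                length(x$components[[i]]$faces)))
  invisible(x)
}

#' Run the full segmentation chain
#'
#' Executes, in order: cleaning, optional smoothing, lesion-mask
#' subtraction from the BSR, submesh extraction, principal curvature by
#' quadric fitting, blue-band selection on the equalized minimum
#' curvature, small-component removal, and area measurement. Also emits
#' lesion-candidate flags (never auto-removing anything). Component face
#' and vertex indices in the result refer to the input mesh.
#'
#' @param mesh the full bone `vera_mesh`.
#' @param bsr the broader-selection-region `vera_selection` on `mesh`.
#' @param params a [segmentation_params()] list.
#' @param lesion_masks list of `vera_selection`s subtracted from the BSR.
#' @return A `vera_result`: `segmentation`, `lesion_flags`, `resolution`,
#'   `total_area_mm2`, `params`, `provenance`.
#' @export
run_vera <- function(mesh, bsr, params = segmentation_params(),
                     lesion_masks = list()) {
  check_selection(mesh, bsr)
  if (length(bsr$indices) == 0L) stop("BSR selection is empty")
  resol <- estimate_resolution(mesh)
  if (!resol$passes_min)
    warning(sprintf(paste0(
      "mesh resolution (median edge %.3f mm) is coarser than the 0.30 mm ",
      "minimum; surface changes may be under-resolved"),
      resol$median_edge_length), call. = FALSE)

  cleaned <- clean_mesh(mesh)
  vmap <- attr(cleaned, "vertex_map")
  remap_sel <- function(sel, m) {
    idx <- vmap[sel$indices]
    vertex_selection(m, idx[!is.na(idx)], label = sel$label)
  }
  work <- if (params$smooth_enabled)
    smooth_surface(cleaned, params$smooth_iterations) else cleaned
  bsr_w <- remap_sel(bsr, work)
  for (mask in lesion_masks) {
    check_selection(mesh, mask)
    bsr_w <- combine_selections(bsr_w, remap_sel(mask, work), "subtract",
                                label = bsr$label)
  }
  if (length(bsr_w$indices) == 0L)
    stop("BSR is empty after lesion-mask subtraction")

  sub <- extract_submesh(work, bsr_w)
  curv <- principal_curvatures_quadric(
    sub, neighborhood_radius = params$neighborhood_radius,
    neighborhood_scale = params$neighborhood_scale)
  sel <- select_projections(sub, curv, params$blue_threshold)
  seg <- remove_small_components(sub, sel, params$min_component_diameter)

  # map faces/vertices back to the input mesh (cleaning preserves order,
  # so cleaned indices are positions in `used`/`fkeep` chains)
  ov <- attr(sub, "orig_vertices")   # submesh vertex -> cleaned vertex
  of <- attr(sub, "orig_faces")      # submesh face -> cleaned face
  clean_to_orig <- match(seq_len(n_vertices(cleaned)), vmap)
  fmap <- attr(cleaned, "face_map")  # cleaned face -> input face
  for (i in seq_along(seg$components)) {
    seg$components[[i]]$vertices <- clean_to_orig[ov[seg$components[[i]]$vertices]]
    seg$components[[i]]$faces_submesh <- seg$components[[i]]$faces
    seg$components[[i]]$faces <- fmap[of[seg$components[[i]]$faces]]
  }

  eqsel <- vertex_selection(work, bsr_w$indices, label = bsr$label)
  flags <- flag_lesion_candidates(
    sub, vertex_selection(sub, seq_len(n_vertices(sub)), "BSR"),
    curv, params$blue_threshold, params$lesion_flag_diameter)

  if (seg$total_area_mm2 == 0 && length(sel$indices) > 0L)
    message("no component survived filtering; for small, already-smooth ",
            "models consider smooth_enabled = FALSE and ",
            "min_component_diameter = 1.0 (applied consistently across ",
            "the sample)")

  structure(list(segmentation = seg,
                 total_area_mm2 = seg$total_area_mm2,
                 lesion_flags = flags,
                 resolution = resol,
                 params = params,
                 provenance = list(fingerprint = mesh_fingerprint(mesh),
                                   bsr_label = bsr$label,
                                   params_digest = params_digest(params)),
                 submesh = sub,
                 bsr_vertices = clean_to_orig[ov],
                 projection_selection = sel),
            class = "vera_result")
}

#' @export
print.vera_result <- function(x, ...) {
  cat(sprintf("<vera_result> BSR '%s': total area %.3f mm^2 in %d component(s)\n",
              x$provenance$bsr_label, x$total_area_mm2,
              length(x$segmentation$components)))
  nflag <- sum(x$lesion_flags$flagged)
  if (nflag > 0)
    cat(sprintf("  ! %d component(s) exceed the lesion flag diameter - review\n",
                nflag))
  invisible(x)
}

#' Write a segmentation result as JSON and/or a colorized mesh
#'
#' The colorized PLY shows the BSR in red and retained irregularities in
#' blue, over a grey bone, the standard presentation for visual checking.
#'
#' @param result a `vera_result`.
#' @param mesh the input mesh the result was computed on.
#' @param json_path optional output JSON path.
#' @param mesh_path optional output PLY path.
#' @return Invisibly, the list written to JSON.
#' @export
export_result <- function(result, mesh, json_path = NULL, mesh_path = NULL) {
  doc <- list(
    format = "vera-result/1",
    total_area_mm2 = result$total_area_mm2,
    components = lapply(result$segmentation$components, function(cc)
      list(area_mm2 = cc$area_mm2, diameter_mm = cc$diameter_mm,
           n_faces = length(cc$faces))),
    lesion_flags = if (nrow(result$lesion_flags) > 0)
      result$lesion_flags[, c("n_vertices", "diameter_mm", "flagged")]
    else NULL,
    resolution = result$resolution[c("median_edge_length", "passes_min",
                                     "passes_recommended")],
    params = unclass(result$params),
    provenance = result$provenance)
  if (!is.null(json_path))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(mesh_path)) {
    # grey bone, BSR in red, retained irregularities in blue
    color <- matrix(0.7, n_vertices(mesh), 3L)
    sub_verts <- result$bsr_vertices
    if (!is.null(sub_verts)) {
      color[sub_verts, 1] <- 1; color[sub_verts, 2] <- 0.2
      color[sub_verts, 3] <- 0.2
    }
    for (cc in result$segmentation$components) {
      color[cc$vertices, 1] <- 0; color[cc$vertices, 2] <- 0.2
      color[cc$vertices, 3] <- 1
    }
    out <- mesh; out$color <- color
    write_mesh(out, mesh_path, format = "ply")
  }
  invisible(doc)
}

#' Batch measurement over a manifest
#'
#' One row per specimen: mesh path, BSR selection path, specimen id,
#' enthesis code and side. Failing rows are recorded with their reason,
#' never silently skipped.
#'
#' @param manifest data.frame (or CSV path) with columns `mesh`, `bsr`,
#'   `specimen_id`, `enthesis_code`, `side`.
#' @param params a [segmentation_params()] list.
#' @return A data.frame of measurement records (`specimen_id`,
#'   `enthesis_code`, `side`, `area_mm2`, `params_digest`, `status`,
#'   `message`); failures have `NA` area and `status = "error"`.
#' @export
batch_measure <- function(manifest, params = segmentation_params()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("mesh", "bsr", "specimen_id", "enthesis_code", "side")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(manifest) == 0L) {
    warning("empty manifest")
    return(data.frame(specimen_id = character(0), enthesis_code = character(0),
                      side = character(0), area_mm2 = numeric(0),
                      params_digest = character(0), status = character(0),
                      message = character(0)))
  }
  dg <- params_digest(params)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    res <- tryCatch({
      mesh <- read_mesh(as.character(r$mesh))
      bsr <- read_selection(as.character(r$bsr))
      out <- run_vera(mesh, bsr, params)
      data.frame(specimen_id = as.character(r$specimen_id),
                 enthesis_code = as.character(r$enthesis_code),
                 side = as.character(r$side),
                 area_mm2 = out$total_area_mm2, params_digest = dg,
                 status = "ok", message = "")
    }, error = function(e)
      data.frame(specimen_id = as.character(r$specimen_id),
                 enthesis_code = as.character(r$enthesis_code),
                 side = as.character(r$side),
                 area_mm2 = NA_real_, params_digest = dg,
                 status = "error", message = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  nerr <- sum(out$status == "error")
  if (nerr > 0)
    warning(sprintf("%d of %d manifest rows failed; see `message` column",
                    nerr, nrow(out)))
  out
}
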