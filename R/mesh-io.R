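# Readers and writers for the three interchange formats used for bone
# surface scans.  PLY (ascii and binary_little_endian) is the primary
# format: it carries the per-vertex scalar field as the `quality` property
# and vertex colours as uchar red/green/blue.  OBJ and STL carry geometry
# only.  No unit metadata exists in any of these formats; coordinates are
# taken to be millimetres throughout.

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  switch(type,
    char = , int8 = readBin(con, integer(), 1L, size = 1L, signed = TRUE),
    uchar = , uint8 = readBin(con, integer(), 1L, size = 1L, signed = FALSE),
    short = , int16 = readBin(con, integer(), 1L, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, integer(), 1L, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, integer(), 1L, size = 4L, endian = "little"),
    float = , float32 = readBin(con, double(), 1L, size = 4L, endian = "little"),
    double = , float64 = readBin(con, double(), 1L, size = 8L, endian = "little"),
    stop("unsupported PLY property type: ", type))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (length(magic) == 0L || !identical(trimws(magic), "ply"))
    stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else stop("unrecognised PLY header line: ", line)
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  if (!"vertex" %in% names(elements) || !"face" %in% names(elements))
    stop("PLY file lacks vertex or face element: ", path)

  vert <- elements$vertex
  facel <- elements$face
  pnames <- vapply(vert$props, `[[`, "", "name")

  if (fmt == "ascii") {
    vl <- readLines(con, n = vert$count)
    nums <- scan(text = vl, quiet = TRUE)
    if (length(nums) != vert$count * length(pnames))
      stop("truncated PLY vertex block in ", path)
    vmat <- matrix(nums, ncol = length(pnames), byrow = TRUE)
    vdat <- as.data.frame(vmat)
    names(vdat) <- pnames
    fl <- readLines(con, n = facel$count)
    ftok <- strsplit(trimws(fl), "\\s+")
    faces_list <- lapply(ftok, function(t) as.integer(t[-1])[seq_len(as.integer(t[1]))])
  } else {
    sizes <- vapply(vert$props, function(p) .ply_type_size[[p$type]], 1L)
    # uniform-size fast path: read the vertex block as a raw matrix
    vdat <- as.data.frame(matrix(0, vert$count, length(pnames)))
    names(vdat) <- pnames
    for (i in seq_len(vert$count)) {
      for (j in seq_along(vert$props))
        vdat[[j]][i] <- .ply_read_scalar(con, vert$props[[j]]$type)
    }
    fp <- facel$props[[1L]]
    if (!fp$list) stop("PLY face element must use a list property")
    faces_list <- vector("list", facel$count)
    for (i in seq_len(facel$count)) {
      cnt <- .ply_read_scalar(con, fp$count_type)
      idx <- integer(cnt)
      for (k in seq_len(cnt)) idx[k] <- .ply_read_scalar(con, fp$type)
      faces_list[[i]] <- idx
    }
  }

  if (!all(c("x", "y", "z") %in% pnames))
    stop("PLY vertex element lacks x/y/z")
  V <- cbind(vdat$x, vdat$y, vdat$z)
  color <- NULL
  if (all(c("red", "green", "blue") %in% pnames))
    color <- cbind(vdat$red, vdat$green, vdat$blue) / 255
  field <- if ("quality" %in% pnames) vdat$quality

  poly <- lengths(faces_list)
  if (any(poly < 3L)) stop("PLY face with fewer than 3 vertices")
  if (any(poly > 3L)) {
    warning("non-triangular faces triangulated by fanning")
    faces_list <- unlist(lapply(faces_list, function(ix) {
      lapply(seq_len(length(ix) - 2L), function(k) ix[c(1L, k + 1L, k + 2L)])
    }), recursive = FALSE)
  }
  Fm <- do.call(rbind, faces_list) + 1L
  triangle_mesh(V, Fm, field = field, color = color)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  has_col <- !is.null(mesh$color)
  has_fld <- !is.null(mesh$field)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (has_col) hdr <- c(hdr, "property uchar red", "property uchar green",
                        "property uchar blue")
  if (has_fld) hdr <- c(hdr, "property double quality")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  col255 <- if (has_col) round(pmin(pmax(mesh$color, 0), 1) * 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (!binary) {
    rows <- apply(mesh$vertices, 1L, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = " "))
    if (has_col)
      rows <- paste(rows, col255[, 1], col255[, 2], col255[, 3])
    if (has_fld)
      rows <- paste(rows, formatC(mesh$field, digits = 17, format = "g"))
    writeLines(rows, con)
    if (nf > 0L)
      writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                       mesh$faces[, 3] - 1L), con)
  } else {
    for (i in seq_len(nv)) {
      writeBin(as.double(mesh$vertices[i, ]), con, size = 8L, endian = "little")
      if (has_col)
        writeBin(as.raw(col255[i, ]), con)
      if (has_fld)
        writeBin(as.double(mesh$field[i]), con, size = 8L, endian = "little")
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("no vertices found in OBJ file: ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces_list <- lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    idx <- vapply(t[-1], function(s) as.integer(strsplit(s, "/")[[1]][1]), 1L)
    unname(idx)
  })
  poly <- lengths(faces_list)
  if (any(poly > 3L)) {
    warning("non-triangular faces triangulated by fanning")
    faces_list <- unlist(lapply(faces_list, function(ix) {
      lapply(seq_len(length(ix) - 2L), function(k) ix[c(1L, k + 1L, k + 2L)])
    }), recursive = FALSE)
  }
  Fm <- do.call(rbind, faces_list)
  triangle_mesh(V, Fm)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v",
                   formatC(mesh$vertices[, 1], digits = 17, format = "g"),
                   formatC(mesh$vertices[, 2], digits = 17, format = "g"),
                   formatC(mesh$vertices[, 3], digits = 17, format = "g")), con)
  if (n_faces(mesh) > 0L)
    writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
               con)
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("not an STL file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, raw(), 80L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (is_ascii && sz >= 84) {
    # a binary STL may also start with "solid": check the triangle count
    ntri <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    if (sz == 84 + 50 * as.numeric(ntri)) is_ascii <- FALSE
  }
  close(con)
  on.exit()
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed ascii STL: ", path)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t)
      as.numeric(t[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, raw(), 80L)
    ntri <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    rec <- readBin(con, raw(), 50L * ntri)
    m <- matrix(rec, nrow = 50L)
    # 12 floats (normal + 3 vertices) + uint16 attribute per record
    fl <- readBin(as.vector(m[1:48, , drop = FALSE]), double(),
                  n = 12L * ntri, size = 4L, endian = "little")
    fl <- matrix(fl, nrow = 12L)
    V <- matrix(as.vector(fl[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  }
  ntri <- nrow(V) / 3L
  Fm <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  # STL stores no connectivity: weld coincident corners on read
  clean_mesh(triangle_mesh(V, Fm))
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vera", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vera", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.double(c(nrm[i, ], t(v[f[i, ], , drop = FALSE]))), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "stl")) ext else
    stop("cannot guess mesh format from extension: ", path)
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' PLY is the preferred format (ascii or binary little-endian); a
#' per-vertex `quality` property becomes the mesh scalar field and uchar
#' red/green/blue become vertex colours. STL carries no connectivity, so
#' coincident corners are welded on read. Coordinates are interpreted as
#' millimetres.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"ply"`, `"obj"`, `"stl"`.
#' @return A `vera_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.info(path)$size == 0) stop("empty file: ", path)
  if (format == "auto") format <- .guess_format(path)
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a `vera_mesh`.
#' @param path output file path.
#' @param format one of `"auto"` (by extension), `"ply"`, `"obj"`, `"stl"`.
#' @param binary write binary PLY/STL instead of ascii.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("cannot write to directory: ", dir)
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path, binary = binary))
  invisible(path)
}
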