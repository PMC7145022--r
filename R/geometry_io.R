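#' Surface mesh constructor
#'
#' A triangulated surface: vertex coordinates in millimetres and a triangle
#' index table. Meshes are validated on construction: indices must be in
#' range, coordinates finite, and no triangle may have (numerically) zero
#' area.
#'
#' @param vertices numeric matrix, one vertex per row, columns x, y, z (mm).
#' @param triangles integer matrix, one triangle per row, 1-based vertex
#'   indices.
#' @param name text identifier carried through reports and error messages.
#' @return an object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `name`.
#' @export
surface_mesh <- function(vertices, triangles, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         name = as.character(name)[1]),
                    class = "surface_mesh")
  validate_mesh(mesh)
  mesh
}

#' Validate a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @param area_tol triangles with area below this (mm^2) are degenerate.
#' @return the mesh, invisibly; stops with a validation error otherwise.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-10) {
  v <- mesh$vertices; f <- mesh$triangles
  if (!is.matrix(v) || ncol(v) != 3 || nrow(v) < 3)
    stop("mesh validation: need a numeric vertex matrix with 3 columns and >= 3 rows")
  if (!all(is.finite(v)))
    stop("mesh validation: non-finite vertex coordinates in '", mesh$name, "'")
  if (!is.matrix(f) || ncol(f) != 3 || nrow(f) < 1)
    stop("mesh validation: mesh '", mesh$name, "' has no triangles")
  if (anyNA(f) || any(f < 1L) || any(f > nrow(v)))
    stop("mesh validation: triangle index out of range (vertex count ",
         nrow(v), ") in '", mesh$name, "'")
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (any(area <= area_tol))
    stop("mesh validation: degenerate (zero-area) triangle(s) ",
         paste(utils::head(which(area <= area_tol), 5), collapse = ", "),
         " in '", mesh$name, "'")
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> '", x$name, "': ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Read a triangular surface mesh (OBJ or PLY)
#'
#' Wavefront OBJ (`v`/`f` records; polygonal faces are fan-triangulated) and
#' PLY in ASCII or binary little-endian form. Coordinates are taken as
#' millimetres; no unit conversion is applied.
#'
#' @param path file path ending in `.obj` or `.ply`.
#' @return a validated [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stop("read_mesh: unsupported extension '.", ext, "' (need .obj or .ply)"))
  validate_mesh(mesh)
  message("read_mesh: '", basename(path), "': ", nrow(mesh$vertices),
          " vertices, ", nrow(mesh$triangles), " triangles")
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grepl("^v\\s", lines)
  flines <- grepl("^f\\s", lines)
  if (!any(vlines)) stop("read_obj: no vertex records in ", path)
  if (!any(flines)) stop("read_obj: no face records in ", path)
  parse_v <- function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    xyz <- suppressWarnings(as.numeric(parts[1:3]))
    if (length(parts) < 3 || anyNA(xyz))
      stop("read_obj: malformed vertex at line ", i, ": '", lines[i], "'")
    xyz
  }
  verts <- t(vapply(which(vlines), parse_v, numeric(3)))
  tris <- list()
  for (i in which(flines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", parts)))
    if (length(idx) < 3 || anyNA(idx))
      stop("read_obj: malformed face at line ", i, ": '", lines[i], "'")
    neg <- idx < 0
    idx[neg] <- nrow(verts) + 1L + idx[neg]
    if (any(idx < 1L | idx > nrow(verts)))
      stop("read_obj: face index out of range at line ", i,
           " (vertex count ", nrow(verts), ")")
    for (k in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  structure(list(vertices = verts,
                 triangles = do.call(rbind, tris),
                 name = sub("\\.[^.]*$", "", basename(path))),
            class = "surface_mesh")
}

.ply_sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  sz <- .ply_sizes[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("read_ply: missing 'ply' magic in ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("read_ply: truncated header in ", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("read_ply: unsupported PLY format '", fmt, "' in ", path)
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("read_ply: need 'vertex' and 'face' elements in ", path)

  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 1L
    vt <- elements$vertex
    pnames <- vapply(vt$props, `[[`, "", "name")
    verts <- matrix(NA_real_, vt$count, 3L)
    for (i in seq_len(vt$count)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(txt[pos]), "\\s+")[[1]]))
      if (anyNA(vals[match(c("x", "y", "z"), pnames)]))
        stop("read_ply: malformed vertex record ", i, " in ", path)
      verts[i, ] <- vals[match(c("x", "y", "z"), pnames)]
      pos <- pos + 1L
    }
    fc <- elements$face
    tris <- list()
    for (i in seq_len(fc$count)) {
      vals <- suppressWarnings(as.integer(strsplit(trimws(txt[pos]), "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) < vals[1] + 1L)
        stop("read_ply: malformed face record ", i, " in ", path)
      idx <- vals[2:(vals[1] + 1L)] + 1L
      for (k in seq_len(length(idx) - 2L))
        tris[[length(tris) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
      pos <- pos + 1L
    }
  } else {
    vt <- elements$vertex
    verts <- matrix(NA_real_, vt$count, 3L)
    pnames <- vapply(vt$props, `[[`, "", "name")
    for (i in seq_len(vt$count)) {
      row <- numeric(length(vt$props))
      for (j in seq_along(vt$props)) row[j] <- .ply_read_scalar(con, vt$props[[j]]$type)
      verts[i, ] <- row[match(c("x", "y", "z"), pnames)]
    }
    fc <- elements$face
    tris <- list()
    lp <- fc$props[[1]]
    for (i in seq_len(fc$count)) {
      n <- .ply_read_scalar(con, lp$count_type)
      idx <- integer(n)
      for (j in seq_len(n)) idx[j] <- .ply_read_scalar(con, lp$type) + 1L
      for (k in seq_len(n - 2L))
        tris[[length(tris) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
    }
  }
  structure(list(vertices = verts, triangles = do.call(rbind, tris),
                 name = sub("\\.[^.]*$", "", basename(path))),
            class = "surface_mesh")
}

#' Write a surface mesh (OBJ or ASCII PLY)
#'
#' Coordinates are written with enough digits that a round trip through
#' [read_mesh()] reproduces them to better than 1e-6 mm.
#'
#' @param mesh a valid [surface_mesh()].
#' @param path output path ending in `.obj` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  validate_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  fmt <- function(m) apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  lines <- switch(ext,
    obj = c(paste("v", fmt(mesh$vertices)),
            paste("f", apply(mesh$triangles, 1L, paste, collapse = " "))),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(mesh$vertices)),
            "property double x", "property double y", "property double z",
            paste("element face", nrow(mesh$triangles)),
            "property list uchar int vertex_indices", "end_header",
            fmt(mesh$vertices),
            apply(mesh$triangles - 1L, 1L, function(r)
              paste(c(3L, r), collapse = " "))),
    stop("write_mesh: unsupported extension '.", ext, "'"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_mesh: cannot write to ", path)
  invisible(path)
}

#' Landmark configuration constructor
#'
#' An ordered set of 3D points (mm) split into an anchor block (the fixed
#' anatomical landmarks, first rows) and a semi-landmark block. Anchor
#' labels use the standard craniofacial notations (enl, exl, ..., ve);
#' semi-landmarks get generated labels `s0001`, `s0002`, ...
#'
#' @param points numeric matrix K x 3 (mm).
#' @param anchor_count number of anchors occupying the first rows.
#' @param labels character labels for the anchors (length `anchor_count`);
#'   semi-landmark labels are generated.
#' @return an object of class `landmark_config`.
#' @export
landmark_configuration <- function(points, anchor_count,
                                   labels = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("landmark_configuration: points must be K x 3")
  if (!all(is.finite(points)))
    stop("landmark_configuration: non-finite coordinates")
  anchor_count <- as.integer(anchor_count)
  semi <- nrow(points) - anchor_count
  if (anchor_count < 0L || semi < 0L)
    stop("landmark_configuration: anchor_count ", anchor_count,
         " exceeds point count ", nrow(points))
  if (is.null(labels)) labels <- sprintf("a%02d", seq_len(anchor_count))
  if (length(labels) != anchor_count)
    stop("landmark_configuration: need one label per anchor")
  full_labels <- c(as.character(labels),
                   if (semi > 0L) sprintf("s%04d", seq_len(semi)))
  rownames(points) <- full_labels
  structure(list(points = points, anchor_count = anchor_count,
                 semilandmark_count = as.integer(semi),
                 labels = as.character(labels)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> ", x$anchor_count, " anchors + ",
      x$semilandmark_count, " semi-landmarks\n", sep = "")
  invisible(x)
}

#' Anchor / semi-landmark blocks of a configuration
#' @param config a `landmark_config`.
#' @return coordinate matrix of the requested block.
#' @export
anchor_points <- function(config) {
  config$points[seq_len(config$anchor_count), , drop = FALSE]
}

#' @rdname anchor_points
#' @export
semilandmark_points <- function(config) {
  if (config$semilandmark_count == 0L)
    return(config$points[0, , drop = FALSE])
  config$points[config$anchor_count + seq_len(config$semilandmark_count), ,
                drop = FALSE]
}

#' Read a landmark CSV (`label,x,y,z`, mm units)
#'
#' The first `anchor_count` rows are the anchor block; remaining rows are
#' semi-landmarks.
#'
#' @param path CSV path with header `label,x,y,z`.
#' @param anchor_count how many leading rows are anchors.
#' @return a [landmark_configuration()].
#' @export
read_landmarks <- function(path, anchor_count) {
  if (!file.exists(path)) stop("read_landmarks: file does not exist: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = c("character", "character",
                                                "character", "character")),
                 error = function(e) stop("read_landmarks: cannot parse ",
                                          path, ": ", conditionMessage(e)))
  if (!identical(names(df), c("label", "x", "y", "z")))
    stop("read_landmarks: header must be 'label,x,y,z' in ", path)
  if (nrow(df) == 0L) stop("read_landmarks: no landmark rows in ", path)
  xyz <- suppressWarnings(cbind(as.numeric(df$x), as.numeric(df$y),
                                as.numeric(df$z)))
  bad <- which(!stats::complete.cases(xyz) | !is.finite(rowSums(xyz)))
  if (length(bad))
    stop("read_landmarks: non-numeric coordinate at data row ",
         bad[1], " of ", path)
  if (nrow(df) < anchor_count)
    stop("read_landmarks: ", nrow(df), " rows < anchor_count ", anchor_count)
  landmark_configuration(xyz, anchor_count,
                         labels = df$label[seq_len(anchor_count)])
}

#' Write a landmark configuration as CSV
#' @param config a `landmark_config`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(config, path) {
  lab <- rownames(config$points)
  lines <- c("label,x,y,z",
             paste(lab,
                   sprintf("%.10g", config$points[, 1]),
                   sprintf("%.10g", config$points[, 2]),
                   sprintf("%.10g", config$points[, 3]), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Age classes used throughout the analysis
#'
#' Five classes: children (below 13), teenagers (13-19), young adults
#' (20-29), adults (30-49) and senior adults (50 and above).
#' @export
AGE_CLASSES <- c("<13", "13-19", "20-29", "30-49", "50>")

#' Read / write a specimen metadata table
#'
#' Columns `id,ethnicity,sex,age_class,replicate_of`; `replicate_of` is
#' empty for first digitizations and names an existing `id` for
#' re-digitized copies.
#'
#' @param path CSV path.
#' @return a data.frame with validated columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("id", "ethnicity", "sex", "age_class", "replicate_of")
  if (!all(need %in% names(df)))
    stop("read_metadata: need columns ", paste(need, collapse = ","))
  bad <- setdiff(unique(df$age_class), AGE_CLASSES)
  if (length(bad))
    stop("read_metadata: unknown age class(es) ", paste(bad, collapse = ", "),
         "; valid: ", paste(AGE_CLASSES, collapse = ", "))
  rep_of <- df$replicate_of[!is.na(df$replicate_of)]
  if (!all(rep_of %in% df$id))
    stop("read_metadata: replicate_of refers to unknown id(s): ",
         paste(setdiff(rep_of, df$id), collapse = ", "))
  df
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}
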