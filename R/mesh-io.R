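#' Triangulated surface meshes
#'
#' A `surface_mesh` stores an open or closed triangulated surface in world
#' millimetre coordinates: an `n x 3` vertex matrix and an `m x 3` matrix of
#' 1-based triangle vertex indices. Triangle winding is counter-clockwise
#' seen from outside, so the right-hand rule on the vertex order gives the
#' outward normal. Duplicate vertices closer than 1e-9 mm are merged and
#' zero-area triangles are dropped at construction, so a valid mesh never
#' carries degenerate cells.
#'
#' @param vertices numeric `n x 3` matrix of vertex positions (mm).
#' @param triangles integer `m x 3` matrix of 1-based vertex indices.
#' @param subject_id optional subject identifier carried through the pipeline.
#' @param merge_tol vertices closer than this (mm) are merged.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles` and `subject_id`.
#' @export
surface_mesh <- function(vertices, triangles, subject_id = NULL,
                         merge_tol = 1e-9) {
  v <- as_points3(vertices, "vertices")
  f <- as.matrix(triangles)
  if (ncol(f) != 3L) stop("triangles must be an m x 3 index matrix")
  storage.mode(f) <- "integer"
  if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
    stop("triangle indices out of range")

  if (merge_tol > 0 && nrow(v) > 1) {
    key <- apply(round(v / max(merge_tol, 1e-12)), 1L, paste, collapse = ",")
    first <- match(key, key)
    if (any(first != seq_len(nrow(v)))) {
      keep <- which(first == seq_len(nrow(v)))
      remap <- integer(nrow(v))
      remap[keep] <- seq_along(keep)
      f[] <- remap[first[f]]
      v <- v[keep, , drop = FALSE]
    }
  }
  ## drop degenerate triangles (repeated index or zero area)
  if (nrow(f) > 0) {
    repeated <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    zero <- row_norms(cr) <= 0
    bad <- repeated | zero
    if (any(bad)) f <- f[!bad, , drop = FALSE]
  }
  structure(list(vertices = v, triangles = f,
                 subject_id = subject_id),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else ""))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Four-landmark set
#'
#' Exactly four named anatomical landmarks (left eye, right eye, nose tip,
#' lip midpoint) used for initial rigid alignment of face surfaces.
#'
#' @param left_eye,right_eye,nose,lip_midpoint numeric length-3 points (mm).
#' @return A `landmark_set`: a 4 x 3 matrix with fixed row names.
#' @export
landmark_set <- function(left_eye, right_eye, nose, lip_midpoint) {
  m <- rbind(left_eye = as.numeric(left_eye), right_eye = as.numeric(right_eye),
             nose = as.numeric(nose), lip_midpoint = as.numeric(lip_midpoint))
  if (ncol(m) != 3L || !all(is.finite(m))) stop("landmarks must be finite 3-D points")
  ## collinearity check: rank of centred configuration must exceed 1
  c0 <- sweep(m, 2L, colMeans(m))
  s <- svd(c0, nu = 0, nv = 0)$d
  if (s[2] <= 1e-9 * max(s[1], 1e-12))
    stop("degenerate landmark configuration: points are collinear")
  structure(m, class = "landmark_set")
}

landmark_names <- c("left_eye", "right_eye", "nose", "lip_midpoint")

#' Read landmarks from delimited text
#'
#' Expects a header-free or headered table with columns `name,x,y,z` holding
#' exactly the four canonical landmark names.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, sep = ",") {
  tab <- utils::read.table(path, sep = sep, stringsAsFactors = FALSE,
                           header = FALSE, strip.white = TRUE)
  if (tolower(tab[1, 1]) == "name") tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 4L) stop("landmark file must have columns name,x,y,z")
  nm <- tolower(trimws(as.character(tab[[1]])))
  idx <- match(landmark_names, nm)
  if (anyNA(idx))
    stop("landmark file must contain exactly: ", paste(landmark_names, collapse = ", "))
  xyz <- apply(tab[idx, 2:4], 2L, function(col) as.numeric(as.character(col)))
  landmark_set(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path, sep = ",") {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- data.frame(name = rownames(landmarks), landmarks[, 1], landmarks[, 2],
                   landmarks[, 3])
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = c("name", "x", "y", "z"), quote = FALSE)
  invisible(path)
}

## ---- mesh readers -------------------------------------------------------

#' Read a triangle mesh
#'
#' Reads PLY (ASCII and binary little-endian), Wavefront OBJ, legacy VTK
#' POLYDATA (ASCII) and STL (ASCII and binary) files into a [surface_mesh()].
#' Units are assumed to be millimetres. Quad or larger cells raise an error
#' naming the offending cell; OBJ 1-based indices are converted internally.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"obj"`, `"vtk"`, `"stl"`; `"auto"`
#'   uses the file extension.
#' @param subject_id optional id stored on the mesh.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "vtk", "stl"),
                      subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "obj", "vtk", "stl"))
      stop("cannot infer mesh format from extension: ", path)
  }
  out <- switch(format,
                ply = read_ply(path),
                obj = read_obj(path),
                vtk = read_vtk_polydata(path),
                stl = read_stl(path))
  surface_mesh(out$vertices, out$triangles, subject_id = subject_id)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; header <- character()
  elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated PLY header")
    header <- c(header, line)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      p <- if (tok[2] == "list") list(list = TRUE, count_type = tok[3],
                                      type = tok[4], name = tok[5])
           else list(list = FALSE, type = tok[2], name = tok[3])
      elements[[cur]]$props <- c(elements[[cur]]$props, list(p))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY header missing format line")
  if (!"vertex" %in% names(elements) || !"face" %in% names(elements))
    stop("PLY file lacks vertex or face element")

  if (fmt == "ascii") {
    dat <- readLines(con)
    dat <- dat[nzchar(trimws(dat))]
    nv <- elements$vertex$count; nf <- elements$face$count
    vlines <- dat[seq_len(nv)]
    flines <- dat[nv + seq_len(nf)]
    vprops <- vapply(elements$vertex$props, function(p) p$name, "")
    vm <- matrix(scan(text = vlines, quiet = TRUE), nrow = nv, byrow = TRUE)
    v <- vm[, match(c("x", "y", "z"), vprops), drop = FALSE]
    f <- t(vapply(strsplit(trimws(flines), "\\s+"), function(tk) {
      n <- as.integer(tk[1])
      if (n != 3L) stop("non-triangular PLY face with ", n, " vertices")
      as.integer(tk[2:4])
    }, integer(3)))
  } else if (fmt == "binary_little_endian") {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    read_scalar <- function(type, n = 1L) {
      sz <- sizes[[type]]
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "numeric" else "integer"
      readBin(con, what, n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    nv <- elements$vertex$count
    vp <- elements$vertex$props
    if (any(vapply(vp, function(p) p$list, TRUE)))
      stop("list properties on PLY vertices are unsupported")
    vtypes <- vapply(vp, function(p) p$type, "")
    vnames <- vapply(vp, function(p) p$name, "")
    if (length(unique(vtypes)) == 1L) {
      vm <- matrix(read_scalar(vtypes[1], nv * length(vp)),
                   nrow = nv, byrow = TRUE)
    } else {
      vm <- matrix(0, nv, length(vp))
      for (i in seq_len(nv)) for (j in seq_along(vp))
        vm[i, j] <- read_scalar(vtypes[j], 1L)
    }
    v <- vm[, match(c("x", "y", "z"), vnames), drop = FALSE]
    nf <- elements$face$count
    fp <- elements$face$props[[1]]
    if (!fp$list) stop("PLY face element must be a list property")
    f <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- read_scalar(fp$count_type, 1L)
      if (cnt != 3L) stop("non-triangular PLY face ", i, " with ", cnt, " vertices")
      f[i, ] <- read_scalar(fp$type, 3L)
    }
  } else stop("unsupported PLY format: ", fmt)
  list(vertices = v, triangles = f + 1L)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines)) stop("OBJ file has no vertices: ", path)
  v <- matrix(scan(text = gsub("^v\\s+", "", vlines), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- t(vapply(seq_along(flines), function(i) {
    tk <- strsplit(gsub("^f\\s+", "", flines[i]), "\\s+")[[1]]
    if (length(tk) != 3L)
      stop("non-triangular OBJ face ", i, " with ", length(tk), " vertices")
    ## tokens may be v, v/vt, v/vt/vn or v//vn
    as.integer(vapply(strsplit(tk, "/"), `[[`, "", 1L))
  }, integer(3)))
  neg <- f < 0L               # negative OBJ indices count from the end
  if (any(neg)) f[neg] <- nrow(v) + 1L + f[neg]
  list(vertices = v, triangles = f)   # OBJ is 1-based already
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("POLYDATA", lines, fixed = TRUE)))
    stop("legacy VTK file is not POLYDATA: ", path)
  pi0 <- grep("^POINTS", lines)[1]
  if (is.na(pi0)) stop("VTK file has no POINTS section")
  np <- as.integer(strsplit(trimws(lines[pi0]), "\\s+")[[1]][2])
  vals <- numeric(0); i <- pi0 + 1L
  while (length(vals) < 3L * np) {
    vals <- c(vals, scan(text = lines[i], quiet = TRUE))
    i <- i + 1L
  }
  v <- matrix(vals[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  ci0 <- grep("^POLYGONS", lines)[1]
  if (is.na(ci0)) stop("VTK file has no POLYGONS section")
  hdr <- as.integer(strsplit(trimws(lines[ci0]), "\\s+")[[1]][2:3])
  ivals <- integer(0); i <- ci0 + 1L
  while (length(ivals) < hdr[2]) {
    ivals <- c(ivals, as.integer(scan(text = lines[i], quiet = TRUE)))
    i <- i + 1L
  }
  f <- matrix(0L, hdr[1], 3L); k <- 1L
  for (r in seq_len(hdr[1])) {
    cnt <- ivals[k]
    if (cnt != 3L) stop("non-triangular VTK polygon ", r, " with ", cnt, " vertices")
    f[r, ] <- ivals[k + 1:3]
    k <- k + 1L + cnt
  }
  list(vertices = v, triangles = f + 1L)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  sz <- file.info(path)$size
  is_binary <- is.finite(sz) && sz == 84 + 50 * ntri && ntri > 0
  if (is_binary) {
    on.exit(close(con))
    v <- matrix(0, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      v[3L * (i - 1L) + 1:3, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    }
    f <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
    return(list(vertices = v, triangles = f))
  }
  close(con)
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) %% 3L != 0L) stop("malformed ASCII STL: ", path)
  v <- matrix(scan(text = gsub("^vertex\\s+", "", vl), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, triangles = f)
}

#' Write a mesh as ASCII PLY
#'
#' The canonical on-disk form used by the pipeline.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, digits = 9) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$triangles - 1L
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- apply(signif(v, digits), 1L, paste, collapse = " ")
  fl <- paste(3L, f[, 1], f[, 2], f[, 3])
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}
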