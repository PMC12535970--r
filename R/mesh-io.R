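#' Triangle mesh constructor
#'
#' Builds a validated triangle mesh. Coordinates are interpreted as
#' micrometres throughout the package.
#'
#' @param vertices numeric matrix, n x 3.
#' @param faces integer matrix, m x 3, one-based vertex indices.
#' @param validate drop zero-area faces and unreferenced vertices.
#' @return object of class `tri_mesh` with elements `vertices` and `faces`.
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(vertices) < 4L || nrow(faces) < 1L)
    stop("degenerate mesh: need at least 4 vertices and 1 face")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  if (validate) m <- drop_degenerate(m)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(m) {
  V <- m$vertices; F <- m$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

drop_degenerate <- function(m, area_tol = 1e-12) {
  keep <- face_areas(m) > area_tol &
    m$faces[, 1] != m$faces[, 2] &
    m$faces[, 2] != m$faces[, 3] &
    m$faces[, 1] != m$faces[, 3]
  m$faces <- m$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(m$faces)))
  if (length(used) < nrow(m$vertices)) {
    remap <- integer(nrow(m$vertices))
    remap[used] <- seq_along(used)
    m$vertices <- m$vertices[used, , drop = FALSE]
    m$faces[] <- remap[m$faces]
  }
  if (nrow(m$vertices) < 4L || nrow(m$faces) < 1L)
    stop("degenerate mesh: fewer than 4 vertices or no faces after validation")
  m
}

#' Merge duplicate vertices
#'
#' Vertices closer than `tol` (in every coordinate) are collapsed onto one
#' representative; faces are re-indexed and degenerate faces removed.
#'
#' @param m a `tri_mesh`.
#' @param tol merge tolerance in micrometres.
#' @export
merge_vertices <- function(m, tol = 1e-6) {
  key <- paste(round(m$vertices[, 1] / tol),
               round(m$vertices[, 2] / tol),
               round(m$vertices[, 3] / tol))
  first <- !duplicated(key)
  new_id <- cumsum(first)               # new index of each retained vertex
  rep_orig <- match(key, key)           # first original vertex with same key
  m$vertices <- m$vertices[first, , drop = FALSE]
  m$faces[] <- new_id[rep_orig][m$faces]
  drop_degenerate(m)
}

detect_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 80L)
  close(con)
  head_txt <- rawToChar(magic[magic != as.raw(0)][seq_len(min(60, sum(magic != as.raw(0))))])
  if (grepl("^ply", head_txt)) return("ply")
  if (ext == "obj" || grepl("(^|\n)\\s*v\\s", head_txt)) return("obj")
  if (ext == "stl") return("stl")
  if (grepl("^solid", head_txt)) return("stl")
  if (ext %in% c("ply", "obj", "stl")) return(ext)
  stop("unsupported mesh format for ", path)
}

#' Load a surface mesh
#'
#' Reads PLY (ascii or binary little-endian), OBJ (`v`/`f` records) or STL
#' (binary or ascii), detected by extension and magic bytes. Coordinates are
#' multiplied by `units_scale` so the result is in micrometres. Duplicate
#' vertices within 1e-6 um are merged and unreferenced vertices dropped.
#'
#' @param path file path.
#' @param units_scale positive factor converting file units to micrometres.
#' @return a `tri_mesh`.
#' @export
load_mesh <- function(path, units_scale = 1) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  stopifnot(units_scale > 0)
  fmt <- detect_mesh_format(path)
  m <- switch(fmt,
              ply = read_ply(path),
              obj = read_obj(path),
              stl = read_stl(path))
  m$vertices <- m$vertices * units_scale
  merge_vertices(tri_mesh(m$vertices, m$faces))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unreadable PLY header in ", path)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000) stop("unreadable PLY header in ", path)
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  elems <- grep("^element", header)
  get_count <- function(name) {
    ln <- grep(paste0("^element ", name), header, value = TRUE)
    if (!length(ln)) stop("PLY missing element ", name)
    as.integer(strsplit(trimws(ln), "\\s+")[[1]][3])
  }
  nv <- get_count("vertex")
  nf <- get_count("face")
  # vertex property types (only x,y,z and possibly extras)
  vstart <- grep("^element vertex", header)
  vend <- elems[elems > vstart][1]
  if (is.na(vend)) vend <- grep("^end_header", header)
  vprops <- grep("^property", header[seq(vstart + 1, vend - 1)], value = TRUE)
  vtypes <- vapply(strsplit(trimws(vprops), "\\s+"), `[`, "", 2L)
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int = 4L, uint = 4L, int32 = 4L, uint32 = 4L)
  if (binary) {
    V <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(vtypes))
      for (j in seq_along(vtypes)) {
        tp <- vtypes[j]
        row[j] <- if (tp %in% c("float", "float32")) {
          readBin(con, "numeric", 1L, size = 4L, endian = "little")
        } else if (tp %in% c("double", "float64")) {
          readBin(con, "numeric", 1L, size = 8L, endian = "little")
        } else {
          readBin(con, "integer", 1L, size = sizes[[tp]], endian = "little")
        }
      }
      V[i, ] <- row[1:3]
    }
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      idx <- readBin(con, "integer", cnt, size = 4L, endian = "little")
      if (cnt != 3L) stop("only triangle PLY faces are supported")
      F[i, ] <- idx + 1L
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    V <- t(vapply(vl, function(x) as.numeric(x[1:3]), numeric(3)))
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    F <- t(vapply(fl, function(x) {
      if (as.integer(x[1]) != 3L) stop("only triangle PLY faces are supported")
      as.integer(x[2:4]) + 1L
    }, integer(3)))
  }
  list(vertices = V, faces = F)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[grepl("^v\\s", lines)]
  flines <- lines[grepl("^f\\s", lines)]
  if (!length(vlines) || !length(flines)) stop("degenerate mesh: OBJ has no v/f records")
  V <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  F <- t(vapply(strsplit(trimws(flines), "\\s+"), function(x) {
    ids <- vapply(strsplit(x[-1], "/"), `[`, "", 1L)
    if (length(ids) != 3L) stop("only triangle OBJ faces are supported")
    as.integer(ids)
  }, integer(3)))
  list(vertices = V, faces = F)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 5L)
  close(con)
  if (identical(rawToChar(hdr), "solid") && is_ascii_stl(path)) {
    return(read_stl_ascii(path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  V <- matrix(0, nt * 3L, 3)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L) # attribute byte count
    V[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  F <- matrix(seq_len(nt * 3L), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 3L, warn = FALSE))
  any(grepl("facet", txt))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[grepl("^\\s*vertex\\s", lines)]
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  if (nrow(V) %% 3 != 0) stop("malformed ascii STL")
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

#' Write a mesh as ascii PLY
#'
#' Coordinates are written as float64 so a write/read round trip reproduces
#' them bit-compatibly.
#'
#' @param m a `tri_mesh`.
#' @param path output path.
#' @export
write_ply <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply",
               "format ascii 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     m$faces[, 1] - 1L, m$faces[, 2] - 1L, m$faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as OBJ
#' @param m a `tri_mesh`.
#' @param path output path.
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", m$faces[, 1], m$faces[, 2], m$faces[, 3]), con)
  invisible(path)
}

#' Write a mesh as binary STL
#' @param m a `tri_mesh`.
#' @param path output path.
#' @export
write_stl <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(m$faces)), con, size = 4L, endian = "little")
  V <- m$vertices; F <- m$faces
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], , drop = FALSE]
    u <- tri[2, ] - tri[1, ]; w <- tri[3, ] - tri[1, ]
    nrm <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3], u[1] * w[2] - u[2] * w[1])
    nl <- sqrt(sum(nrm^2)); if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# unique undirected edges of a mesh and their Euclidean lengths
mesh_edges <- function(m) {
  F <- m$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(1, 3)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(m$vertices) + 1) + pmax(e[, 1], e[, 2])
  e <- e[!duplicated(key), , drop = FALSE]
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  d <- m$vertices[e[, 1], , drop = FALSE] - m$vertices[e[, 2], , drop = FALSE]
  list(edges = e, lengths = sqrt(rowSums(d^2)))
}

# TRUE when every edge is shared by exactly two faces
is_watertight <- function(m) {
  F <- m$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- sort(pmin(e[, 1], e[, 2]) * (nrow(m$vertices) + 1) +
                pmax(e[, 1], e[, 2]))
  r <- rle(key)
  all(r$lengths == 2L)
}

# signed volume from the divergence theorem (consistent outward winding)
mesh_volume_signed <- function(m) {
  V <- m$vertices; F <- m$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

mesh_surface_area <- function(m) sum(face_areas(m))
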