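#' Read a triangle mesh from PLY, OBJ or STL
#'
#' PLY is the canonical on-disk format; both `ascii` and
#' `binary_little_endian` PLY files are accepted. OBJ and ASCII STL are
#' supported for interchange. Only triangular faces are allowed: a file with
#' quads or larger polygons is rejected with an error naming the face.
#' Vertex order is preserved as stored, except for STL, whose per-facet
#' duplicated vertices are merged on identical coordinates.
#'
#' @param path path to the mesh file.
#' @param format one of `"auto"` (default; by file extension), `"ply"`,
#'   `"obj"`, `"stl"`.
#' @return a [triangle_mesh()].
#' @seealso [save_mesh()], [read_points()]
#' @export
load_mesh <- function(path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") format <- format_from_extension(path)
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' Writes ASCII variants of all three formats. Round trips through
#' [load_mesh()] reproduce vertex coordinates to at least 1e-6 m and, for
#' PLY and OBJ, identical connectivity (STL stores bare facets, so
#' connectivity is re-derived by merging duplicate vertices on load).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format one of `"auto"` (by extension), `"ply"`, `"obj"`, `"stl"`.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  validate_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") format <- format_from_extension(path)
  con <- file(path, "w")
  on.exit(close(con))
  switch(format,
         ply = write_ply(mesh, con),
         obj = write_obj(mesh, con),
         stl = write_stl(mesh, con))
  invisible(path)
}

format_from_extension <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% c("ply", "obj", "stl"))
    stop("cannot infer mesh format from extension '.", ext,
         "'; pass 'format' explicitly")
  ext
}

## ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", n = 1L, size = sz, endian = "little",
            signed = !(sz < 4L && grepl("^u", type)))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header not terminated: ", path)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property") {
      if (tok[2L] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], type = tok[4L], list = TRUE,
               count_type = tok[3L])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], type = tok[2L], list = FALSE)
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' (ascii or binary_little_endian)")
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("PLY file must contain 'vertex' and 'face' elements")

  if (fmt == "ascii") {
    read_ply_ascii(con, elements, path)
  } else {
    read_ply_binary(con, elements, path)
  }
}

read_ply_ascii <- function(con, elements, path) {
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    lines <- readLines(con, n = el$count)
    if (length(lines) < el$count)
      stop("truncated PLY file: ", path)
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      ix <- match(c("x", "y", "z"), pn)
      if (anyNA(ix)) stop("PLY vertex element lacks x/y/z properties")
      verts <- t(vapply(toks, function(tk) as.numeric(tk[ix]), numeric(3L)))
    } else if (el$name == "face") {
      faces <- lapply(seq_along(toks), function(i) {
        tk <- as.numeric(toks[[i]])
        if (tk[1L] != 3L)
          stop("non-triangular face ", i, " (", tk[1L], " vertices) in ", path)
        tk[2:4] + 1
      })
      faces <- do.call(rbind, faces)
    }
  }
  triangle_mesh(verts, faces)
}

read_ply_binary <- function(con, elements, path) {
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      verts <- matrix(NA_real_, el$count, 3L)
      for (i in seq_len(el$count)) {
        row <- vapply(el$props, function(p) ply_read_scalar(con, p$type),
                      numeric(1L))
        verts[i, ] <- row[match(c("x", "y", "z"), pn)]
      }
    } else if (el$name == "face") {
      faces <- matrix(NA_integer_, el$count, 3L)
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (isTRUE(p$list)) {
            k <- ply_read_scalar(con, p$count_type)
            if (k != 3L)
              stop("non-triangular face ", i, " (", k, " vertices) in ", path)
            faces[i, ] <- vapply(1:3, function(j) ply_read_scalar(con, p$type),
                                 numeric(1L)) + 1L
          } else {
            ply_read_scalar(con, p$type)
          }
        }
      }
    } else {
      # skip unknown fixed-size elements
      for (i in seq_len(el$count))
        for (p in el$props) ply_read_scalar(con, p$type)
    }
  }
  triangle_mesh(verts, faces)
}

write_ply <- function(mesh, con) {
  v <- mesh$vertices
  tr <- mesh$triangles
  writeLines(c("ply", "format ascii 1.0",
               "comment written by tinterrain",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(tr)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L,
                     tr[, 3L] - 1L), con)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ file has no vertices or no faces: ", path)
  verts <- t(vapply(strsplit(vlines, "[[:space:]]+"),
                    function(tk) as.numeric(tk[2:4]), numeric(3L)))
  faces <- lapply(seq_along(flines), function(i) {
    tk <- strsplit(flines[[i]], "[[:space:]]+")[[1L]][-1L]
    if (length(tk) != 3L)
      stop("non-triangular face ", i, " (", length(tk), " vertices) in ", path)
    # face refs may be v, v/vt, v/vt/vn or v//vn; keep the vertex index
    as.integer(sub("/.*", "", tk))
  })
  faces <- do.call(rbind, faces)
  if (any(faces < 0L)) stop("negative (relative) OBJ indices not supported")
  triangle_mesh(verts, faces)
}

write_obj <- function(mesh, con) {
  v <- mesh$vertices
  tr <- mesh$triangles
  writeLines("# written by tinterrain", con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("f %d %d %d", tr[, 1L], tr[, 2L], tr[, 3L]), con)
}

## ---- STL (ASCII) ----

read_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!startsWith(lines[1L], "solid"))
    stop("only ASCII STL is supported (file does not start with 'solid'): ",
         path)
  vlines <- lines[startsWith(lines, "vertex")]
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed STL: vertex count not a multiple of 3 in ", path)
  pts <- t(vapply(strsplit(vlines, "[[:space:]]+"),
                  function(tk) as.numeric(tk[2:4]), numeric(3L)))
  # merge exactly coincident vertices to recover shared connectivity
  key <- paste(pts[, 1L], pts[, 2L], pts[, 3L], sep = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  verts <- pts[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

write_stl <- function(mesh, con) {
  v <- mesh$vertices
  tr <- mesh$triangles
  writeLines("solid tinterrain", con)
  for (i in seq_len(nrow(tr))) {
    p <- v[tr[i, ], , drop = FALSE]
    cr <- drop(cross3(p[2L, , drop = FALSE] - p[1L, , drop = FALSE],
                      p[3L, , drop = FALSE] - p[1L, , drop = FALSE]))
    nn <- sqrt(sum(cr^2))
    n <- if (nn > 0) cr / nn else c(0, 0, 1)
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1L], n[2L], n[3L]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", p[, 1L], p[, 2L],
                         p[, 3L]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid tinterrain", con)
}

## ---- point clouds ----

#' Read a 3D point cloud from XYZ/CSV text
#'
#' Reads the first three numeric columns (Easting, Northing, vertical;
#' metres) from a comma- or whitespace-delimited text file. A single header
#' line is detected and skipped automatically.
#'
#' @param path path to the text file.
#' @return n x 3 numeric matrix with columns `E`, `N`, `Z`.
#' @seealso [delaunay_triangulate()] to turn the points into a TIN.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("cannot read point file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tok1 <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(tok1))))
  df <- utils::read.table(path, header = header, sep = sep,
                          comment.char = "#", strip.white = TRUE)
  if (ncol(df) < 3L) stop("point file needs at least 3 columns (E, N, Z)")
  pts <- as.matrix(df[, 1:3])
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("non-numeric values in point file: ", path)
  colnames(pts) <- c("E", "N", "Z")
  pts
}
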