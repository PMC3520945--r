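#' Construct a triangulated irregular network (TIN)
#'
#' A `triangle_mesh` is the basic surface representation used throughout the
#' package: a matrix of 3D vertex positions plus a matrix of vertex-index
#' triples describing the triangular faces. Coordinates follow the
#' right-handed (Easting, Northing, up) convention in metres: the third axis
#' is positive upwards, so depths are negative. Files that store depth
#' positive-down must be negated by the caller on import.
#'
#' @param vertices numeric matrix (or data frame) with 3 columns: Easting,
#'   Northing and vertical position (metres, up positive). At least 3 rows.
#' @param triangles integer matrix with 3 columns of 1-based vertex indices,
#'   one row per triangular face. At least 1 row.
#' @param validate if `TRUE` (default), check the mesh invariants and warn
#'   about zero-area (degenerate) faces. Degenerate faces are retained; they
#'   contribute zero to every area-based measure.
#' @return an object of class `triangle_mesh`: a list with elements
#'   `vertices` (n x 3 numeric matrix, columns `E`, `N`, `Z`) and
#'   `triangles` (m x 3 integer matrix).
#' @examples
#' m <- triangle_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'   rbind(c(1, 2, 3), c(1, 3, 4))
#' )
#' m
#' @export
triangle_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (E, N, Z)")
  if (ncol(triangles) != 3L)
    stop("'triangles' must have 3 columns of vertex indices")
  dimnames(vertices) <- list(NULL, c("E", "N", "Z"))
  dimnames(triangles) <- NULL
  mesh <- structure(list(vertices = vertices, triangles = triangles),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate a triangle mesh
#'
#' Checks the structural invariants of a [triangle_mesh()]: finite vertex
#' coordinates, at least 3 vertices and 1 triangle, all triangle indices in
#' range, and three distinct indices per face. Zero-area faces raise a
#' warning listing the offending face indices but are not removed.
#'
#' @param mesh a `triangle_mesh`.
#' @return the mesh, invisibly.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  if (nrow(v) < 3L) stop("mesh must have at least 3 vertices")
  if (nrow(tr) < 1L) stop("mesh must have at least 1 triangle")
  if (!all(is.finite(v))) stop("vertex coordinates must be finite")
  if (anyNA(tr) || min(tr) < 1L || max(tr) > nrow(v))
    stop("triangle indices out of range [1, ", nrow(v), "]")
  dup <- tr[, 1L] == tr[, 2L] | tr[, 2L] == tr[, 3L] | tr[, 1L] == tr[, 3L]
  if (any(dup))
    stop("triangles with repeated vertex indices: ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  areas <- triangle_areas(mesh)
  if (any(areas == 0))
    warning("mesh contains ", sum(areas == 0), " zero-area triangle(s): ",
            paste(utils::head(which(areas == 0), 5L), collapse = ", "))
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  rngE <- range(x$vertices[, 1L])
  rngN <- range(x$vertices[, 2L])
  rngZ <- range(x$vertices[, 3L])
  cat("Triangulated irregular network (TIN)\n")
  cat("  vertices :", nrow(x$vertices), "\n")
  cat("  triangles:", nrow(x$triangles), "\n")
  cat(sprintf("  extent   : E [%.3f, %.3f]  N [%.3f, %.3f]  Z [%.3f, %.3f] m\n",
              rngE[1L], rngE[2L], rngN[1L], rngN[2L], rngZ[1L], rngZ[2L]))
  invisible(x)
}

#' Construct a plane from a normal vector and offset
#'
#' Planes are stored in Hessian normal form: points `p` on the plane satisfy
#' `normal . p + offset = 0`. The same object serves for the vertical
#' slicing plane of the virtual chain and for the PCA plane of best fit.
#' The normal is renormalised to unit length on construction.
#'
#' @param normal numeric length-3 vector, the plane normal (need not be unit
#'   length; must be non-zero).
#' @param offset signed scalar offset (metres).
#' @return an object of class `tin_plane` with unit `normal` and `offset`.
#' @examples
#' plane(c(0, 0, 1), -2)   # the horizontal plane z = 2
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || !all(is.finite(normal)))
    stop("'normal' must be a finite length-3 vector")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-300) stop("plane normal must be non-zero")
  structure(list(normal = normal / nn, offset = as.numeric(offset) / nn),
            class = "tin_plane")
}

#' @export
print.tin_plane <- function(x, ...) {
  cat(sprintf("plane: %.6g E + %.6g N + %.6g Z + %.6g = 0\n",
              x$normal[1L], x$normal[2L], x$normal[3L], x$offset))
  invisible(x)
}

#' Orthogonal distance from points to a plane
#'
#' The unsigned point-plane distance `|normal . v + offset|` for one point
#' or a matrix of points.
#'
#' @param v length-3 vector or n x 3 matrix of points.
#' @param plane a [plane()].
#' @return non-negative numeric vector of distances (metres).
#' @examples
#' point_plane_distance(c(3, 4, 5), plane(c(0, 0, 1), 0))  # 5
#' @export
point_plane_distance <- function(v, plane) {
  stopifnot(inherits(plane, "tin_plane"))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  abs(v[, 1L] * plane$normal[1L] + v[, 2L] * plane$normal[2L] +
        v[, 3L] * plane$normal[3L] + plane$offset)
}

# cross product of 3-vectors given as the rows of two matrices
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# m x 3 matrix of half cross products (area-weighted face normals); the row
# norm is the triangle area, the direction the (unoriented) face normal
tri_cross <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  cross3(v[tr[, 2L], , drop = FALSE] - a, v[tr[, 3L], , drop = FALSE] - a) / 2
}

# areas of every face of a mesh
triangle_areas <- function(mesh) {
  cr <- tri_cross(mesh)
  sqrt(rowSums(cr^2))
}

#' Area of a triangle
#'
#' Half the magnitude of the cross product of two edge vectors. Degenerate
#' (collinear) triangles have area 0.
#'
#' @param tri 3 x 3 numeric matrix, one vertex per row.
#' @return non-negative area in m^2.
#' @examples
#' triangle_area(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))  # 0.5
#' @export
triangle_area <- function(tri) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3L, ncol(tri) == 3L, all(is.finite(tri)))
  cr <- cross3(tri[2L, , drop = FALSE] - tri[1L, , drop = FALSE],
               tri[3L, , drop = FALSE] - tri[1L, , drop = FALSE])
  sqrt(sum(cr^2)) / 2
}

#' Oriented unit normal of a triangle
#'
#' The face normal is the normalised cross product of two edge vectors with
#' the sign fixed by an upward-facing convention: the vertical component is
#' made non-negative (terrain imaged from overhead faces up). For exactly
#' vertical faces the Northing component is made non-negative instead, and
#' if that is also zero, the Easting component.
#'
#' @param tri 3 x 3 numeric matrix, one vertex per row.
#' @return unit length-3 numeric vector.
#' @examples
#' triangle_normal(rbind(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5)))  # c(0, 0, 1)
#' @export
triangle_normal <- function(tri) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3L, ncol(tri) == 3L, all(is.finite(tri)))
  cr <- drop(cross3(tri[2L, , drop = FALSE] - tri[1L, , drop = FALSE],
                    tri[3L, , drop = FALSE] - tri[1L, , drop = FALSE]))
  nn <- sqrt(sum(cr^2))
  if (nn < 1e-300) stop("degenerate (zero-area) triangle has no normal")
  orient_up(cr / nn)
}

# flip a unit vector so Z >= 0; tie-break on N then E for vertical planes
orient_up <- function(n, tol = 1e-12) {
  if (n[3L] < -tol) return(-n)
  if (abs(n[3L]) <= tol) {
    if (n[2L] < -tol) return(-n)
    if (abs(n[2L]) <= tol && n[1L] < 0) return(-n)
  }
  n
}

#' Edge-length statistics of a mesh
#'
#' Mean, median and maximum length over the unique (undirected) edges of the
#' mesh. The median edge length is the usual basis for choosing the chain
#' selection threshold `gamma` (see [chain_transect()]).
#'
#' @param mesh a `triangle_mesh`.
#' @return named list with `mean`, `median`, `max` (metres) and `n_edges`.
#' @export
edge_length_stats <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  list(mean = mean(len), median = stats::median(len), max = max(len),
       n_edges = length(len))
}
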