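#' Delaunay triangulation of a 2.5D point cloud
#'
#' Triangulates scattered terrain points into a TIN. The triangulation is
#' computed on the Easting-Northing projection of the points (the standard
#' 2.5D setting for overhead-surveyed bathymetry) and the vertical
#' coordinate is carried through unchanged, so every input point becomes a
#' mesh vertex in its original order.
#'
#' The implementation is an incremental Bowyer-Watson insertion with a
#' super-triangle, suitable for clouds up to a few thousand points. Points
#' lying exactly on a circumcircle (e.g. the four corners of a square grid
#' cell) are treated as outside it, so any of the equally valid diagonal
#' splits may be returned; all satisfy the empty-circumcircle property with
#' boundary-case equality.
#'
#' @param points n x 3 matrix of (E, N, Z) coordinates (an n x 2 matrix is
#'   accepted and given Z = 0). At least 3 points, not all collinear in the
#'   E-N projection, no duplicated E-N locations.
#' @return a [triangle_mesh()] over the input points.
#' @examples
#' pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' delaunay_triangulate(pts)
#' @export
delaunay_triangulate <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) == 2L) pts <- cbind(pts, 0)
  if (ncol(pts) != 3L) stop("'points' must have 2 or 3 columns")
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to triangulate")
  if (!all(is.finite(pts))) stop("point coordinates must be finite")
  x <- pts[, 1L]
  y <- pts[, 2L]
  if (anyDuplicated(paste(x, y)))
    stop("duplicated E-N locations cannot be triangulated (2.5D input)")
  ctr <- c(mean(x), mean(y))
  sv <- svd(cbind(x - ctr[1L], y - ctr[2L]), nu = 0L, nv = 0L)$d
  if (sv[2L] <= 1e-12 * sv[1L])
    stop("points are collinear in the E-N projection; no triangulation exists")

  scale <- max(max(x) - min(x), max(y) - min(y))
  # super-triangle comfortably containing all points
  sx <- c(ctr[1L] - 20 * scale, ctr[1L] + 20 * scale, ctr[1L])
  sy <- c(ctr[2L] - 10 * scale, ctr[2L] - 10 * scale, ctr[2L] + 20 * scale)
  px <- c(x, sx)
  py <- c(y, sy)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  cap <- max(64L, 4L * n)
  ta <- matrix(NA_integer_, cap, 3L)    # triangle vertex indices, CCW
  ta[1L, ] <- ccw(c(s1, s2, s3), px, py)
  ntri <- 1L
  active <- rep(FALSE, cap)
  active[1L] <- TRUE
  tol <- 1e-10 * scale^4

  for (p in seq_len(n)) {
    ids <- which(active[seq_len(ntri)])
    ax <- px[ta[ids, 1L]] - px[p]; ay <- py[ta[ids, 1L]] - py[p]
    bx <- px[ta[ids, 2L]] - px[p]; by <- py[ta[ids, 2L]] - py[p]
    cx <- px[ta[ids, 3L]] - px[p]; cy <- py[ta[ids, 3L]] - py[p]
    a2 <- ax * ax + ay * ay
    b2 <- bx * bx + by * by
    c2 <- cx * cx + cy * cy
    det <- ax * (by * c2 - cy * b2) -
      ay * (bx * c2 - cx * b2) +
      a2 * (bx * cy - cx * by)
    bad <- ids[det > tol]
    if (length(bad) == 0L)
      stop("Bowyer-Watson insertion failed (degenerate configuration)")
    # cavity boundary: edges of bad triangles that appear exactly once
    ed <- rbind(ta[bad, c(1L, 2L), drop = FALSE],
                ta[bad, c(2L, 3L), drop = FALSE],
                ta[bad, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    once <- !(key %in% key[duplicated(key)])
    ed <- ed[once, , drop = FALSE]
    active[bad] <- FALSE
    need <- ntri + nrow(ed)
    if (need > cap) {
      newcap <- max(2L * cap, need)
      tmp <- matrix(NA_integer_, newcap, 3L)
      tmp[seq_len(ntri), ] <- ta[seq_len(ntri), ]
      ta <- tmp
      active <- c(active, rep(FALSE, newcap - cap))
      cap <- newcap
    }
    for (k in seq_len(nrow(ed))) {
      ntri <- ntri + 1L
      ta[ntri, ] <- ccw(c(p, ed[k, 1L], ed[k, 2L]), px, py)
      active[ntri] <- TRUE
    }
  }
  keep <- which(active[seq_len(ntri)])
  tri <- ta[keep, , drop = FALSE]
  tri <- tri[tri[, 1L] <= n & tri[, 2L] <= n & tri[, 3L] <= n, , drop = FALSE]
  if (nrow(tri) == 0L)
    stop("triangulation degenerate: no triangles among the input points")
  triangle_mesh(pts, tri)
}

# order a vertex index triple counter-clockwise in the E-N projection
ccw <- function(t3, px, py) {
  cr <- (px[t3[2L]] - px[t3[1L]]) * (py[t3[3L]] - py[t3[1L]]) -
    (py[t3[2L]] - py[t3[1L]]) * (px[t3[3L]] - px[t3[1L]])
  if (cr < 0) t3[c(1L, 3L, 2L)] else t3
}
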