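#' Specify a rectangular measurement window
#'
#' The window is the horizontal footprint over which one feature record is
#' computed; its size sets the measurement scale, playing the role the
#' chain length plays for transect rugosity. The rectangle may be rotated:
#' `orientation` is the angle of its long (`length`) axis from East,
#' counter-clockwise, in degrees.
#'
#' @param centre length-2 (E, N) window centre (m).
#' @param width window extent across the long axis (m), > 0.
#' @param length window extent along the long axis (m), > 0; defaults to
#'   `width` (square window).
#' @param orientation angle of the long axis from East (degrees, CCW);
#'   default 0 = axis-aligned.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(centre, width, length = width, orientation = 0) {
  centre <- as.numeric(centre)
  stopifnot(base::length(centre) == 2L, width > 0, length > 0)
  structure(list(centre = centre, width = as.numeric(width),
                 length = as.numeric(length),
                 orientation = as.numeric(orientation)),
            class = "window_spec")
}

#' Build a spatial index over mesh triangles
#'
#' Bins triangle centroids into a regular grid of cells in the E-N plane so
#' that window extraction only examines triangles near the query rectangle
#' instead of scanning the whole mesh. Because a triangle lying entirely
#' inside a convex window necessarily has its centroid inside it, querying
#' the cells overlapping the window yields a superset of the members, which
#' [extract_window()] then filters exactly; indexed and exhaustive
#' extraction give identical results. The index also caches the
#' area-weighted face normals (half cross products) reused by the area
#' computations.
#'
#' @param mesh a [triangle_mesh()].
#' @param cellsize bin edge length (m); default 1/32 of the larger E-N
#'   extent.
#' @return an object of class `mesh_index`.
#' @export
mesh_index <- function(mesh, cellsize = NULL) {
  v <- mesh$vertices
  tr <- mesh$triangles
  if (is.null(cellsize)) {
    ext <- max(diff(range(v[, 1L])), diff(range(v[, 2L])))
    cellsize <- max(ext / 32, 1e-9)
  }
  cx <- (v[tr[, 1L], 1L] + v[tr[, 2L], 1L] + v[tr[, 3L], 1L]) / 3
  cy <- (v[tr[, 1L], 2L] + v[tr[, 2L], 2L] + v[tr[, 3L], 2L]) / 3
  origin <- c(min(cx), min(cy))
  ix <- pmin(floor((cx - origin[1L]) / cellsize),
             floor((max(cx) - origin[1L]) / cellsize))
  iy <- pmin(floor((cy - origin[2L]) / cellsize),
             floor((max(cy) - origin[2L]) / cellsize))
  nx <- max(ix) + 1L
  key <- ix + iy * nx
  ord <- order(key)
  cross <- tri_cross(mesh)
  structure(list(ord = ord, key = key[ord], nx = nx, ny = max(iy) + 1L,
                 origin = origin, cellsize = cellsize, n_tri = nrow(tr),
                 cross = cross, area = sqrt(rowSums(cross^2))),
            class = "mesh_index")
}

# triangle ids whose centroid falls in cells overlapping the bbox (superset)
index_query <- function(index, xmin, xmax, ymin, ymax) {
  cs <- index$cellsize
  i0 <- max(0L, floor((xmin - index$origin[1L]) / cs))
  i1 <- min(index$nx - 1L, floor((xmax - index$origin[1L]) / cs))
  j0 <- max(0L, floor((ymin - index$origin[2L]) / cs))
  j1 <- min(index$ny - 1L, floor((ymax - index$origin[2L]) / cs))
  if (i1 < i0 || j1 < j0) return(integer(0L))
  out <- vector("list", (j1 - j0 + 1L))
  for (j in j0:j1) {
    # cells j*nx + i0 .. j*nx + i1 are contiguous in the sorted keys
    lo <- findInterval(j * index$nx + i0 - 0.5, index$key) + 1L
    hi <- findInterval(j * index$nx + i1 + 0.5, index$key)
    if (hi >= lo) out[[j - j0 + 1L]] <- index$ord[lo:hi]
  }
  unlist(out, use.names = FALSE)
}

#' Extract the mesh subset inside a window
#'
#' Returns the triangles that fall entirely within the window rectangle in
#' the E-N projection (all three vertices inside the closed rectangle;
#' boundary vertices count as inside) together with the distinct vertices
#' they use. For rotated windows the test is performed after rotating
#' coordinates by `-orientation` about the window centre.
#'
#' @param mesh a [triangle_mesh()].
#' @param spec a [window_spec()].
#' @param index optional [mesh_index()]; identical results, faster on large
#'   meshes.
#' @return an object of class `window_subset`: list with `spec`, `tri_ids`
#'   (row indices into `mesh$triangles`), `triangles` (index triples) and
#'   `vertex_ids`. May be empty.
#' @export
extract_window <- function(mesh, spec, index = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(spec, "window_spec"))
  hl <- spec$length / 2
  hw <- spec$width / 2
  if (is.null(index)) {
    cand_ids <- seq_len(nrow(mesh$triangles))
  } else {
    r <- sqrt(hl^2 + hw^2)
    cand_ids <- index_query(index,
                            spec$centre[1L] - r, spec$centre[1L] + r,
                            spec$centre[2L] - r, spec$centre[2L] + r)
  }
  if (length(cand_ids) == 0L)
    return(structure(list(spec = spec, tri_ids = integer(0L),
                          triangles = matrix(integer(0L), 0L, 3L),
                          vertex_ids = integer(0L)),
                     class = "window_subset"))
  tris <- mesh$triangles[cand_ids, , drop = FALSE]
  v <- mesh$vertices
  th <- spec$orientation * pi / 180
  v_inside <- function(ids) {
    x <- v[ids, 1L] - spec$centre[1L]
    y <- v[ids, 2L] - spec$centre[2L]
    if (spec$orientation != 0) {
      xr <- cos(th) * x + sin(th) * y
      y <- -sin(th) * x + cos(th) * y
      x <- xr
    }
    abs(x) <= hl & abs(y) <= hw
  }
  keep <- v_inside(tris[, 1L]) & v_inside(tris[, 2L]) & v_inside(tris[, 3L])
  tri_ids <- cand_ids[keep]
  tris <- tris[keep, , drop = FALSE]
  structure(list(spec = spec, tri_ids = tri_ids, triangles = tris,
                 vertex_ids = unique(as.vector(tris))),
            class = "window_subset")
}

#' @export
print.window_subset <- function(x, ...) {
  cat("window subset:", nrow(x$triangles), "triangles,",
      length(x$vertex_ids), "vertices\n")
  invisible(x)
}

#' Surface area of a window subset
#'
#' The summed area of the member triangles (the contoured, draped area of
#' the terrain inside the window). An empty subset has area 0.
#'
#' @param subset a [extract_window()] result.
#' @param mesh the mesh the subset refers to.
#' @return non-negative area (m^2).
#' @export
surface_area <- function(subset, mesh) {
  stopifnot(inherits(subset, "window_subset"))
  if (length(subset$tri_ids) == 0L) return(0)
  sub <- triangle_mesh(mesh$vertices, subset$triangles, validate = FALSE)
  sum(triangle_areas(sub))
}

#' Fit the PCA plane of best fit to 3D points
#'
#' Eigen-decomposition of the covariance of the centred points yields an
#' orthonormal basis ordered by descending explained variance; the third
#' component, orthogonal to the directions of greatest scatter, is the
#' normal of the plane of best fit. Because the terrain is imaged from
#' overhead, the outward normal is taken to be the one with an upward
#' (positive vertical) component; an exactly vertical best-fit plane is
#' disambiguated towards positive Northing with a warning.
#'
#' @param points n x 3 matrix of points, n >= 3, spanning at least a plane
#'   (rank >= 2 after centring).
#' @param weights optional non-negative weights (e.g. triangle areas when
#'   fitting to triangle centroids); default unweighted.
#' @return an object of class `pca_basis`: list with `basis` (3 x 3 matrix,
#'   columns e1, e2, e3 by descending eigenvalue), `normal` (oriented
#'   = +/- e3), `centroid`, `eigenvalues`.
#' @examples
#' pts <- cbind(runif(50), runif(50), 2)        # points on z = 2
#' fit_pca_plane(pts)$normal                    # c(0, 0, 1)
#' @export
fit_pca_plane <- function(points, weights = NULL) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3L)
  if (nrow(p) < 3L) stop("need at least 3 points to fit a plane")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  stopifnot(length(weights) == nrow(p), all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  ctr <- colSums(p * w)
  d <- sweep(p, 2L, ctr)
  cv <- crossprod(d * sqrt(w), d * sqrt(w))
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] <= 1e-12 * max(eg$values[1L], 1e-300))
    stop("points are collinear (rank < 2); the best-fit plane is undefined")
  basis <- eg$vectors
  n <- basis[, 3L]
  if (abs(n[3L]) <= 1e-12) {
    warning("best-fit plane is vertical; normal oriented towards +Northing")
    n <- orient_up(n)
  } else if (n[3L] < 0) {
    n <- -n
  }
  basis[, 3L] <- n
  structure(list(basis = basis, normal = n, centroid = ctr,
                 eigenvalues = eg$values),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA plane fit: normal (%.4f, %.4f, %.4f), centroid (%.3f, %.3f, %.3f)\n",
              x$normal[1L], x$normal[2L], x$normal[3L],
              x$centroid[1L], x$centroid[2L], x$centroid[3L]))
  invisible(x)
}

#' Projected area of a window subset onto a plane
#'
#' Each member triangle contributes its area foreshortened by the absolute
#' cosine between its face normal and the projection plane normal,
#' `A_i * |n_i . n|`. The absolute value makes back-facing (overhang)
#' triangles add rather than cancel; where overhanging triangles overlap in
#' projection the projected area is then double-counted, inflating rugosity
#' — acceptable for overhead-imaged terrain, which rarely captures
#' overhangs.
#'
#' @param subset a [extract_window()] result.
#' @param mesh the mesh the subset refers to.
#' @param plane_normal unit length-3 projection plane normal.
#' @return projected area (m^2), `<= surface_area(subset, mesh)`.
#' @export
projected_area <- function(subset, mesh, plane_normal) {
  stopifnot(inherits(subset, "window_subset"))
  n <- as.numeric(plane_normal)
  stopifnot(length(n) == 3L, abs(sqrt(sum(n^2)) - 1) < 1e-6)
  if (length(subset$tri_ids) == 0L) return(0)
  sub <- triangle_mesh(mesh$vertices, subset$triangles, validate = FALSE)
  cr <- tri_cross(sub)
  sum(abs(cr[, 1L] * n[1L] + cr[, 2L] * n[2L] + cr[, 3L] * n[3L]))
}

#' Slope of a fitted plane
#'
#' The angle between the plane of best fit and the horizontal plane, equal
#' to the angle between their normals: `acos(n . k)` with `k = (0, 0, 1)`.
#'
#' @param basis a [fit_pca_plane()] result, or a unit length-3 normal.
#' @return slope in degrees, in `[0, 90]`.
#' @export
slope <- function(basis) {
  n <- basis_normal(basis)
  acos(min(1, max(-1, abs(n[3L])))) * 180 / pi
}

#' Aspect of a fitted plane, with northness and eastness
#'
#' The compass direction the sloped surface faces: the angle between North
#' and the horizontal projection of the upward plane normal, computed with
#' the four-quadrant arctangent `atan2(n_E, n_N)`. Zero faces North,
#' +90 deg faces East, range (-180, 180]. Northness (`cos`) and eastness
#' (`sin`) re-express the angle as vector components free of the -180/+180
#' wrap-around. At zero slope the normal points straight up and the facing
#' direction is undefined: all three values are returned as `NA`.
#'
#' @param basis a [fit_pca_plane()] result, or a unit length-3 normal.
#' @return named list with `aspect` (degrees), `northness`, `eastness`.
#' @export
aspect <- function(basis) {
  n <- basis_normal(basis)
  if (slope(basis) <= 1e-9)
    return(list(aspect = NA_real_, northness = NA_real_,
                eastness = NA_real_))
  psi <- atan2(n[1L], n[2L]) * 180 / pi
  if (psi <= -180) psi <- psi + 360
  list(aspect = psi, northness = cos(psi * pi / 180),
       eastness = sin(psi * pi / 180))
}

basis_normal <- function(basis) {
  n <- if (inherits(basis, "pca_basis")) basis$normal else as.numeric(basis)
  stopifnot(length(n) == 3L, abs(sqrt(sum(n^2)) - 1) < 1e-6)
  if (n[3L] < 0) n <- -n
  n
}

#' Area-based rugosity of a window subset
#'
#' The rugosity index `R = A_s / A_p`: the contoured surface area divided
#' by its orthogonal projection onto a reference plane. With
#' `projection = "pca"` the reference is the plane of best fit through the
#' window vertices, which decouples rugosity from slope (a tilted but flat
#' patch scores 1); with `"horizontal"` the reference is the E-N plane, the
#' raster-style convention that confounds rugosity with slope (a flat patch
#' at slope `a` scores `1/cos(a)`).
#'
#' Windows with fewer than `min_triangles` members, a degenerate plane fit
#' or zero projected area yield an undefined record (`NA` values and a
#' `reason` code) rather than an error, so exhaustive feature maps stay
#' total.
#'
#' @param subset a [extract_window()] result.
#' @param mesh the mesh the subset refers to.
#' @param projection `"pca"`, `"horizontal"` or `"both"` (default).
#' @param min_triangles minimum member count for a defined record
#'   (default 10; a plane fit on fewer vertices is ill-conditioned at
#'   typical mesh resolutions).
#' @param pca_weighting `"vertex"` (default; each window vertex once) or
#'   `"area"` (triangle centroids weighted by triangle area).
#' @return one-row data frame with columns `centre_E`, `centre_N`, `width`,
#'   `length`, `orientation`, `n_triangles`, `A_s`, `A_p_pca`, `A_p_ne`,
#'   `R_pca`, `R_ne`, `slope`, `aspect`, `northness`, `eastness`, `reason`
#'   (`NA` when defined). Fields not requested by `projection` are `NA`.
#' @export
rugosity <- function(subset, mesh, projection = c("both", "pca", "horizontal"),
                     min_triangles = 10L, pca_weighting = c("vertex", "area")) {
  projection <- match.arg(projection)
  pca_weighting <- match.arg(pca_weighting)
  rec <- window_record(mesh, subset, min_triangles = min_triangles,
                       pca_weighting = pca_weighting)
  if (projection == "pca") rec[c("A_p_ne", "R_ne")] <- NA_real_
  if (projection == "horizontal")
    rec[c("A_p_pca", "R_pca", "slope", "aspect", "northness",
          "eastness")] <- NA_real_
  rec
}

# the full FeatureRecord for one window; cross rows may be passed from an
# index cache to avoid recomputation
window_record <- function(mesh, subset, min_triangles = 10L,
                          pca_weighting = "vertex", cross = NULL) {
  spec <- subset$spec
  rec <- data.frame(centre_E = spec$centre[1L], centre_N = spec$centre[2L],
                    width = spec$width, length = spec$length,
                    orientation = spec$orientation,
                    n_triangles = length(subset$tri_ids),
                    A_s = NA_real_, A_p_pca = NA_real_, A_p_ne = NA_real_,
                    R_pca = NA_real_, R_ne = NA_real_, slope = NA_real_,
                    aspect = NA_real_, northness = NA_real_,
                    eastness = NA_real_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(subset$tri_ids) < min_triangles) {
    rec$reason <- "too_few_triangles"
    return(rec)
  }
  if (is.null(cross)) {
    sub <- triangle_mesh(mesh$vertices, subset$triangles, validate = FALSE)
    cr <- tri_cross(sub)
  } else {
    cr <- cross[subset$tri_ids, , drop = FALSE]
  }
  areas <- sqrt(rowSums(cr^2))
  rec$A_s <- sum(areas)
  rec$A_p_ne <- sum(abs(cr[, 3L]))
  basis <- tryCatch({
    if (pca_weighting == "area") {
      tr <- subset$triangles
      v <- mesh$vertices
      cent <- (v[tr[, 1L], , drop = FALSE] + v[tr[, 2L], , drop = FALSE] +
                 v[tr[, 3L], , drop = FALSE]) / 3
      fit_pca_plane(cent, weights = areas)
    } else {
      fit_pca_plane(mesh$vertices[subset$vertex_ids, , drop = FALSE])
    }
  }, error = function(e) NULL)
  if (is.null(basis)) {
    rec$reason <- "degenerate_pca"
    return(rec)
  }
  n <- basis$normal
  rec$A_p_pca <- sum(abs(cr[, 1L] * n[1L] + cr[, 2L] * n[2L] +
                           cr[, 3L] * n[3L]))
  if (rec$A_p_pca <= 0 || rec$A_p_ne <= 0) {
    rec$reason <- "zero_projected_area"
    return(rec)
  }
  rec$R_pca <- rec$A_s / rec$A_p_pca
  rec$R_ne <- rec$A_s / rec$A_p_ne
  rec$slope <- slope(basis)
  asp <- aspect(basis)
  rec$aspect <- asp$aspect
  rec$northness <- asp$northness
  rec$eastness <- asp$eastness
  rec
}

#' Multi-scale sliding-window terrain features
#'
#' Computes the full feature record (surface and projected areas, both
#' rugosity variants, slope, aspect, northness, eastness) for every window
#' centre at each requested window size. Each record is identical to
#' composing [extract_window()], [fit_pca_plane()] and [rugosity()] at that
#' centre. Undefined windows carry `NA` values with a reason code.
#'
#' @param mesh a [triangle_mesh()].
#' @param window_sizes numeric vector of square window side lengths (m).
#' @param centres `"every_vertex"` (a window over each mesh vertex) or
#'   `"grid"` (a regular grid of centres across the mesh extent).
#' @param stride grid spacing (m) when `centres = "grid"`.
#' @param orientation window orientation (degrees from East), default 0.
#' @param min_triangles,pca_weighting see [rugosity()].
#' @param index optional [mesh_index()]; built automatically when omitted.
#' @return named list of data frames, one per window size (names are the
#'   sizes), each with one row per centre.
#' @examples
#' m <- generate_terrain(terrain_spec("flat", extent = c(2, 2),
#'                                    resolution = 0.1))
#' ff <- multiscale_features(m, 0.5, centres = "grid", stride = 0.5)
#' ff[["0.5"]][, c("centre_E", "centre_N", "R_pca", "R_ne", "slope")]
#' @export
multiscale_features <- function(mesh, window_sizes,
                                centres = c("every_vertex", "grid"),
                                stride = NULL, orientation = 0,
                                min_triangles = 10L,
                                pca_weighting = c("vertex", "area"),
                                index = NULL) {
  centres_mode <- if (is.character(centres)) match.arg(centres) else "custom"
  pca_weighting <- match.arg(pca_weighting)
  stopifnot(all(window_sizes > 0))
  v <- mesh$vertices
  if (centres_mode == "every_vertex") {
    cen <- unique(v[, 1:2, drop = FALSE])
  } else if (centres_mode == "grid") {
    if (is.null(stride)) stop("'stride' is required for grid centres")
    cen <- as.matrix(expand.grid(
      E = seq(min(v[, 1L]), max(v[, 1L]), by = stride),
      N = seq(min(v[, 2L]), max(v[, 2L]), by = stride)))
  } else {
    cen <- as.matrix(centres)
    stopifnot(ncol(cen) == 2L)
  }
  if (is.null(index))
    index <- mesh_index(mesh, cellsize = max(window_sizes) / 4)
  out <- vector("list", length(window_sizes))
  names(out) <- as.character(window_sizes)
  for (s in seq_along(window_sizes)) {
    size <- window_sizes[s]
    rows <- vector("list", nrow(cen))
    for (i in seq_len(nrow(cen))) {
      spec <- window_spec(cen[i, ], width = size, orientation = orientation)
      sub <- extract_window(mesh, spec, index = index)
      rows[[i]] <- window_record(mesh, sub, min_triangles = min_triangles,
                                 pca_weighting = pca_weighting,
                                 cross = index$cross)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  out
}

#' Write feature records to CSV
#'
#' @param records a feature data frame (one element of
#'   [multiscale_features()]'s result).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write one feature as an ESRI ASCII grid
#'
#' Grids the per-centre values of one feature column onto a regular raster
#' by nearest centre and writes the plain-text `.asc` format (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA) understood by GIS packages.
#' Cells without a defined value get the NODATA code -9999.
#'
#' @param records a feature data frame with `centre_E`/`centre_N` columns.
#' @param field name of the feature column to grid (e.g. `"R_pca"`).
#' @param path output path (conventionally `.asc`).
#' @param cellsize raster cell size (m); default the median spacing of the
#'   distinct centre Eastings.
#' @return `path`, invisibly.
#' @export
write_feature_grid <- function(records, field, path, cellsize = NULL) {
  stopifnot(field %in% names(records))
  ex <- sort(unique(records$centre_E))
  ny <- sort(unique(records$centre_N))
  if (is.null(cellsize)) {
    sp <- c(diff(ex), diff(ny))
    if (length(sp) == 0L) stop("cannot infer cellsize from a single centre")
    cellsize <- stats::median(sp)
  }
  xs <- seq(min(ex), max(ex), by = cellsize)
  ys <- seq(min(ny), max(ny), by = cellsize)
  # nearest centre by snapping each axis independently
  ci <- findInterval(xs, ex[-length(ex)] + diff(ex) / 2) + 1
  cj <- findInterval(ys, ny[-length(ny)] + diff(ny) / 2) + 1
  key <- paste(records$centre_E, records$centre_N)
  val <- matrix(-9999, length(ys), length(xs))
  for (j in seq_along(ys)) {
    rows <- match(paste(ex[ci], ny[cj[j]]), key)
    vv <- records[[field]][rows]
    vv[is.na(vv)] <- -9999
    val[j, ] <- vv
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", length(xs)),
               paste("nrows", length(ys)),
               paste("xllcorner", min(xs) - cellsize / 2),
               paste("yllcorner", min(ys) - cellsize / 2),
               paste("cellsize", cellsize),
               "NODATA_value -9999"), con)
  # ESRI rows run north to south
  for (j in rev(seq_along(ys)))
    writeLines(paste(format(val[j, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}
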