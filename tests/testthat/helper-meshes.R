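# shared fixtures and independent oracles, all built in code

# the minimal TIN: a unit square split into two triangles
unit_square_mesh <- function(z = 0) {
  triangle_mesh(rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
                rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# seeded irregular rough terrain: Delaunay of jittered points with noisy z
rough_delaunay_mesh <- function(n = 120, seed = 42, sigma = 0.1) {
  set.seed(seed)
  pts <- cbind(runif(n, 0, 2), runif(n, 0, 2), rnorm(n, 0, sigma))
  delaunay_triangulate(pts)
}

# rotate a mesh (and optionally points) by beta degrees about the vertical
rotate_mesh <- function(mesh, beta_deg, about = c(0, 0)) {
  th <- beta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  en <- sweep(mesh$vertices[, 1:2, drop = FALSE], 2L, about) %*% t(R)
  mesh$vertices[, 1:2] <- sweep(en, 2L, about, `+`)
  mesh
}

# brute-force empty-circumcircle check: TRUE if no point lies strictly
# inside the circumcircle of any triangle
circumcircle_ok <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  for (k in seq_len(nrow(mesh$triangles))) {
    t3 <- mesh$triangles[k, ]
    a <- v[t3[1L], 1:2]; b <- v[t3[2L], 1:2]; c2 <- v[t3[3L], 1:2]
    # circumcentre by solving the perpendicular-bisector system
    d <- 2 * (a[1L] * (b[2L] - c2[2L]) + b[1L] * (c2[2L] - a[2L]) +
                c2[1L] * (a[2L] - b[2L]))
    ux <- (sum(a^2) * (b[2L] - c2[2L]) + sum(b^2) * (c2[2L] - a[2L]) +
             sum(c2^2) * (a[2L] - b[2L])) / d
    uy <- (sum(a^2) * (c2[1L] - b[1L]) + sum(b^2) * (a[1L] - c2[1L]) +
             sum(c2^2) * (b[1L] - a[1L])) / d
    r2 <- sum((a - c(ux, uy))^2)
    d2 <- (v[, 1L] - ux)^2 + (v[, 2L] - uy)^2
    d2[t3] <- Inf
    if (any(d2 < r2 * (1 - tol))) return(FALSE)
  }
  TRUE
}

# rasterisation oracle for the projected area onto the horizontal plane:
# project every triangle to E-N, cover a fine grid of cell centres and
# count covered cells (valid when triangles tile without projective
# overlap, e.g. any 2.5D Delaunay mesh)
raster_projected_area <- function(mesh, subset = NULL, ncell = 1500L) {
  tris <- if (is.null(subset)) mesh$triangles else subset$triangles
  v <- mesh$vertices
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  dx <- diff(xr) / ncell
  dy <- diff(yr) / ncell
  xs <- xr[1L] + (seq_len(ncell) - 0.5) * dx
  ys <- yr[1L] + (seq_len(ncell) - 0.5) * dy
  covered <- matrix(FALSE, ncell, ncell)
  for (k in seq_len(nrow(tris))) {
    p <- v[tris[k, ], 1:2, drop = FALSE]
    i <- which(xs >= min(p[, 1L]) - dx & xs <= max(p[, 1L]) + dx)
    j <- which(ys >= min(p[, 2L]) - dy & ys <= max(p[, 2L]) + dy)
    if (!length(i) || !length(j)) next
    gx <- rep(xs[i], length(j))
    gy <- rep(ys[j], each = length(i))
    s1 <- (p[2L, 1L] - p[1L, 1L]) * (gy - p[1L, 2L]) -
      (p[2L, 2L] - p[1L, 2L]) * (gx - p[1L, 1L])
    s2 <- (p[3L, 1L] - p[2L, 1L]) * (gy - p[2L, 2L]) -
      (p[3L, 2L] - p[2L, 2L]) * (gx - p[2L, 1L])
    s3 <- (p[1L, 1L] - p[3L, 1L]) * (gy - p[3L, 2L]) -
      (p[1L, 2L] - p[3L, 2L]) * (gx - p[3L, 1L])
    inside <- (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
    covered[i, j][inside] <- TRUE
  }
  sum(covered) * dx * dy
}

# analytic arc-length rugosity of a transect across a sinusoid of
# amplitude A and wavelength lam, by adaptive quadrature
sinusoid_arc_ratio <- function(A, lam, span) {
  f <- function(x) sqrt(1 + (A * 2 * pi / lam * cos(2 * pi * x / lam))^2)
  stats::integrate(f, 0, span, rel.tol = 1e-12)$value / span
}
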