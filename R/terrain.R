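#' Specify a synthetic terrain
#'
#' Seeded generators for test bathymetry with known analytic structure.
#' Families:
#' \describe{
#'   \item{`flat`}{horizontal plane at `z0`.}
#'   \item{`inclined`}{plane at `slope_deg` facing `facing` (compass
#'     degrees, 0 = North): `z = z0 - tan(slope) * (E sin f + N cos f)`.}
#'   \item{`sinusoid`}{`z = z0 + amplitude * sin(2 pi d / wavelength)` with
#'     `d` the coordinate along `direction` (degrees from East).}
#'   \item{`peak_trough`}{a peak and a trough separated by an inflection
#'     line of high slope: `z = z0 + a * N' * exp(-(E'^2 + N'^2))` with
#'     `E' = E / w`, `N' = N / w`; defaults `a = 1` m, `w = 1` m on a
#'     6 m x 6 m extent.}
#'   \item{`noise_field`}{Gaussian random field: white vertical noise of
#'     standard deviation `sigma` smoothed to correlation length
#'     `corr_len` (seeded).}
#' }
#' The domain is a regular grid centred on the origin, spanning
#' `extent[1]` m in E and `extent[2]` m in N at `resolution` m spacing.
#'
#' @param family one of `"flat"`, `"inclined"`, `"sinusoid"`,
#'   `"peak_trough"`, `"noise_field"`.
#' @param extent length-2 E and N spans (m); a scalar is recycled.
#' @param resolution grid spacing (m), > 0 and at most `min(extent) / 4`.
#' @param z0 vertical offset (m); depths are negative, default 0.
#' @param slope_deg,facing inclined-plane slope (deg) and facing direction
#'   (compass deg, 0 = North, 90 = East).
#' @param amplitude,wavelength,direction sinusoid parameters (m, m, deg
#'   from East).
#' @param a,w peak-trough amplitude (m) and width scale (m).
#' @param sigma,corr_len noise-field standard deviation and correlation
#'   length (m).
#' @param jitter fraction of `resolution` by which vertex E-N positions are
#'   perturbed uniformly (0 = regular grid; > 0 produces an irregular TIN
#'   via [delaunay_triangulate()], so keep such grids small).
#' @param seed integer seed for the stochastic families and jitter.
#' @return an object of class `terrain_spec`.
#' @seealso [generate_terrain()]
#' @export
terrain_spec <- function(family = c("flat", "inclined", "sinusoid",
                                    "peak_trough", "noise_field"),
                         extent = c(6, 6), resolution = 0.05, z0 = 0,
                         slope_deg = 30, facing = 0,
                         amplitude = 0.2, wavelength = 1, direction = 0,
                         a = 1, w = 1, sigma = 0.05, corr_len = 0.2,
                         jitter = 0, seed = 1L) {
  family <- match.arg(family)
  extent <- rep(as.numeric(extent), length.out = 2L)
  stopifnot(resolution > 0, resolution <= min(extent) / 4,
            amplitude >= 0, a >= 0, sigma >= 0, jitter >= 0, jitter < 0.5)
  structure(list(family = family, extent = extent, resolution = resolution,
                 z0 = z0, slope_deg = slope_deg, facing = facing,
                 amplitude = amplitude, wavelength = wavelength,
                 direction = direction, a = a, w = w, sigma = sigma,
                 corr_len = corr_len, jitter = jitter,
                 seed = as.integer(seed)),
            class = "terrain_spec")
}

#' Generate a synthetic terrain mesh
#'
#' Builds the TIN for a [terrain_spec()]. Regular grids are triangulated by
#' the diagonal cell split (a valid Delaunay triangulation of a square
#' grid, where the cocircular cell corners make either diagonal
#' admissible); jittered grids are triangulated with
#' [delaunay_triangulate()]. Identical spec and seed give identical meshes.
#' The analytic height function is attached as the `"height_fn"` attribute
#' (taking E and N vectors; `NULL` for `noise_field`) so tests can compare
#' against closed-form geometry.
#'
#' @param spec a [terrain_spec()].
#' @return a [triangle_mesh()] with attribute `height_fn`.
#' @examples
#' m <- generate_terrain(terrain_spec("peak_trough", extent = c(6, 6),
#'                                    resolution = 0.1))
#' m
#' @export
generate_terrain <- function(spec) {
  stopifnot(inherits(spec, "terrain_spec"))
  es <- seq(-spec$extent[1L] / 2, spec$extent[1L] / 2, by = spec$resolution)
  ns <- seq(-spec$extent[2L] / 2, spec$extent[2L] / 2, by = spec$resolution)
  g <- expand.grid(E = es, N = ns)
  E <- g$E
  N <- g$N
  if (spec$jitter > 0) {
    with_seed(spec$seed + 1L, {
      E <- E + stats::runif(length(E), -1, 1) * spec$jitter * spec$resolution
      N <- N + stats::runif(length(N), -1, 1) * spec$jitter * spec$resolution
    })
  }
  hf <- height_function(spec)
  if (spec$family == "noise_field") {
    z <- spec$z0 + noise_field_heights(length(es), length(ns),
                                       spec$resolution, spec$sigma,
                                       spec$corr_len, spec$seed)
  } else {
    z <- hf(E, N)
  }
  pts <- cbind(E, N, z)
  mesh <- if (spec$jitter > 0) {
    delaunay_triangulate(pts)
  } else {
    triangle_mesh(pts, grid_triangles(length(es), length(ns)),
                  validate = FALSE)
  }
  attr(mesh, "height_fn") <- if (spec$family == "noise_field") NULL else hf
  attr(mesh, "terrain_spec") <- spec
  mesh
}

height_function <- function(spec) {
  z0 <- spec$z0
  switch(spec$family,
         flat = function(E, N) rep(z0, length(E)),
         inclined = {
           m <- tan(spec$slope_deg * pi / 180)
           f <- spec$facing * pi / 180
           function(E, N) z0 - m * (E * sin(f) + N * cos(f))
         },
         sinusoid = {
           th <- spec$direction * pi / 180
           k <- 2 * pi / spec$wavelength
           amp <- spec$amplitude
           function(E, N) z0 + amp * sin(k * (E * cos(th) + N * sin(th)))
         },
         peak_trough = {
           a <- spec$a
           w <- spec$w
           function(E, N) {
             Ep <- E / w
             Np <- N / w
             z0 + a * Np * exp(-(Ep^2 + Np^2))
           }
         },
         noise_field = NULL)
}

# two triangles per grid cell, consistent lower-left/upper-right diagonal
grid_triangles <- function(ncol_E, nrow_N) {
  i <- rep(seq_len(ncol_E - 1L), nrow_N - 1L)
  j <- rep(seq_len(nrow_N - 1L), each = ncol_E - 1L)
  ll <- (j - 1L) * ncol_E + i
  lr <- ll + 1L
  ul <- ll + ncol_E
  ur <- ul + 1L
  rbind(cbind(ll, lr, ur), cbind(ll, ur, ul))
}

# correlated Gaussian heights on a grid: white noise smoothed by a
# separable Gaussian kernel (circular convolution), rescaled to sd sigma
noise_field_heights <- function(nE, nN, res, sigma, corr_len, seed) {
  z <- with_seed(seed, matrix(stats::rnorm(nE * nN), nE, nN))
  if (corr_len > 0) {
    half <- max(1L, ceiling(3 * corr_len / res))
    k <- exp(-0.5 * (seq(-half, half) * res / corr_len)^2)
    k <- k / sum(k)
    pad_conv <- function(mat, kern) {
      h <- (length(kern) - 1L) / 2L
      n <- nrow(mat)
      idx <- ((seq_len(n + 2L * h) - 1L - h) %% n) + 1L
      out <- apply(mat[idx, , drop = FALSE], 2L,
                   function(col) stats::filter(col, kern, sides = 2L))
      out[h + seq_len(n), , drop = FALSE]
    }
    z <- pad_conv(z, k)
    z <- t(pad_conv(t(z), k))
  }
  as.vector(z) / stats::sd(as.vector(z)) * sigma
}

#' Add Gaussian vertical noise to mesh vertices
#'
#' Perturbs the vertical coordinate of every vertex by independent
#' zero-mean Gaussian noise, emulating reconstruction noise from stereo
#' feature-location and calibration uncertainty. `sigma = 0` returns the
#' mesh unchanged; the same seed always gives the same mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param sigma noise standard deviation (m), >= 0.
#' @param seed integer seed.
#' @return the perturbed mesh (connectivity unchanged).
#' @export
add_vertex_noise <- function(mesh, sigma, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), sigma >= 0)
  if (sigma == 0) return(mesh)
  n <- nrow(mesh$vertices)
  mesh$vertices[, 3L] <- mesh$vertices[, 3L] +
    with_seed(seed, stats::rnorm(n, sd = sigma))
  mesh
}

# evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
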