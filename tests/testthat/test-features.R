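test_that("window extraction keeps exactly the fully contained triangles", {
  m <- rough_delaunay_mesh(n = 100, seed = 13)
  all_in <- extract_window(m, window_spec(c(1, 1), width = 10))
  expect_identical(sort(all_in$tri_ids), seq_len(nrow(m$triangles)))

  # a window strictly inside one big triangle contains no whole triangle
  big <- triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                             c(10, 10, 1)),
                       rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  expect_identical(nrow(extract_window(big,
                                       window_spec(c(2, 2), 1))$triangles),
                   0L)

  # 4x4 grid, 1.5-spacing window: equals the brute-force membership test
  gg <- expand.grid(E = seq(-1.5, 1.5, by = 1), N = seq(-1.5, 1.5, by = 1))
  g <- delaunay_triangulate(cbind(gg$E, gg$N, 0))
  spec <- window_spec(c(0, 0), width = 1.5)
  sub <- extract_window(g, spec)
  vin <- abs(g$vertices[, 1]) <= 0.75 & abs(g$vertices[, 2]) <= 0.75
  brute <- which(vin[g$triangles[, 1]] & vin[g$triangles[, 2]] &
                   vin[g$triangles[, 3]])
  expect_identical(sub$tri_ids, brute)
  expect_identical(sort(sub$vertex_ids),
                   sort(unique(as.vector(g$triangles[brute, ]))))
})

test_that("indexed extraction equals the exhaustive scan", {
  m <- add_vertex_noise(
    generate_terrain(terrain_spec("sinusoid", extent = c(4, 4),
                                  resolution = 0.1)),
    sigma = 0.02, seed = 2)
  idx <- mesh_index(m)
  set.seed(19)
  for (i in 1:8) {
    spec <- window_spec(runif(2, -2, 2), width = runif(1, 0.3, 1.5),
                        length = runif(1, 0.3, 1.5),
                        orientation = runif(1, 0, 360))
    a <- extract_window(m, spec)
    b <- extract_window(m, spec, index = idx)
    expect_identical(sort(a$tri_ids), sort(b$tri_ids))
  }
})

test_that("surface area sums member triangle areas", {
  flat <- generate_terrain(terrain_spec("flat", extent = c(2, 2),
                                        resolution = 0.1))
  win <- extract_window(flat, window_spec(c(0, 0), 1))
  expect_equal(surface_area(win, flat), 1, tolerance = 1e-12)

  empty <- extract_window(flat, window_spec(c(50, 50), 0.5))
  expect_identical(surface_area(empty, flat), 0)

  # 45 degree sawtooth over a unit window has area sqrt(2)
  E <- seq(0, 1, by = 0.25)
  z <- c(0, 0.25, 0, 0.25, 0)
  pts <- rbind(cbind(E, 0, z), cbind(E, 0.5, z), cbind(E, 1, z))
  saw <- delaunay_triangulate(pts)
  wall <- extract_window(saw, window_spec(c(0.5, 0.5), 1))
  expect_equal(surface_area(wall, saw), sqrt(2), tolerance = 1e-9)
})

test_that("PCA plane fitting recovers planar and noisy-planar normals", {
  set.seed(23)
  xy <- cbind(runif(200, -1, 1), runif(200, -1, 1))
  flat <- fit_pca_plane(cbind(xy, 2))
  expect_equal(flat$normal, c(0, 0, 1), tolerance = 1e-9)

  tilt <- fit_pca_plane(cbind(xy, xy[, 1]))        # plane z = E
  expect_equal(tilt$normal, c(-1, 0, 1) / sqrt(2), tolerance = 1e-9)

  # orthonormal basis ordered by descending eigenvalue
  b <- tilt$basis
  expect_equal(crossprod(b), diag(3), tolerance = 1e-9)
  expect_true(all(diff(tilt$eigenvalues) <= 1e-12))

  noisy <- cbind(xy, xy[, 1] + rnorm(200, 0, 0.01))
  fit <- fit_pca_plane(noisy)
  ang <- acos(abs(sum(fit$normal * c(-1, 0, 1) / sqrt(2)))) * 180 / pi
  expect_lt(ang, 1)

  expect_error(fit_pca_plane(cbind(1:5, 1:5, 1:5)), "collinear")
  expect_warning(v <- fit_pca_plane(cbind(runif(50), 0, runif(50))),
                 "vertical")
  expect_equal(v$normal, c(0, 1, 0), tolerance = 1e-9)
})

test_that("projected area foreshortens by the cosine of the tilt", {
  flat <- generate_terrain(terrain_spec("flat", extent = c(2, 2),
                                        resolution = 0.1))
  win <- extract_window(flat, window_spec(c(0, 0), 1))
  expect_equal(projected_area(win, flat, c(0, 0, 1)),
               surface_area(win, flat), tolerance = 1e-12)

  wallm <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 1),
                               c(2, 2, 0)),
                         rbind(c(1L, 2L, 3L), c(1L, 2L, 4L)))
  vert_only <- structure(list(spec = window_spec(c(0.5, 0), 3),
                              tri_ids = 1L,
                              triangles = rbind(c(1L, 2L, 3L)),
                              vertex_ids = 1:3),
                         class = "window_subset")
  expect_equal(projected_area(vert_only, wallm, c(0, 0, 1)), 0,
               tolerance = 1e-12)

  m30 <- generate_terrain(terrain_spec("inclined", extent = c(4, 4),
                                       resolution = 0.1, slope_deg = 30))
  w30 <- extract_window(m30, window_spec(c(0, 0), 1))
  As <- surface_area(w30, m30)
  expect_equal(projected_area(w30, m30, c(0, 0, 1)), As * cos(pi / 6),
               tolerance = 1e-9)
  # projections never exceed the contoured area
  expect_lte(projected_area(w30, m30, c(0, 0, 1)), As)
  n_pca <- fit_pca_plane(m30$vertices[w30$vertex_ids, ])$normal
  expect_lte(projected_area(w30, m30, n_pca), As * (1 + 1e-12))
})

test_that("plane fitting decouples rugosity from slope on inclined planes", {
  for (alpha in c(0, 15, 30, 45, 60)) {
    m <- generate_terrain(terrain_spec("inclined", extent = c(3, 3),
                                       resolution = 0.05,
                                       slope_deg = alpha, facing = 90))
    rec <- rugosity(extract_window(m, window_spec(c(0, 0), 1)), m)
    expect_equal(rec$R_pca, 1, tolerance = 1e-6)
    expect_equal(rec$R_ne, 1 / cos(alpha * pi / 180), tolerance = 1e-6)
    expect_equal(rec$slope, alpha, tolerance = 0.01)
    if (alpha > 0) expect_equal(rec$aspect, 90, tolerance = 0.1)
  }
})

test_that("undefined windows return reasons instead of errors", {
  m <- rough_delaunay_mesh(n = 100, seed = 14)
  tiny <- rugosity(extract_window(m, window_spec(c(1, 1), 0.05)), m)
  expect_identical(tiny$reason, "too_few_triangles")
  expect_true(is.na(tiny$R_pca))

  flat <- generate_terrain(terrain_spec("flat", extent = c(2, 2),
                                        resolution = 0.1))
  rec <- rugosity(extract_window(flat, window_spec(c(0, 0), 1)), flat)
  expect_true(is.na(rec$aspect))       # undefined direction at zero slope
  expect_true(is.na(rec$reason))
})

test_that("slope and aspect match their closed forms", {
  expect_equal(slope(c(0, 0, 1)), 0)
  expect_equal(slope(c(1, 0, 1) / sqrt(2)), 45, tolerance = 1e-9)
  expect_equal(slope(c(0.6, 0, 0.8)), acos(0.8) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(slope(c(0.6, 0, 0.8)), 36.8699, tolerance = 1e-4)

  north <- aspect(c(0, 0.5, sqrt(0.75)))
  expect_equal(north$aspect, 0)
  expect_equal(north$northness, 1)
  expect_equal(north$eastness, 0)

  east <- aspect(c(0.5, 0, sqrt(0.75)))
  expect_equal(east$aspect, 90)

  sw <- aspect(c(-0.5, -0.5, 1 / sqrt(2)))
  expect_equal(sw$aspect, -135)
  expect_equal(sw$northness, -sqrt(2) / 2)
  expect_equal(sw$eastness, -sqrt(2) / 2)
  expect_equal(sw$northness^2 + sw$eastness^2, 1, tolerance = 1e-9)

  expect_true(is.na(aspect(c(0, 0, 1))$aspect))
})

test_that("multiscale features equal the single-window composition", {
  m <- add_vertex_noise(
    generate_terrain(terrain_spec("sinusoid", extent = c(3, 3),
                                  resolution = 0.1)),
    sigma = 0.01, seed = 5)
  ff <- multiscale_features(m, 1, centres = rbind(c(0.2, -0.3)))
  single <- rugosity(extract_window(m, window_spec(c(0.2, -0.3), 1)), m)
  expect_equal(ff[["1"]], single, tolerance = 1e-12)

  flat <- generate_terrain(terrain_spec("flat", extent = c(3, 3),
                                        resolution = 0.1))
  for (sz in c(0.5, 1)) {
    rec <- multiscale_features(flat, sz, centres = "grid",
                               stride = 1)[[as.character(sz)]]
    ok <- is.na(rec$reason)
    expect_true(all(abs(rec$R_pca[ok] - 1) < 1e-9))
    expect_true(all(abs(rec$R_ne[ok] - 1) < 1e-9))
    expect_true(all(rec$slope[ok] < 1e-6))
    expect_true(all(is.na(rec$aspect)))
  }
})

test_that("larger windows smooth the rugosity field", {
  m <- add_vertex_noise(
    generate_terrain(terrain_spec("sinusoid", extent = c(5, 2),
                                  resolution = 0.05, amplitude = 0.2,
                                  wavelength = 0.5)),
    sigma = 0.02, seed = 3)
  idx <- mesh_index(m, cellsize = 0.5)
  sizes <- c(0.5, 1, 1.5, 2)           # one to four wavelengths
  cen <- as.matrix(expand.grid(seq(-1.2, 1.2, by = 0.15),
                               seq(-0.4, 0.4, by = 0.2)))
  ff <- multiscale_features(m, sizes, centres = cen, index = idx)
  v <- vapply(ff, function(d) stats::var(d$R_ne, na.rm = TRUE), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("features are equivariant under rotation about the vertical", {
  m <- generate_terrain(terrain_spec("peak_trough", extent = c(6, 6),
                                     resolution = 0.05))
  base <- rugosity(extract_window(m, window_spec(c(0.31, -0.42), 1)), m)
  beta <- 35
  rot <- rotate_mesh(m, beta)
  th <- beta * pi / 180
  cen <- drop(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L) %*%
                c(0.31, -0.42))
  spun <- rugosity(extract_window(rot, window_spec(cen, 1,
                                                   orientation = beta)),
                   rot)
  expect_equal(spun$R_pca, base$R_pca, tolerance = 1e-9)
  expect_equal(spun$R_ne, base$R_ne, tolerance = 1e-9)
  expect_equal(spun$slope, base$slope, tolerance = 1e-9)
  expect_equal((base$aspect - spun$aspect) %% 360, beta %% 360,
               tolerance = 1e-6)
})

test_that("feature tables export to CSV and ESRI ASCII grids", {
  m <- generate_terrain(terrain_spec("peak_trough", extent = c(4, 4),
                                     resolution = 0.05))
  ff <- multiscale_features(m, 1, centres = "grid", stride = 0.5)[["1"]]
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ff, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$R_pca, ff$R_pca, tolerance = 1e-6)

  asc <- withr::local_tempfile(fileext = ".asc")
  write_feature_grid(ff, "R_ne", asc)
  hdr <- readLines(asc, n = 6)
  expect_match(hdr[1], "^ncols 9$")
  expect_match(hdr[2], "^nrows 9$")
  expect_match(hdr[6], "NODATA_value -9999")
  grid <- as.matrix(utils::read.table(asc, skip = 6))
  expect_identical(dim(grid), c(9L, 9L))
  # ESRI rows run north to south: top row is the northernmost centres
  north_row <- ff$R_ne[ff$centre_N == 2]
  expect_equal(unname(grid[1, ]), north_row, tolerance = 1e-6)
})
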