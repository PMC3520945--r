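test_that("the translation scheme produces the documented placement sets", {
  ps <- translate_placements(c(0, 0), c(2, 0))
  expect_identical(nrow(ps), 49L)                 # 1 + 4 radii x 12 angles

  for (combo in list(c(2, 5), c(1, 1), c(3, 8))) {
    p <- translate_placements(c(1, 1), c(3, 2),
                              radii = seq_len(combo[1]) / 10,
                              n_angles = combo[2])
    expect_identical(nrow(p), as.integer(1 + combo[1] * combo[2]))
  }

  # every placement keeps the original separation vector
  sep <- cbind(ps$eE - ps$sE, ps$eN - ps$sN)
  expect_true(all(abs(sep[, 1] - 2) < 1e-12))
  expect_true(all(abs(sep[, 2]) < 1e-12))
  # ordering is radius-major, angle-minor, original first
  expect_identical(ps$radius, c(0, rep(c(0.05, 0.1, 0.2, 0.4), each = 12)))
  expect_equal(ps$angle[2:13], seq(0, 330, by = 30))
  # the first translated placement points East from the original
  expect_equal(ps$sE[2], 0.05)
  expect_equal(ps$sN[2], 0)

  # degenerate radius 0 duplicates the original
  p0 <- translate_placements(c(0, 0), c(2, 0), radii = 0, n_angles = 4)
  expect_true(all(p0$sE == 0 & p0$eE == 2 & p0$sN == 0 & p0$eN == 0))
})

test_that("flat terrain yields a degenerate sensitivity summary of 1", {
  m <- generate_terrain(terrain_spec("flat", extent = c(4, 4),
                                     resolution = 0.1))
  # offsets that are grid multiples keep every chain along a vertex row
  ps <- translate_placements(c(-1, 0), c(1, 0), radii = c(0.1, 0.2),
                             n_angles = 4)
  s <- placement_sensitivity(m, ps, metric = "chain")
  expect_equal(s$mean, 1, tolerance = 1e-12)
  expect_equal(s$min, 1, tolerance = 1e-12)
  expect_equal(s$max, 1, tolerance = 1e-12)
  expect_identical(s$n_undefined, 0L)

  # off-row transects pick up only endpoint-jog terms bounded by
  # 2 * gamma / tape length
  s49 <- placement_sensitivity(m, translate_placements(c(-1, 0.013),
                                                       c(1, 0.013)),
                               metric = "chain")
  expect_gte(s49$min, 1)
  expect_lt(s49$max, 1 + 2 * 0.05 / 2)
})

test_that("a single placement gives mean = min = max = original", {
  m <- add_vertex_noise(
    generate_terrain(terrain_spec("flat", extent = c(3, 3),
                                  resolution = 0.05)),
    sigma = 0.02, seed = 4)
  one <- translate_placements(c(-1, 0.2), c(1, -0.1), radii = numeric(0),
                              n_angles = 1)
  expect_identical(nrow(one), 1L)
  s <- placement_sensitivity(m, one, metric = "chain")
  expect_equal(s$mean, s$original)
  expect_equal(s$min, s$max)
})

test_that("sensitivity summaries ignore placement order", {
  m <- add_vertex_noise(
    generate_terrain(terrain_spec("sinusoid", extent = c(4, 2),
                                  resolution = 0.05, wavelength = 0.8)),
    sigma = 0.01, seed = 6)
  ps <- translate_placements(c(-1, 0), c(1, 0), radii = c(0.1, 0.3),
                             n_angles = 6)
  s1 <- placement_sensitivity(m, ps, metric = "chain")
  shuf <- ps[c(1, sample(2:nrow(ps))), ]
  class(shuf) <- class(ps)
  s2 <- placement_sensitivity(m, shuf, metric = "chain")
  expect_equal(s2$mean, s1$mean)
  expect_equal(s2$min, s1$min)
  expect_equal(s2$max, s1$max)
  expect_true(s1$min <= s1$mean && s1$mean <= s1$max)
  expect_gte(s1$original, s1$min)
  expect_lte(s1$original, s1$max)
})

test_that("correlation reports match closed-form and sampled oracles", {
  set.seed(33)
  x <- rnorm(200)
  exact <- correlation_report(data.frame(x = x, y = 2 * x + 1),
                              fit = c("x", "y"))
  expect_equal(exact$r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(exact$fit$slope, 2, tolerance = 1e-12)
  expect_equal(exact$fit$intercept, 1, tolerance = 1e-12)
  expect_identical(diag(exact$r), c(x = 1, y = 1))
  expect_identical(exact$r, t(exact$r))

  rho <- 0.7
  z1 <- rnorm(10000)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(10000)
  samp <- correlation_report(data.frame(a = z1, b = z2))
  expect_equal(samp$r["a", "b"], rho, tolerance = 0.02)

  # zero-variance field gives an undefined entry, not an error
  degen <- correlation_report(data.frame(a = z1[1:50], c = rep(2, 50)))
  expect_true(is.na(degen$r["a", "c"]))

  # incomplete records are counted
  withna <- data.frame(a = c(z1[1:20], NA), b = c(z2[1:20], 1))
  expect_identical(correlation_report(withna)$n_dropped, 1L)
})

test_that("correlation ordering on peak-trough terrain matches the
           slope-decoupling mechanism", {
  m <- generate_terrain(terrain_spec("peak_trough", extent = c(6, 6),
                                     resolution = 0.02))
  ff <- multiscale_features(m, 1, centres = "grid", stride = 0.3)[["1"]]
  r <- correlation_report(ff[, c("slope", "R_pca", "R_ne")])$r
  expect_gt(r["slope", "R_ne"], r["R_pca", "R_ne"])
  expect_gt(r["R_pca", "R_ne"], r["slope", "R_pca"])
})

test_that("window rugosity is more robust to placement than the chain", {
  m <- generate_terrain(terrain_spec("noise_field", extent = c(4, 4),
                                     resolution = 0.025, sigma = 0.08,
                                     corr_len = 0.15, seed = 20))
  ps <- translate_placements(c(-0.75, 0), c(0.75, 0))
  idx <- mesh_index(m)
  ch <- placement_sensitivity(m, ps, metric = "chain")
  wi <- placement_sensitivity(m, ps, metric = "window", width = 1,
                              projection = "pca", index = idx)
  expect_lt(wi$spread, ch$spread)
})
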