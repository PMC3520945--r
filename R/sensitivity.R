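#' Systematic translations of a transect placement
#'
#' Emulates the placement-repeatability experiment: the original
#' start/end pair plus one pair per (radius, angle) combination, each
#' rigidly translated in the E-N plane by `r * (cos t, sin t)` so that every
#' placement keeps the original separation vector (orientation and length).
#' Angles start at 0 = East and advance counter-clockwise in
#' `360 / n_angles` increments; placements are ordered radius-major,
#' angle-minor, original first. The classic scheme of radii
#' 5, 10, 20, 40 cm at 12 angles gives 1 + 4 x 12 = 49 placements.
#'
#' @param v_s,v_e length-2 (E, N) original endpoints (a third coordinate is
#'   ignored; verticals are re-sampled from the mesh when evaluated).
#' @param radii positive translation radii (m).
#' @param n_angles number of equally spaced directions, >= 1.
#' @return an object of class `placement_set`: data frame with columns
#'   `radius`, `angle` (deg; `NA` for the original), `sE`, `sN`, `eE`, `eN`.
#' @export
translate_placements <- function(v_s, v_e, radii = c(0.05, 0.1, 0.2, 0.4),
                                 n_angles = 12L) {
  v_s <- as.numeric(v_s)[1:2]
  v_e <- as.numeric(v_e)[1:2]
  stopifnot(all(radii >= 0), n_angles >= 1L)
  ang <- (seq_len(n_angles) - 1L) * 360 / n_angles
  grid <- expand.grid(angle = ang, radius = radii)[, c("radius", "angle")]
  off <- cbind(grid$radius * cos(grid$angle * pi / 180),
               grid$radius * sin(grid$angle * pi / 180))
  df <- data.frame(radius = c(0, grid$radius), angle = c(NA, grid$angle),
                   sE = c(v_s[1L], v_s[1L] + off[, 1L]),
                   sN = c(v_s[2L], v_s[2L] + off[, 2L]),
                   eE = c(v_e[1L], v_e[1L] + off[, 1L]),
                   eN = c(v_e[2L], v_e[2L] + off[, 2L]))
  class(df) <- c("placement_set", "data.frame")
  df
}

#' Rugosity sensitivity to transect placement
#'
#' Evaluates a rugosity metric at every placement of a [placement_set]
#' and summarises its spread. For `metric = "chain"` the virtual chain-tape
#' pipeline is run per placement, with endpoint verticals re-looked-up from
#' the mesh at each translated location (a displaced chain lies on the
#' terrain). For `metric = "window"` an oriented rectangular window of the
#' given `width` is used, with length equal to the placement separation and
#' the long axis along it, run through the area-based pipeline.
#' Placements that yield an undefined value are dropped from the summary
#' and counted.
#'
#' @param mesh a [triangle_mesh()].
#' @param placements a [translate_placements()] result.
#' @param metric `"chain"` or `"window"`.
#' @param gamma chain selection threshold (m); `NULL` = half the median
#'   edge length.
#' @param width window width across the transect (m), for
#'   `metric = "window"`.
#' @param projection `"pca"` or `"horizontal"` rugosity for
#'   `metric = "window"`.
#' @param min_triangles minimum window member count, see [rugosity()].
#' @param index optional [mesh_index()] reused across placements.
#' @return an object of class `sensitivity_summary`: list with `mean`,
#'   `min`, `max`, `spread` (max - min), `original` (first placement's
#'   value), `values`, `n_placements`, `n_undefined`, `metric`.
#' @export
placement_sensitivity <- function(mesh, placements,
                                  metric = c("chain", "window"),
                                  gamma = NULL, width = 1,
                                  projection = c("pca", "horizontal"),
                                  min_triangles = 10L, index = NULL) {
  metric <- match.arg(metric)
  projection <- match.arg(projection)
  stopifnot(inherits(placements, "placement_set"))
  if (metric == "chain" && is.null(gamma))
    gamma <- 0.5 * edge_length_stats(mesh)$median
  if (metric == "window" && is.null(index))
    index <- mesh_index(mesh)
  vals <- vapply(seq_len(nrow(placements)), function(i) {
    s <- c(placements$sE[i], placements$sN[i])
    e <- c(placements$eE[i], placements$eN[i])
    if (metric == "chain") {
      tryCatch(
        suppressWarnings(chain_transect(mesh, s, e, gamma = gamma)$R_c),
        error = function(err) NA_real_)
    } else {
      d <- e - s
      spec <- window_spec((s + e) / 2, width = width,
                          length = sqrt(sum(d^2)),
                          orientation = atan2(d[2L], d[1L]) * 180 / pi)
      sub <- extract_window(mesh, spec, index = index)
      rec <- window_record(mesh, sub, min_triangles = min_triangles,
                           cross = index$cross)
      if (projection == "pca") rec$R_pca else rec$R_ne
    }
  }, numeric(1L))
  ok <- vals[!is.na(vals)]
  if (length(ok) == 0L)
    stop("all ", nrow(placements), " placements yielded undefined values")
  structure(list(mean = mean(ok), min = min(ok), max = max(ok),
                 spread = max(ok) - min(ok), original = vals[1L],
                 values = vals, n_placements = nrow(placements),
                 n_undefined = sum(is.na(vals)), metric = metric),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf(paste0("placement sensitivity (%s metric, %d placements",
                     ", %d undefined)\n"),
              x$metric, x$n_placements, x$n_undefined))
  cat(sprintf("  original %.4f | mean %.4f  min %.4f  max %.4f  spread %.4f\n",
              x$original, x$mean, x$min, x$max, x$spread))
  invisible(x)
}

#' Correlation matrix and least-squares fit over feature fields
#'
#' Pearson correlations between per-centre feature fields (typically slope,
#' PCA-plane rugosity and horizontal-plane rugosity), computed
#' pairwise-complete with the number of dropped incomplete records
#' reported, plus an ordinary least-squares fit (correlation, slope,
#' intercept) for one requested field pair.
#'
#' @param fields data frame (or matrix) of numeric per-centre fields;
#'   typically columns `slope`, `R_pca`, `R_ne` of a
#'   [multiscale_features()] element.
#' @param fit optional length-2 character vector `c(x, y)` naming the pair
#'   to regress (`y ~ x`).
#' @return an object of class `correlation_report`: list with `r` (the
#'   correlation matrix; entries against a zero-variance field are `NA`),
#'   `n` (records), `n_dropped` (incomplete records), and optionally `fit`
#'   = list(`x`, `y`, `r`, `slope`, `intercept`).
#' @examples
#' x <- rnorm(100); df <- data.frame(x = x, y = 2 * x + 1)
#' correlation_report(df, fit = c("x", "y"))
#' @export
correlation_report <- function(fields, fit = NULL) {
  m <- as.matrix(as.data.frame(fields))
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("need at least 3 records to correlate")
  n_dropped <- sum(!stats::complete.cases(m))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = "pearson"))
  out <- list(r = r, n = nrow(m), n_dropped = n_dropped)
  if (!is.null(fit)) {
    stopifnot(length(fit) == 2L, all(fit %in% colnames(m)))
    cc <- stats::complete.cases(m[, fit])
    x <- m[cc, fit[1L]]
    y <- m[cc, fit[2L]]
    co <- stats::coef(stats::lm(y ~ x))
    out$fit <- list(x = fit[1L], y = fit[2L],
                    r = suppressWarnings(stats::cor(x, y)),
                    slope = unname(co[2L]), intercept = unname(co[1L]))
  }
  class(out) <- "correlation_report"
  out
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("correlation report over", x$n, "records (", x$n_dropped,
      "incomplete )\n")
  print(round(x$r, digits))
  if (!is.null(x$fit))
    cat(sprintf("fit %s ~ %s: r = %.2f, m = %.2f, b = %.2f\n",
                x$fit$y, x$fit$x, x$fit$r, x$fit$slope, x$fit$intercept))
  invisible(x)
}
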