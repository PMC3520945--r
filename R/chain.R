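#' Vertical slicing plane through two transect endpoints
#'
#' The virtual chain is cut by the vertical plane containing the start
#' point, the end point and a third point directly above the start. The
#' returned plane therefore has a horizontal normal (zero vertical
#' component) and contains both endpoints.
#'
#' @param v_s,v_e length-3 start and end points (E, N, Z). They must be
#'   distinct in the E-N projection.
#' @return a [plane()] with horizontal unit normal.
#' @export
define_vertical_plane <- function(v_s, v_e) {
  v_s <- as.numeric(v_s)
  v_e <- as.numeric(v_e)
  d <- v_e[1:2] - v_s[1:2]
  if (sqrt(sum(d^2)) < 1e-12)
    stop("endpoints coincide in the E-N projection; no vertical plane defined")
  # (v_e - v_s) x up is horizontal and orthogonal to the transect
  n <- c(d[2L], -d[1L], 0)
  plane(n, -sum(n * v_s))
}

#' Select the mesh vertices that form a virtual chain
#'
#' Returns the vertices whose orthogonal distance to the slicing plane is at
#' most `gamma` and whose along-transect position (scalar projection onto
#' the horizontal start-to-end direction) lies between the endpoints.
#' `v_s` and `v_e` themselves are appended as virtual chain points unless a
#' selected mesh vertex coincides with them.
#'
#' @param mesh a [triangle_mesh()].
#' @param plane the vertical slicing plane from [define_vertical_plane()].
#' @param gamma selection threshold (m), > 0; typically half the median mesh
#'   edge length.
#' @param v_s,v_e transect endpoints (length-3).
#' @return matrix of candidate points (columns E, N, Z), unordered.
#' @export
select_chain_vertices <- function(mesh, plane, gamma, v_s, v_e) {
  stopifnot(inherits(mesh, "triangle_mesh"), gamma > 0)
  v_s <- as.numeric(v_s)
  v_e <- as.numeric(v_e)
  v <- mesh$vertices
  d <- point_plane_distance(v, plane)
  u <- v_e[1:2] - v_s[1:2]
  span <- sqrt(sum(u^2))
  u <- u / span
  t_along <- (v[, 1L] - v_s[1L]) * u[1L] + (v[, 2L] - v_s[2L]) * u[2L]
  sel <- d <= gamma & t_along >= 0 & t_along <= span
  if (!any(sel))
    stop("no mesh vertices within gamma = ", gamma,
         " m of the slicing plane between the endpoints")
  cand <- v[sel, , drop = FALSE]
  for (p in list(v_s, v_e)) {
    dd <- sqrt(rowSums(sweep(cand, 2L, p)^2))
    if (min(dd) > 1e-9) cand <- rbind(cand, p)
  }
  rownames(cand) <- NULL
  cand
}

#' Trace an ordered chain through candidate vertices
#'
#' Orders the candidate points from `v_s` to `v_e`. The default ordering is
#' by scalar projection onto the horizontal start-to-end direction, which is
#' a deterministic total order; ties are broken by vertical coordinate, then
#' by candidate order. The `"greedy"` ordering instead walks from `v_s` to
#' the nearest unvisited candidate until `v_e` is reached, mimicking
#' adjacency-linking on a Euclidean distance matrix; both orderings agree on
#' clean transects but the greedy walk can jump on noisy vertex ribbons.
#'
#' A warning is emitted when the largest along-transect gap between
#' consecutive chain points exceeds `10 * gamma`: the chain then bridges
#' unsampled terrain.
#'
#' @param candidates matrix of candidate points from
#'   [select_chain_vertices()].
#' @param v_s,v_e transect endpoints (length-3).
#' @param ordering `"projection"` (default) or `"greedy"`.
#' @param gamma the selection threshold used, for the gap warning; `NULL`
#'   disables the warning.
#' @return an object of class `tin_chain`: list with `points` (ordered
#'   matrix), `v_s`, `v_e`, `gamma`, `max_gap` (m).
#' @export
trace_chain <- function(candidates, v_s, v_e,
                        ordering = c("projection", "greedy"), gamma = NULL) {
  ordering <- match.arg(ordering)
  cand <- as.matrix(candidates)
  if (nrow(cand) < 2L) stop("need at least 2 candidate points to trace")
  v_s <- as.numeric(v_s)
  v_e <- as.numeric(v_e)
  u <- v_e[1:2] - v_s[1:2]
  u <- u / sqrt(sum(u^2))
  t_along <- (cand[, 1L] - v_s[1L]) * u[1L] + (cand[, 2L] - v_s[2L]) * u[2L]
  if (ordering == "projection") {
    ord <- order(t_along, cand[, 3L], seq_len(nrow(cand)))
  } else {
    ord <- integer(nrow(cand))
    left <- rep(TRUE, nrow(cand))
    cur <- which.min(sqrt(rowSums(sweep(cand, 2L, v_s)^2)))
    for (k in seq_len(nrow(cand))) {
      ord[k] <- cur
      left[cur] <- FALSE
      if (!any(left)) break
      d2 <- rowSums(sweep(cand, 2L, cand[cur, ])^2)
      d2[!left] <- Inf
      cur <- which.min(d2)
    }
  }
  pts <- cand[ord, , drop = FALSE]
  # drop coincident consecutive points
  dup <- c(FALSE, rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) < 1e-24)
  pts <- pts[!dup, , drop = FALSE]
  gaps <- diff(sort(t_along))
  max_gap <- if (length(gaps)) max(gaps) else 0
  if (!is.null(gamma) && max_gap > 10 * gamma)
    warning(sprintf(paste0("largest along-transect gap (%.3g m) exceeds ",
                           "10*gamma; the chain bridges unsampled terrain"),
                    max_gap))
  structure(list(points = pts, v_s = v_s, v_e = v_e, gamma = gamma,
                 max_gap = max_gap),
            class = "tin_chain")
}

#' @export
print.tin_chain <- function(x, ...) {
  cat("virtual chain:", nrow(x$points), "points, length",
      format(chain_length(x), digits = 6), "m, tape",
      format(sqrt(sum((x$v_e - x$v_s)^2)), digits = 6), "m\n")
  invisible(x)
}

chain_length <- function(chain) {
  p <- chain$points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Chain-tape rugosity of a traced chain
#'
#' The arc-chord ratio `R_c = L / D`: the summed 3D distance along
#' consecutive chain points divided by the straight-line 3D distance between
#' the endpoints. Flat terrain gives 1; rougher terrain gives larger values.
#' Segment lengths are full 3D distances between consecutive selected
#' vertices, matching the lay of a physical chain; the in-plane variant
#' (segments projected onto the slicing plane) is also reported for
#' comparison, the two differing by at most gamma-order terms.
#'
#' @param chain a `tin_chain` from [trace_chain()].
#' @return list with `R_c`, `L` (chain length, m), `D` (tape distance, m),
#'   `R_c_inplane`, and `n_vertices`.
#' @export
chain_rugosity <- function(chain) {
  stopifnot(inherits(chain, "tin_chain"))
  D <- sqrt(sum((chain$v_e - chain$v_s)^2))
  if (D < 1e-12) stop("zero tape distance between chain endpoints")
  L <- chain_length(chain)
  # in-plane variant: project points onto the slicing plane before summing
  pl <- define_vertical_plane(chain$v_s, chain$v_e)
  p <- chain$points
  s <- p[, 1L] * pl$normal[1L] + p[, 2L] * pl$normal[2L] + pl$offset
  proj <- p - outer(s, c(pl$normal[1:2], 0))
  Lp <- sum(sqrt(rowSums((proj[-1L, , drop = FALSE] -
                            proj[-nrow(proj), , drop = FALSE])^2)))
  list(R_c = L / D, L = L, D = D, R_c_inplane = Lp / D,
       n_vertices = nrow(chain$points))
}

#' Virtual chain-tape rugosity along a transect
#'
#' Convenience pipeline: defines the vertical slicing plane from two
#' transect endpoints given in the E-N plane (verticals looked up from the
#' nearest mesh vertex), selects the near-plane vertices, traces the chain
#' and computes the rugosity.
#'
#' @param mesh a [triangle_mesh()].
#' @param start,end length-2 (E, N) transect endpoints; length-3 inputs are
#'   accepted and their vertical used directly.
#' @param gamma selection threshold (m). Default `NULL` uses half the
#'   median mesh edge length, which keeps the vertex ribbon near-continuous
#'   without capturing parallel grid rows.
#' @param ordering chain ordering, see [trace_chain()].
#' @return list as [chain_rugosity()] plus `gamma`, `max_gap` and `chain`.
#' @examples
#' m <- generate_terrain(terrain_spec("flat", extent = c(2, 2),
#'                                    resolution = 0.25))
#' chain_transect(m, c(-0.75, 0), c(0.75, 0))$R_c   # 1
#' @export
chain_transect <- function(mesh, start, end, gamma = NULL,
                           ordering = c("projection", "greedy")) {
  ordering <- match.arg(ordering)
  if (is.null(gamma)) gamma <- 0.5 * edge_length_stats(mesh)$median
  v_s <- lookup_vertical(mesh, start)
  v_e <- lookup_vertical(mesh, end)
  pl <- define_vertical_plane(v_s, v_e)
  cand <- select_chain_vertices(mesh, pl, gamma, v_s, v_e)
  chain <- trace_chain(cand, v_s, v_e, ordering = ordering, gamma = gamma)
  c(chain_rugosity(chain),
    list(gamma = gamma, max_gap = chain$max_gap, chain = chain))
}

# complete an (E, N) location with the vertical of the nearest mesh vertex
lookup_vertical <- function(mesh, p) {
  p <- as.numeric(p)
  if (length(p) == 3L) return(p)
  if (length(p) != 2L) stop("transect endpoints must be length 2 or 3")
  v <- mesh$vertices
  i <- which.min((v[, 1L] - p[1L])^2 + (v[, 2L] - p[2L])^2)
  c(p, v[i, 3L])
}
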