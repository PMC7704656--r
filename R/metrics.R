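#' Regular rectangular partition of the unit square
#'
#' Cells are built from `N`-regular partitions of `[0, 1]` on each axis,
#' giving \eqn{P = (N-1)^2} axis-aligned rectangles. Cells are half-open
#' (`[x_i, x_{i+1})`) except along the upper and right boundary, so every
#' point of the domain belongs to exactly one cell.
#'
#' @param N number of partition points per axis (`N >= 2`).
#' @return a `domain_partition` list with `N`, `P` and `breaks`.
#' @export
domain_partition <- function(N = 11L) {
  if (N < 2) stop("'N' must be at least 2", call. = FALSE)
  structure(list(N = as.integer(N), P = (as.integer(N) - 1L)^2,
                 breaks = seq(0, 1, length.out = N)),
            class = "domain_partition")
}

# Cell index (1..P) of points, row-major over (ix, iy).
partition_cell <- function(partition, pts) {
  pts <- matrix(pts, ncol = 2L)
  k <- partition$N - 1L
  ix <- pmin(pmax(findInterval(pts[, 1L], partition$breaks,
                               rightmost.closed = TRUE), 1L), k)
  iy <- pmin(pmax(findInterval(pts[, 2L], partition$breaks,
                               rightmost.closed = TRUE), 1L), k)
  (iy - 1L) * k + ix
}

#' Local-weight compression metric
#'
#' Measures how well an extracted graph preserves, cell by cell, the mass of
#' the thresholded continuous solution:
#' \deqn{\hat w_q(G) = \frac1P \Big[\sum_\alpha \big|\sum_{e} I_\alpha(e)
#'   w_e - w_\alpha\big|^q\Big]^{1/q}}
#' where \eqn{w_\alpha} sums the tracked per-triangle weights (barycenters in
#' cell \eqn{C_\alpha}, \eqn{\mu^* \ge \delta}) and the indicator
#' \eqn{I_\alpha(e)} is 1, 1/2 or 0 when both, one or neither endpoint of
#' edge `e` lies in the cell. Zero means the compression relocates no mass.
#'
#' @param graph extracted graph with `x`, `y`, `weight` attributes.
#' @param solution a `dmk_continuous` or per-triangle weight vector.
#' @param mesh the mesh carrying the solution.
#' @param delta threshold defining the reference subgrid.
#' @param partition a [domain_partition()].
#' @param q exponent (`q >= 1`), default 2 (Euclidean).
#' @return a `metric_report` list: `w_hat`, `q`, `P` and a `per_cell` data
#'   frame with columns `cell`, `graph_weight`, `raw_weight`.
#' @export
local_weight_metric <- function(graph, solution, mesh, delta = 0.01,
                                partition = domain_partition(11L), q = 2) {
  if (q < 1) stop("'q' must be >= 1", call. = FALSE)
  mu <- if (inherits(solution, "dmk_continuous")) solution$mu else as.numeric(solution)
  P <- partition$P
  raw <- numeric(P)
  sel <- which(mu >= delta)
  if (length(sel)) {
    cells <- partition_cell(partition, mesh$barycenters[sel, , drop = FALSE])
    agg <- tapply(mu[sel], cells, sum)
    raw[as.integer(names(agg))] <- as.numeric(agg)
  }
  gside <- numeric(P)
  if (igraph::ecount(graph)) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    c1 <- partition_cell(partition, cbind(igraph::V(graph)$x[el[, 1]],
                                          igraph::V(graph)$y[el[, 1]]))
    c2 <- partition_cell(partition, cbind(igraph::V(graph)$x[el[, 2]],
                                          igraph::V(graph)$y[el[, 2]]))
    w <- igraph::E(graph)$weight
    same <- c1 == c2
    add <- function(cells, vals) {
      agg <- tapply(vals, cells, sum)
      gside[as.integer(names(agg))] <<- gside[as.integer(names(agg))] + as.numeric(agg)
    }
    if (any(same)) add(c1[same], w[same])
    if (any(!same)) { add(c1[!same], w[!same] / 2); add(c2[!same], w[!same] / 2) }
  }
  w_hat <- sum(abs(gside - raw)^q)^(1 / q) / P
  structure(list(w_hat = w_hat, q = q, P = P,
                 per_cell = data.frame(cell = seq_len(P), graph_weight = gside,
                                       raw_weight = raw)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: w_hat(q = %g) = %.6g over %d cells\n",
              x$q, x$w_hat, x$P))
  invisible(x)
}

#' Total network length
#'
#' \eqn{L(G) = \sum_e \ell_e} with unit lengths (edge count) or Euclidean
#' endpoint distances; small values indicate a parsimonious network.
#'
#' @param graph an igraph with `x`, `y` vertex attributes.
#' @param mode `"euclidean"` or `"unit"`.
#' @return the total length.
#' @export
total_length <- function(graph, mode = c("euclidean", "unit")) {
  mode <- match.arg(mode)
  if (!igraph::ecount(graph)) return(0)
  if (mode == "unit") return(igraph::ecount(graph))
  el <- igraph::as_edgelist(graph, names = FALSE)
  dx <- igraph::V(graph)$x[el[, 1]] - igraph::V(graph)$x[el[, 2]]
  dy <- igraph::V(graph)$y[el[, 1]] - igraph::V(graph)$y[el[, 2]]
  sum(sqrt(dx^2 + dy^2))
}

#' Junction-to-junction vein lengths
#'
#' Contracts every maximal chain of degree-2 nodes into a single vein whose
#' length is the sum of its segment lengths, and returns one length per
#' resulting junction-to-junction (or junction-to-leaf) vein. A connected
#' component that is a pure cycle of degree-2 nodes becomes one closed vein
#' of length equal to its perimeter. Used for vein-length distribution
#' analysis of venation-like networks.
#'
#' @param graph an igraph with a `length` edge attribute (Euclidean lengths).
#' @return numeric vector of vein lengths.
#' @export
edge_length_distribution <- function(graph) {
  m <- igraph::ecount(graph)
  if (!m) return(numeric(0))
  el <- igraph::as_edgelist(graph, names = FALSE)
  len <- igraph::E(graph)$length
  deg <- igraph::degree(graph)
  inc <- igraph::incident_edges(graph, igraph::V(graph))
  visited <- logical(m)
  veins <- numeric(0)

  walk <- function(eid, from) {
    # follow the chain starting with edge eid leaving junction `from`
    total <- 0
    node <- from
    repeat {
      visited[eid] <<- TRUE
      total <- total + len[eid]
      node <- if (el[eid, 1] == node) el[eid, 2] else el[eid, 1]
      if (deg[node] != 2L) break
      nxt <- as.integer(inc[[node]])
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break  # closed back onto a visited edge
      eid <- nxt[1L]
    }
    total
  }

  junctions <- which(deg != 2L)
  for (v in junctions) {
    for (eid in as.integer(inc[[v]])) {
      if (!visited[eid]) veins <- c(veins, walk(eid, v))
    }
  }
  # remaining unvisited edges form pure degree-2 cycles
  while (any(!visited)) {
    eid <- which(!visited)[1L]
    veins <- c(veins, walk(eid, el[eid, 1]))
  }
  veins
}

#' Fit an exponential law to a length distribution
#'
#' Builds a count histogram with `bins` equal-width bins over the data range
#' and fits \eqn{P(\ell) = P_0 e^{-\gamma \ell}} to (bin centre, count) pairs
#' by nonlinear least squares. Counts (not densities) are fitted, so
#' \eqn{P_0} scales with the sample size and binning, while the decay rate
#' \eqn{\gamma} is the physically meaningful parameter.
#'
#' @param lengths numeric vector of at least 10 lengths.
#' @param bins number of histogram bins, default 30.
#' @return list with `P0`, `gamma`, `residual` (sum of squared residuals),
#'   and the `histogram` data frame (`mid`, `count`).
#' @export
fit_exponential <- function(lengths, bins = 30L) {
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) < 10L)
    stop("need at least 10 lengths to fit a distribution", call. = FALSE)
  if (diff(range(lengths)) == 0)
    stop("degenerate lengths (all equal); cannot fit an exponential", call. = FALSE)
  breaks <- seq(min(lengths), max(lengths), length.out = bins + 1L)
  h <- graphics::hist(lengths, breaks = breaks, plot = FALSE)
  mid <- h$mids; count <- h$counts
  # log-linear start values from the non-empty bins
  pos <- count > 0
  start_fit <- stats::lm(log(count[pos]) ~ mid[pos])
  gamma0 <- max(-unname(stats::coef(start_fit)[2]), 1e-8)
  P00 <- exp(unname(stats::coef(start_fit)[1]))
  fit <- minpack.lm::nlsLM(count ~ P0 * exp(-gamma * mid),
                           start = list(P0 = P00, gamma = gamma0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  list(P0 = unname(est["P0"]), gamma = unname(est["gamma"]),
       residual = sum(stats::residuals(fit)^2),
       histogram = data.frame(mid = mid, count = count))
}
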