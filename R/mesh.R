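#' Structured triangulations of the unit square
#'
#' Builds a conforming triangulation of \eqn{\Omega = [0,1]^2}: the square is
#' divided into `ndiv` x `ndiv` cells, each cell is split into two triangles
#' along its lower-left to upper-right diagonal, and every triangle is then
#' uniformly subdivided into four congruent triangles `nref` times. The
#' triangle count is therefore `2 * ndiv^2 * 4^nref`. Midpoint quadrisection
#' of this structured mesh reproduces the structured mesh at twice the
#' division count, so refinement levels nest: the vertex set at level `nref`
#' is a subset of the one at `nref + 1`.
#'
#' @param ndiv positive integer, number of divisions along each axis.
#' @param nref non-negative integer, number of uniform refinement sweeps.
#' @return an object of class `tri_mesh`: a list with
#'   * `vertices`: n x 2 matrix of vertex coordinates,
#'   * `triangles`: m x 3 integer matrix of vertex indices (1-based),
#'   * `barycenters`: m x 2 matrix of triangle centroids,
#'   * `areas`: length-m vector of triangle areas (sums to 1),
#'   * `edge_adjacency`: list, triangles sharing a full edge with each triangle,
#'   * `node_adjacency`: list, triangles sharing at least one vertex.
#' @export
build_structured_mesh <- function(ndiv, nref = 0L) {
  if (length(ndiv) != 1L || !is.finite(ndiv) || ndiv < 1 || ndiv != round(ndiv))
    stop("'ndiv' must be a positive integer", call. = FALSE)
  if (length(nref) != 1L || !is.finite(nref) || nref < 0 || nref != round(nref))
    stop("'nref' must be a non-negative integer", call. = FALSE)
  n <- as.integer(ndiv) * 2L^as.integer(nref)

  xs <- seq(0, 1, length.out = n + 1L)
  vertices <- cbind(x = rep(xs, times = n + 1L), y = rep(xs, each = n + 1L))
  vid <- function(i, j) (j - 1L) * (n + 1L) + i  # i = column, j = row, 1-based

  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  v00 <- vid(ij$i,      ij$j)
  v10 <- vid(ij$i + 1L, ij$j)
  v01 <- vid(ij$i,      ij$j + 1L)
  v11 <- vid(ij$i + 1L, ij$j + 1L)
  # lower triangle (below the diagonal), then upper, interleaved per cell
  tri <- matrix(0L, nrow = 2L * n * n, ncol = 3L)
  tri[seq(1L, nrow(tri), by = 2L), ] <- cbind(v00, v10, v11)
  tri[seq(2L, nrow(tri), by = 2L), ] <- cbind(v00, v11, v01)

  mesh <- structure(list(vertices = vertices, triangles = tri), class = "tri_mesh")
  mesh$barycenters <- (vertices[tri[, 1L], , drop = FALSE] +
                       vertices[tri[, 2L], , drop = FALSE] +
                       vertices[tri[, 3L], , drop = FALSE]) / 3
  mesh$areas <- triangle_areas(vertices, tri)
  adj <- triangle_adjacency(tri)
  mesh$edge_adjacency <- adj$edge
  mesh$node_adjacency <- adj$node
  mesh$ndiv <- as.integer(ndiv)
  mesh$nref <- as.integer(nref)
  mesh
}

triangle_areas <- function(vertices, tri) {
  p1 <- vertices[tri[, 1L], , drop = FALSE]
  p2 <- vertices[tri[, 2L], , drop = FALSE]
  p3 <- vertices[tri[, 3L], , drop = FALSE]
  abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

# Edge- and node-based triangle adjacency from the connectivity table alone,
# so it holds for any conforming triangulation, not just the structured one.
triangle_adjacency <- function(tri) {
  m <- nrow(tri)
  # edges keyed by sorted vertex pair
  ea <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  key <- paste(pmin(ea[, 1L], ea[, 2L]), pmax(ea[, 1L], ea[, 2L]))
  owner <- rep(seq_len(m), times = 3L)
  by_edge <- split(owner, key)
  edge_adj <- vector("list", m)
  pair_idx <- by_edge[lengths(by_edge) == 2L]
  if (length(pair_idx)) {
    a <- vapply(pair_idx, `[`, integer(1L), 1L)
    b <- vapply(pair_idx, `[`, integer(1L), 2L)
    edge_adj <- split_accumulate(c(a, b), c(b, a), m)
  } else {
    edge_adj <- rep(list(integer(0L)), m)
  }
  # node adjacency via vertex -> triangle incidence
  vo <- rep(seq_len(m), times = 3L)
  by_vertex <- split(vo, as.vector(tri))
  node_adj <- rep(list(integer(0L)), m)
  pairs_from <- integer(0L); pairs_to <- integer(0L)
  for (tris in by_vertex) {
    if (length(tris) > 1L) {
      g <- expand.grid(a = tris, b = tris)
      g <- g[g$a != g$b, , drop = FALSE]
      pairs_from <- c(pairs_from, g$a)
      pairs_to <- c(pairs_to, g$b)
    }
  }
  node_adj <- split_accumulate(pairs_from, pairs_to, m, unique_values = TRUE)
  list(edge = edge_adj, node = node_adj)
}

split_accumulate <- function(from, to, m, unique_values = FALSE) {
  out <- rep(list(integer(0L)), m)
  if (length(from)) {
    sp <- split(to, factor(from, levels = seq_len(m)))
    out <- lapply(sp, function(v) {
      v <- as.integer(v)
      if (unique_values) v <- unique(v)
      sort(v)
    })
  }
  out
}

#' Write / read a mesh as a plain-text node/element file
#'
#' The format is a commented header, a vertex table (`v x y`) and a triangle
#' table (`t i j k`) with 0-based vertex indices, as documented in the header.
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# tri_mesh: vertex lines 'v x y', triangle lines 't i j k'",
               "# triangle vertex indices are 0-based"), con)
  writeLines(sprintf("v %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines(sprintf("t %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  vl <- ln[startsWith(ln, "v ")]
  tl <- ln[startsWith(ln, "t ")]
  vertices <- do.call(rbind, lapply(strsplit(vl, " +"), function(p) as.numeric(p[2:3])))
  colnames(vertices) <- c("x", "y")
  tri <- do.call(rbind, lapply(strsplit(tl, " +"), function(p) as.integer(p[2:4]) + 1L))
  mesh <- structure(list(vertices = vertices, triangles = tri), class = "tri_mesh")
  mesh$barycenters <- (vertices[tri[, 1L], , drop = FALSE] +
                       vertices[tri[, 2L], , drop = FALSE] +
                       vertices[tri[, 3L], , drop = FALSE]) / 3
  mesh$areas <- triangle_areas(vertices, tri)
  adj <- triangle_adjacency(tri)
  mesh$edge_adjacency <- adj$edge
  mesh$node_adjacency <- adj$node
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles (total area %.6f)\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}
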