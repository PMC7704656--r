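# Shared fixtures and small independent oracles.

# cache for expensive runs reused across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

cached_mesh <- function(ndiv, nref = 0L) {
  cached(sprintf("mesh_%d_%d", ndiv, nref), build_structured_mesh(ndiv, nref))
}

# lognormal random conductivity field on a mesh
random_field <- function(mesh, seed) {
  set.seed(seed)
  exp(stats::rnorm(nrow(mesh$triangles), sd = 2))
}

# A hand-built strip of three triangles A-B-C where B is edge-adjacent to
# both A and C, and A and C share only a vertex.
strip_mesh <- function() {
  vertices <- cbind(x = c(0, 1, 0.5, 1.5, 2), y = c(0, 0, 1, 1, 0))
  tri <- rbind(c(1L, 2L, 3L),   # A
               c(2L, 4L, 3L),   # B shares edge 2-3 with A
               c(2L, 5L, 4L))   # C shares edge 2-4 with B, vertex 2 with A
  mesh <- structure(list(vertices = vertices, triangles = tri), class = "tri_mesh")
  mesh$barycenters <- (vertices[tri[, 1], ] + vertices[tri[, 2], ] +
                       vertices[tri[, 3], ]) / 3
  mesh$areas <- routenet:::triangle_areas(vertices, tri)
  adj <- routenet:::triangle_adjacency(tri)
  mesh$edge_adjacency <- adj$edge
  mesh$node_adjacency <- adj$node
  mesh
}

# spatial igraph builder: nodes as list(name = c(x, y)), edges as matrix of
# name pairs with optional weights/lengths
spatial_graph <- function(coords, edges, weight = 1, length = NULL) {
  nm <- names(coords)
  xy <- do.call(rbind, coords)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = nm, x = xy[, 1], y = xy[, 2]))
  igraph::E(g)$weight <- rep_len(weight, nrow(edges))
  if (is.null(length)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    length <- sqrt((igraph::V(g)$x[el[, 1]] - igraph::V(g)$x[el[, 2]])^2 +
                   (igraph::V(g)$y[el[, 1]] - igraph::V(g)$y[el[, 2]])^2)
  }
  igraph::E(g)$length <- rep_len(length, nrow(edges))
  g
}

# uniformly random connected labeled graph on n nodes (spanning tree + extras)
random_connected_graph <- function(n, extra = 2L) {
  edges <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1)))
  all_pairs <- t(utils::combn(n, 2L))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  pool <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% key, , drop = FALSE]
  if (extra > 0L && nrow(pool))
    edges <- rbind(edges, pool[sample.int(nrow(pool), min(extra, nrow(pool))), ,
                               drop = FALSE])
  edges
}

# independent P1 stiffness assembly used as an oracle: basis gradients from a
# 3x3 linear solve per triangle rather than the closed-form cross products
oracle_stiffness <- function(mesh, mu) {
  nv <- nrow(mesh$vertices)
  K <- matrix(0, nv, nv)
  for (t in seq_len(nrow(mesh$triangles))) {
    vids <- mesh$triangles[t, ]
    P <- cbind(1, mesh$vertices[vids, , drop = FALSE])
    grads <- matrix(0, 3, 2)
    for (k in 1:3) {
      rhs <- c(0, 0, 0); rhs[k] <- 1
      coefs <- solve(P, rhs)        # affine hat function a + bx + cy
      grads[k, ] <- coefs[2:3]
    }
    K[vids, vids] <- K[vids, vids] +
      mu[t] * mesh$areas[t] * (grads %*% t(grads))
  }
  K
}

# two-rectangle continuous run shared by several tests
two_rect_run <- function(ndiv = 16, beta = 1.1, max_iter = 1500L, tol = 1e-4) {
  key <- sprintf("tworect_%d_%g_%d_%g", ndiv, beta, max_iter, tol)
  cached(key, {
    cfg <- generate_fixture("two-rectangles")
    mesh <- cached_mesh(ndiv)
    f <- evaluate_forcing(mesh, cfg$forcing)
    list(cfg = cfg, mesh = mesh, f = f,
         sol = run_continuous_dmk(mesh, f, beta = beta, max_iter = max_iter,
                                  tol = tol))
  })
}

# the venation case study: disk source / annular sink at full default scale,
# with the iteration cap raised so the continuous dynamics reaches equilibrium
disk_annulus_run <- function() {
  cached("disk_annulus_full", {
    cfg <- generate_fixture("disk-annulus")
    cfg$continuous$max_iter <- 12000L
    run_pipeline(cfg)
  })
}

expect_monotone_energy <- function(trace) {
  expect_true(all(diff(trace) <= 1e-8 * abs(trace[1])))
}
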