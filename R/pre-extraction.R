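#' Threshold a conductivity field
#'
#' Keeps the triangles carrying the relevant part of the solution,
#' \eqn{\{i : \mu^*(b_i) \ge \delta\}}. `delta = 0` selects the whole grid;
#' larger thresholds give nested, smaller selections.
#'
#' @param solution a `dmk_continuous`, or any per-triangle numeric vector.
#' @param delta non-negative threshold.
#' @return integer vector of selected triangle indices.
#' @export
select_triangles <- function(solution, delta) {
  if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
  mu <- if (inherits(solution, "dmk_continuous")) solution$mu else as.numeric(solution)
  sel <- which(mu >= delta)
  if (!length(sel))
    warning("threshold leaves no triangle selected; downstream graphs are empty",
            call. = FALSE)
  sel
}

#' Pre-extract a spatial graph from a thresholded field
#'
#' Converts the selected triangles into a weighted spatial graph. Node/edge
#' rules:
#' * `"I"` (edge-or-node sharing): one node per selected triangle at its
#'   barycenter; edge when the triangles share a grid edge or a grid vertex;
#' * `"II"` (edge-only sharing): as rule I but only full grid edges count,
#'   so every node has degree at most 3;
#' * `"III"` (original triangulation): nodes are the grid vertices of the
#'   selected triangles and edges their grid edges.
#'
#' Weight rules on an edge between triangles i, j with conductivities
#' \eqn{\mu_i, \mu_j}:
#' * `"AVG"`: \eqn{w_{ij} = (\mu_i + \mu_j)/2};
#' * `"ER"` (effective reweighing): \eqn{w_{ij} = \mu_i/d_i + \mu_j/d_j} with
#'   \eqn{d_i} the node degree in the extracted graph, which conserves the
#'   total density: \eqn{\sum_e w_e = \sum_{i: d_i > 0} \mu_i}.
#'
#' Rule III admits only AVG (a grid edge borders at most two triangles; its
#' weight is the mean conductivity over the adjacent selected triangles).
#'
#' @param mesh a `tri_mesh`.
#' @param solution a `dmk_continuous` or per-triangle scalar field to track.
#' @param delta selection threshold (see [select_triangles()]).
#' @param rule `"I"`, `"II"` or `"III"`.
#' @param weight_rule `"AVG"` or `"ER"`.
#' @param length_mode `"euclidean"` (default) or `"unit"` edge lengths.
#' @return an [igraph::igraph] with vertex attributes `name` (stable id:
#'   `"t<i>"` for triangle nodes, `"v<i>"` for grid-vertex nodes), `x`, `y`,
#'   `triangle` (originating triangle, rules I-II) and edge attributes
#'   `weight`, `length`.
#' @export
pre_extract <- function(mesh, solution, delta = 0.01,
                        rule = c("I", "II", "III"),
                        weight_rule = c("ER", "AVG"),
                        length_mode = c("euclidean", "unit")) {
  rule <- match.arg(rule)
  weight_rule <- match.arg(weight_rule)
  length_mode <- match.arg(length_mode)
  if (rule == "III" && weight_rule == "ER")
    stop("the ER rule does not apply to rule III; use AVG", call. = FALSE)
  mu <- if (inherits(solution, "dmk_continuous")) solution$mu else as.numeric(solution)
  sel <- select_triangles(mu, delta)

  if (rule %in% c("I", "II")) {
    adj <- if (rule == "I") mesh$node_adjacency else mesh$edge_adjacency
    in_sel <- logical(nrow(mesh$triangles)); in_sel[sel] <- TRUE
    from <- integer(0); to <- integer(0)
    for (i in sel) {
      nb <- adj[[i]]
      nb <- nb[nb > i & in_sel[nb]]
      if (length(nb)) { from <- c(from, rep.int(i, length(nb))); to <- c(to, nb) }
    }
    pos <- mesh$barycenters[sel, , drop = FALSE]
    d <- if (length(from)) data.frame(from = paste0("t", from), to = paste0("t", to))
         else data.frame(from = character(0), to = character(0))
    g <- igraph::graph_from_data_frame(
      d = d,
      directed = FALSE,
      vertices = data.frame(name = paste0("t", sel),
                            x = pos[, 1], y = pos[, 2], triangle = sel))
    mu_of <- stats::setNames(mu[sel], paste0("t", sel))
  } else {
    tri <- mesh$triangles[sel, , drop = FALSE]
    ek <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
    a <- pmin(ek[, 1L], ek[, 2L]); b <- pmax(ek[, 1L], ek[, 2L])
    owner_mu <- rep(mu[sel], times = 3L)
    key <- paste(a, b)
    w <- tapply(owner_mu, key, mean)     # 1 or 2 adjacent selected triangles
    first <- !duplicated(key)
    ea <- a[first]; eb <- b[first]
    w <- as.numeric(w[key[first]])
    vids <- sort(unique(c(ea, eb)))
    d <- if (length(ea)) data.frame(from = paste0("v", ea), to = paste0("v", eb))
         else data.frame(from = character(0), to = character(0))
    g <- igraph::graph_from_data_frame(
      d = d,
      directed = FALSE,
      vertices = data.frame(name = paste0("v", vids),
                            x = mesh$vertices[vids, 1],
                            y = mesh$vertices[vids, 2]))
    igraph::E(g)$weight <- w
  }

  if (rule %in% c("I", "II")) {
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el)) {
      if (weight_rule == "AVG") {
        igraph::E(g)$weight <- (mu_of[el[, 1]] + mu_of[el[, 2]]) / 2
      } else {
        deg <- igraph::degree(g)
        igraph::E(g)$weight <- mu_of[el[, 1]] / deg[el[, 1]] +
                               mu_of[el[, 2]] / deg[el[, 2]]
      }
    } else {
      igraph::E(g)$weight <- numeric(0)
    }
  }

  igraph::E(g)$length <- if (length_mode == "unit") {
    rep(1, igraph::ecount(g))
  } else {
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el)) {
      dx <- igraph::V(g)$x[el[, 1]] - igraph::V(g)$x[el[, 2]]
      dy <- igraph::V(g)$y[el[, 1]] - igraph::V(g)$y[el[, 2]]
      sqrt(dx^2 + dy^2)
    } else numeric(0)
  }
  g$rule <- rule
  g$weight_rule <- weight_rule
  g
}

#' Write / read an extracted graph as TSV tables
#'
#' `<prefix>_edges.tsv` has columns `u, v, weight, length` (node names);
#' `<prefix>_nodes.tsv` has `id, x, y`. [write_graphml()] wraps
#' [igraph::write_graph()] for GraphML output.
#'
#' @param graph an igraph with `x`, `y` vertex and `weight`, `length` edge
#'   attributes.
#' @param prefix path prefix for the two TSV files.
#' @export
write_graph_tsv <- function(graph, prefix) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  edges <- data.frame(u = el[, 1], v = el[, 2],
                      weight = igraph::E(graph)$weight,
                      length = igraph::E(graph)$length)
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- data.frame(id = igraph::V(graph)$name,
                      x = igraph::V(graph)$x, y = igraph::V(graph)$y)
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(prefix) {
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, colClasses = c("character", "character",
                                                           "numeric", "numeric"))
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE, colClasses = c("character", "numeric",
                                                           "numeric"))
  igraph::graph_from_data_frame(
    d = data.frame(from = edges$u, to = edges$v,
                   weight = edges$weight, length = edges$length),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, x = nodes$x, y = nodes$y))
}

#' @param path GraphML file path.
#' @rdname write_graph_tsv
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
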