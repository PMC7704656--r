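#' Nodes eligible as sources or sinks
#'
#' A graph node is eligible as a source (sink) when its position lies inside
#' the support of \eqn{f^+} (\eqn{f^-}) of the original routing problem.
#'
#' @param graph an extracted graph with `x`, `y` vertex attributes.
#' @param spec the [forcing_spec()] of the routing problem.
#' @return list with character vectors `sources` and `sinks` of node names.
#' @export
eligible_nodes <- function(graph, spec) {
  stopifnot(inherits(spec, "forcing_spec"))
  pts <- cbind(igraph::V(graph)$x, igraph::V(graph)$y)
  nm <- igraph::V(graph)$name
  in_src <- rep(FALSE, nrow(pts)); in_snk <- rep(FALSE, nrow(pts))
  for (region in spec$regions) {
    hit <- region_contains(region, pts)
    if (region$sign > 0) in_src <- in_src | hit else in_snk <- in_snk | hit
  }
  if (!any(in_src) || !any(in_snk))
    stop("no eligible source or no eligible sink node in the graph", call. = FALSE)
  list(sources = nm[in_src], sinks = nm[in_snk])
}

hull_vertices <- function(names, x, y) {
  if (length(names) <= 2L) return(names)
  h <- unique(grDevices::chull(x, y))
  px <- x[h]; py <- y[h]
  k <- length(h)
  area <- 0.5 * abs(sum(px * py[c(2:k, 1)] - px[c(2:k, 1)] * py))
  if (k < 3L || area < 1e-14) {
    # collinear point set: the hull degenerates to a segment, keep its ends
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
    return(unique(names[ij]))
  }
  names[h]
}

#' Select representative terminals
#'
#' From the eligible nodes, keeps as terminals those that either (i) are a
#' vertex of the 2D convex hull of the eligible positions of their sign --
#' capturing the outer shape of the source/sink supports -- or (ii) have
#' normalized unweighted shortest-path betweenness centrality below `tau_bc`
#' on the whole pre-extracted graph -- capturing end-points (leaf-like nodes)
#' inside the supports. Nodes eligible for both signs are dropped with a
#' warning; if a criterion empties a side, all eligible nodes of that sign
#' are used as a fallback, with a warning.
#'
#' @param graph the pre-extracted graph.
#' @param eligible the output of [eligible_nodes()] (or a compatible list).
#' @param tau_bc betweenness threshold, default 0.1.
#' @return list with node-name vectors `sources` and `sinks`.
#' @export
select_terminals <- function(graph, eligible, tau_bc = 0.1) {
  if (!length(eligible$sources) || !length(eligible$sinks))
    stop("eligible source and sink sets must be non-empty", call. = FALSE)
  bc <- igraph::betweenness(graph, directed = FALSE, weights = NA, normalized = TRUE)
  names(bc) <- igraph::V(graph)$name
  pick <- function(elig) {
    idx <- match(elig, igraph::V(graph)$name)
    hull <- hull_vertices(elig, igraph::V(graph)$x[idx], igraph::V(graph)$y[idx])
    elig[elig %in% hull | bc[elig] < tau_bc]
  }
  s_plus <- pick(eligible$sources)
  s_minus <- pick(eligible$sinks)
  contested <- intersect(s_plus, s_minus)
  if (length(contested)) {
    warning(sprintf("%d node(s) eligible as both source and sink dropped from both sets",
                    length(contested)), call. = FALSE)
    s_plus <- setdiff(s_plus, contested)
    s_minus <- setdiff(s_minus, contested)
  }
  if (!length(s_plus)) {
    warning("terminal criteria left no source; falling back to all eligible sources",
            call. = FALSE)
    s_plus <- setdiff(eligible$sources, contested)
  }
  if (!length(s_minus)) {
    warning("terminal criteria left no sink; falling back to all eligible sinks",
            call. = FALSE)
    s_minus <- setdiff(eligible$sinks, contested)
  }
  list(sources = s_plus, sinks = s_minus)
}

#' Assign balanced per-component terminal fluxes
#'
#' Each connected component of the graph is treated as a closed system: in a
#' component containing at least one selected source and one selected sink,
#' every source node receives \eqn{f_i = +1/|S^+ \cap V(C_m)|} and every sink
#' \eqn{f_i = -1/|S^- \cap V(C_m)|}, so each active component carries unit
#' mass and \eqn{\sum_{i \in C_m} f_i = 0}. Components lacking a terminal of
#' either sign get all-zero flux and are flagged inactive.
#'
#' @param graph the pre-extracted graph.
#' @param sources,sinks node-name vectors (from [select_terminals()]).
#' @return a `terminal_set`: list with `sources`, `sinks`, `flux` (named
#'   per-node vector), `component` (named membership vector) and
#'   `active_components`.
#' @export
assign_fluxes <- function(graph, sources, sinks) {
  comp <- igraph::components(graph)
  nm <- igraph::V(graph)$name
  member <- stats::setNames(comp$membership, nm)
  flux <- stats::setNames(numeric(length(nm)), nm)
  active <- integer(0)
  for (cm in seq_len(comp$no)) {
    in_c <- nm[member == cm]
    sp <- intersect(sources, in_c)
    sm <- intersect(sinks, in_c)
    if (length(sp) && length(sm)) {
      flux[sp] <- 1 / length(sp)
      flux[sm] <- -1 / length(sm)
      active <- c(active, cm)
    }
  }
  structure(list(sources = sources, sinks = sinks, flux = flux,
                 component = member, active_components = active),
            class = "terminal_set")
}

#' @export
print.terminal_set <- function(x, ...) {
  cat(sprintf("terminal_set: %d sources, %d sinks, %d active component(s)\n",
              length(x$sources), length(x$sinks), length(x$active_components)))
  invisible(x)
}

#' Write a terminal report as TSV
#'
#' Columns: `id, x, y, role, flux, component`.
#'
#' @param terminals a `terminal_set`.
#' @param graph the graph the terminals were selected on.
#' @param path output TSV path.
#' @export
write_terminals <- function(terminals, graph, path) {
  nm <- igraph::V(graph)$name
  role <- ifelse(nm %in% terminals$sources, "source",
                 ifelse(nm %in% terminals$sinks, "sink", "none"))
  tab <- data.frame(id = nm, x = igraph::V(graph)$x, y = igraph::V(graph)$y,
                    role = role, flux = terminals$flux[nm],
                    component = terminals$component[nm])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_terminals
#' @export
read_terminals <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "integer"))
  structure(list(sources = tab$id[tab$role == "source"],
                 sinks = tab$id[tab$role == "sink"],
                 flux = stats::setNames(tab$flux, tab$id),
                 component = stats::setNames(tab$component, tab$id),
                 active_components = sort(unique(tab$component[tab$flux != 0]))),
            class = "terminal_set")
}
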