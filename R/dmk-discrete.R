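#' Build a discrete routing problem on a graph
#'
#' Assembles the signed incidence matrix, edge lengths, initial edge
#' conductivities and per-node forcing for the discrete Monge-Kantorovich
#' (Physarum / basis-pursuit) dynamics. Edge orientation is arbitrary but
#' fixed (the endpoint with the lower vertex index is the tail); every
#' reported quantity is orientation-independent except the sign of the flux.
#' By default the initial conductivity of an edge is its pre-extraction
#' weight, \eqn{\mu_e(0) = w(e)}.
#'
#' @param graph an igraph with `weight` and `length` edge attributes.
#' @param flux per-node forcing: either a `terminal_set` or a named numeric
#'   vector summing to zero on every connected component.
#' @param beta_d routing exponent of the filter dynamics, `>= 1` (values
#'   below 1 spread flow instead of removing edges and do not act as a
#'   filter).
#' @param mu0_edges optional per-edge initial conductivity (> 0); defaults to
#'   the edge weights.
#' @param lengths optional per-edge lengths (> 0); defaults to the `length`
#'   edge attribute.
#' @return a `discrete_problem` list.
#' @export
discrete_problem <- function(graph, flux, beta_d = 1.1, mu0_edges = NULL,
                             lengths = NULL) {
  if (beta_d < 1)
    stop("beta_d < 1 does not act as a filter and is not supported", call. = FALSE)
  if (inherits(flux, "terminal_set")) flux <- flux$flux
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  f <- stats::setNames(numeric(length(nm)), nm)
  f[names(flux)] <- flux

  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el); n <- length(nm)
  tail <- pmin(el[, 1], el[, 2]); head <- pmax(el[, 1], el[, 2])
  B <- Matrix::sparseMatrix(i = c(tail, head), j = rep(seq_len(m), 2L),
                            x = rep(c(1, -1), each = m), dims = c(n, m))
  if (is.null(lengths)) lengths <- igraph::E(graph)$length
  if (is.null(lengths) || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("edge lengths must be positive and finite", call. = FALSE)
  if (is.null(mu0_edges)) mu0_edges <- igraph::E(graph)$weight
  mu0_edges <- rep_len(as.numeric(mu0_edges), m)
  if (any(mu0_edges <= 0))
    stop("initial edge conductivities must be strictly positive", call. = FALSE)

  comp <- igraph::components(graph)$membership
  bal <- tapply(f, comp, sum)
  if (any(abs(bal) > 1e-9))
    stop("forcing is unbalanced on at least one connected component", call. = FALSE)
  structure(list(incidence = B, lengths = rep_len(as.numeric(lengths), m),
                 forcing = f, beta_d = beta_d, mu0 = mu0_edges,
                 node_names = nm, tail = tail, head = head,
                 component = comp,
                 active_components = sort(unique(comp[f != 0]))),
            class = "discrete_problem")
}

# Solve Kirchhoff's law B diag(mu/l) B^T u = f on the active components,
# grounding the lowest-index node of each.
solve_discrete_potential <- function(problem, mu) {
  B <- problem$incidence
  w <- mu / problem$lengths
  L <- B %*% Matrix::Diagonal(x = w) %*% Matrix::t(B)
  n <- length(problem$forcing)
  active_nodes <- which(problem$component %in% problem$active_components)
  ground <- vapply(problem$active_components,
                   function(cm) min(which(problem$component == cm)), integer(1))
  free <- setdiff(active_nodes, ground)
  u <- numeric(n)
  if (length(free))
    u[free] <- as.numeric(Matrix::solve(L[free, free, drop = FALSE],
                                        problem$forcing[free]))
  u
}

#' Discrete transport-cost functional
#'
#' \deqn{L_\beta(\mu) = \frac12 \sum_e \mu_e \Big(\frac{1}{\ell_e}\sum_j
#'   B_{ej} u_j\Big)^2 \ell_e + \frac12 \sum_e
#'   \frac{\mu_e^{P(\beta_d)}}{P(\beta_d)} \ell_e}
#' The first term is the energy dissipated during transport (operating cost),
#' the second the infrastructural cost; their percentage split summarizes the
#' routing regime of the filtered network.
#'
#' @param problem a [discrete_problem()].
#' @param mu per-edge conductivity (>= 0).
#' @param u per-node potential.
#' @return list with `total`, `operating`, `infrastructure`, `operating_pct`,
#'   `infrastructure_pct`.
#' @export
discrete_energy <- function(problem, mu, u) {
  P <- (2 - problem$beta_d) / problem$beta_d
  if (P == 0) stop("beta_d = 2 gives P = 0; the functional is undefined",
                   call. = FALSE)
  du <- u[problem$tail] - u[problem$head]
  operating <- 0.5 * sum(mu * (du / problem$lengths)^2 * problem$lengths)
  infrastructure <- 0.5 * sum(mu^P / P * problem$lengths)
  total <- operating + infrastructure
  list(total = total, operating = operating, infrastructure = infrastructure,
       operating_pct = if (total > 0) 100 * operating / total else 0,
       infrastructure_pct = if (total > 0) 100 * infrastructure / total else 0)
}

#' Run the discrete Monge-Kantorovich filter dynamics
#'
#' Iterates the Physarum-type edge dynamics
#' \deqn{\mu_e' = \Big(\frac{\mu_e}{\ell_e}\big|\textstyle\sum_j B_{ej}
#'   u_j\big|\Big)^{\beta_d} - \mu_e}
#' with the potential `u` obtained from Kirchhoff's law at every step, by
#' explicit relaxation with an energy-guarded adaptive time step. For
#' \eqn{\beta_d = 1} the equilibrium is the global minimizer of the convex
#' transport cost and solves the corresponding basis-pursuit /
#' minimum-cost-flow problem; for \eqn{\beta_d > 1} it concentrates on
#' tree-like subgraphs. Components without terminals are left untouched by
#' the dynamics and reported.
#'
#' @param problem a [discrete_problem()].
#' @param dt initial time step.
#' @param tol convergence tolerance on the relative rate of change of mu.
#' @param max_iter iteration cap.
#' @param mu_floor positive floor applied during iteration for solvability.
#' @param max_halvings energy-guarded halvings of `dt` allowed.
#' @return a `dmk_discrete` object: `mu_star`, `u_star`, `flux` (signed,
#'   tail-to-head), `energy_trace`, `energy_split`, `kirchhoff_residual`
#'   (max over accepted iterates), `iterations`, `converged`,
#'   `active_edges` (logical), `node_names`.
#' @export
run_discrete_dmk <- function(problem, dt = 0.1, tol = 1e-4, max_iter = 2000L,
                             mu_floor = 1e-12, max_halvings = 10L) {
  stopifnot(inherits(problem, "discrete_problem"))
  active_e <- problem$component[problem$tail] %in% problem$active_components
  mu <- problem$mu0
  ell <- problem$lengths
  beta <- problem$beta_d
  u <- solve_discrete_potential(problem, mu)
  en <- discrete_energy(problem, mu, u)
  energy_trace <- en$total
  max_resid <- kirchhoff_residual(problem, mu, u)
  halvings <- 0L; converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    du <- abs(u[problem$tail] - u[problem$head])
    repeat {
      upd <- (mu / ell * du)^beta - mu
      mu_new <- mu
      mu_new[active_e] <- pmax(mu[active_e] + dt * upd[active_e], mu_floor)
      if (any(!is.finite(mu_new)))
        stop(sprintf("numerical failure (non-finite mu) at iteration %d", iter),
             call. = FALSE)
      u_new <- solve_discrete_potential(problem, mu_new)
      en_new <- discrete_energy(problem, mu_new, u_new)
      if (en_new$total <= energy_trace[length(energy_trace)] +
            1e-12 * abs(energy_trace[1]) || halvings >= max_halvings) break
      dt <- dt / 2
      halvings <- halvings + 1L
    }
    rate <- max(abs(mu_new - mu) / (dt * pmax(mu, mu_floor)), 0)
    mu <- mu_new; u <- u_new
    energy_trace <- c(energy_trace, en_new$total)
    max_resid <- max(max_resid, kirchhoff_residual(problem, mu, u))
    if (rate < tol) { converged <- TRUE; break }
  }
  du <- u[problem$tail] - u[problem$head]
  flux <- mu / ell * du
  flux[!active_e] <- NA_real_
  en <- discrete_energy(problem, mu, u)
  structure(list(mu_star = mu, u_star = stats::setNames(u, problem$node_names),
                 flux = flux, energy_trace = energy_trace,
                 energy_split = en, kirchhoff_residual = max_resid,
                 iterations = iter, converged = converged,
                 active_edges = active_e, node_names = problem$node_names),
            class = "dmk_discrete")
}

# Max Kirchhoff residual ||B q - f||_inf over active nodes.
kirchhoff_residual <- function(problem, mu, u) {
  q <- mu / problem$lengths * (u[problem$tail] - u[problem$head])
  r <- as.numeric(problem$incidence %*% q) - problem$forcing
  act <- problem$component %in% problem$active_components
  if (!any(act)) return(0)
  max(abs(r[act]))
}

#' @export
print.dmk_discrete <- function(x, ...) {
  cat(sprintf(paste0("dmk_discrete: %d iterations (%s), kept-energy split ",
                     "%.1f%% operating / %.1f%% infrastructure\n"),
              x$iterations, if (x$converged) "converged" else "not converged",
              x$energy_split$operating_pct, x$energy_split$infrastructure_pct))
  invisible(x)
}

#' Prune filtered edges and reweight the surviving graph
#'
#' Discards the active edges whose equilibrium conductivity fell below
#' `delta_d` (optionally relative to the maximum \eqn{\mu^*}) together with
#' any node left isolated. Weight modes for survivors:
#' * `"BPW"`: use the filter equilibrium \eqn{\mu^*_e} as the new weight;
#' * `"IBP"`: keep the pre-extraction weight unchanged.
#'
#' Components that carried no terminals are passed through unfiltered when
#' `drop_inactive = FALSE`, and removed (the default) otherwise.
#'
#' @param result a `dmk_discrete` from [run_discrete_dmk()].
#' @param graph the graph the problem was built on.
#' @param delta_d pruning threshold on \eqn{\mu^*_e}, default `1e-3`.
#' @param mode `"BPW"` or `"IBP"`.
#' @param relative if `TRUE`, threshold `delta_d * max(mu_star)` instead of
#'   the absolute `delta_d`.
#' @param drop_inactive drop components that carried no terminals.
#' @return the filtered igraph (node and edge sets are subsets of the
#'   input's).
#' @export
prune_and_reweight <- function(result, graph, delta_d = 1e-3,
                               mode = c("BPW", "IBP"), relative = FALSE,
                               drop_inactive = TRUE) {
  mode <- match.arg(mode)
  thr <- if (relative) delta_d * max(result$mu_star[result$active_edges], 0) else delta_d
  keep <- (result$active_edges & result$mu_star >= thr) |
          (!result$active_edges & !drop_inactive)
  if (!any(keep))
    warning("all edges pruned; the filtered graph is empty", call. = FALSE)
  w <- igraph::E(graph)$weight
  if (mode == "BPW") w[result$active_edges] <- result$mu_star[result$active_edges]
  g <- graph
  igraph::E(g)$weight <- w
  igraph::subgraph_from_edges(g, which(keep), delete.vertices = TRUE)
}

#' One-call graph filter
#'
#' Convenience wrapper: builds the [discrete_problem()], runs
#' [run_discrete_dmk()] and prunes with [prune_and_reweight()].
#'
#' @inheritParams discrete_problem
#' @inheritParams prune_and_reweight
#' @param ... passed to [run_discrete_dmk()].
#' @return list with `graph` (filtered igraph) and `result` (`dmk_discrete`).
#' @export
filter_graph <- function(graph, flux, beta_d = 1.1, delta_d = 1e-3,
                         mode = c("BPW", "IBP"), mu0_edges = NULL,
                         drop_inactive = TRUE, ...) {
  mode <- match.arg(mode)
  problem <- discrete_problem(graph, flux, beta_d = beta_d, mu0_edges = mu0_edges)
  result <- run_discrete_dmk(problem, ...)
  list(graph = prune_and_reweight(result, graph, delta_d = delta_d, mode = mode,
                                  drop_inactive = drop_inactive),
       result = result)
}
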