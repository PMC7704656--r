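# P1 finite elements on triangles: u piecewise linear on vertices, mu and
# all derived quantities piecewise constant per triangle.

# Per-triangle gradients of the three P1 basis functions.
# Returns list(gx, gy): m x 3 matrices, column k = gradient of the hat
# function of local vertex k on that triangle.
p1_basis_gradients <- function(mesh) {
  tri <- mesh$triangles
  p1 <- mesh$vertices[tri[, 1L], , drop = FALSE]
  p2 <- mesh$vertices[tri[, 2L], , drop = FALSE]
  p3 <- mesh$vertices[tri[, 3L], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  gx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  gy <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  list(gx = gx, gy = gy)
}

# Sparse P1 stiffness matrix for -div(mu grad u), mu piecewise constant.
assemble_stiffness <- function(mesh, mu, basis = NULL) {
  if (is.null(basis)) basis <- p1_basis_gradients(mesh)
  tri <- mesh$triangles
  m <- nrow(tri); nv <- nrow(mesh$vertices)
  coef <- mu * mesh$areas
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  idx <- expand.grid(a = 1:3, b = 1:3)
  ii <- as.vector(tri[, idx$a])
  jj <- as.vector(tri[, idx$b])
  xx <- as.vector(vapply(seq_len(nrow(idx)), function(k) {
    a <- idx$a[k]; b <- idx$b[k]
    coef * (basis$gx[, a] * basis$gx[, b] + basis$gy[, a] * basis$gy[, b])
  }, numeric(m)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
}

# Load vector: f holds integrated mass per triangle; the piecewise-constant
# density f/area tested against a hat function puts one third on each vertex.
assemble_load <- function(mesh, f) {
  tri <- mesh$triangles
  b <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    inc <- tapply(f / 3, tri[, k], sum)
    b[as.integer(names(inc))] <- b[as.integer(names(inc))] + as.numeric(inc)
  }
  b
}

#' Solve the elliptic transport-potential equation
#'
#' Solves the piecewise-linear finite-element discretization of
#' \eqn{-\nabla\cdot(\mu\nabla u) = f} on the mesh with natural (no-flow)
#' boundary conditions. The pure-Neumann problem determines `u` only up to a
#' constant; the nullspace is removed by pinning one vertex during the solve
#' and shifting the result to zero mean.
#'
#' @param mesh a `tri_mesh`.
#' @param mu per-triangle conductivity, strictly positive.
#' @param f a [evaluate_forcing()] field (balanced, per-triangle masses).
#' @param basis optional precomputed [p1_basis_gradients()] (internal reuse).
#' @return per-vertex potential with zero mean.
#' @export
solve_potential <- function(mesh, mu, f, basis = NULL) {
  if (any(mu <= 0)) stop("conductivity must be strictly positive", call. = FALSE)
  if (abs(sum(f)) > 1e-9)
    stop("forcing is unbalanced: sum(f) != 0, the Neumann system is singular",
         call. = FALSE)
  A <- assemble_stiffness(mesh, mu, basis)
  b <- assemble_load(mesh, f)
  nv <- nrow(mesh$vertices)
  keep <- 2:nv  # pin vertex 1 at u = 0
  u <- numeric(nv)
  u[keep] <- as.numeric(Matrix::solve(A[keep, keep], b[keep]))
  u - mean(u)
}

# Per-triangle gradient of a vertex field.
triangle_gradient <- function(mesh, u, basis = NULL) {
  if (is.null(basis)) basis <- p1_basis_gradients(mesh)
  tri <- mesh$triangles
  uv <- cbind(u[tri[, 1L]], u[tri[, 2L]], u[tri[, 3L]])
  cbind(rowSums(uv * basis$gx), rowSums(uv * basis$gy))
}

#' Transport-cost (Lyapunov) functional of the continuous dynamics
#'
#' \deqn{L(\mu, u) = \frac12 \int_\Omega \mu |\nabla u|^2 dx +
#'   \int_\Omega \frac{\mu^{P(\beta)}}{P(\beta)} dx, \quad
#'   P(\beta) = (2-\beta)/\beta.}
#' The first term is the energy dissipated during transport, the second a
#' sub-additive cost of building the transport infrastructure. The dynamics
#' decreases this functional, and its minimizer is the equilibrium.
#'
#' @param mesh a `tri_mesh`.
#' @param mu per-triangle conductivity (>= 0).
#' @param u per-vertex potential.
#' @param beta routing exponent in `[1, 2)`.
#' @return the energy value.
#' @export
lyapunov_energy <- function(mesh, mu, u, beta) {
  P <- (2 - beta) / beta
  if (P == 0) stop("beta = 2 gives P(beta) = 0; the functional is undefined",
                   call. = FALSE)
  grad <- triangle_gradient(mesh, u)
  g2 <- grad[, 1]^2 + grad[, 2]^2
  sum(0.5 * mu * g2 * mesh$areas) + sum(mu^P / P * mesh$areas)
}

#' Run the continuous dynamical Monge-Kantorovich solver
#'
#' Iterates the Physarum-type conductivity dynamics
#' \deqn{\partial_t \mu = (\mu |\nabla u|)^\beta - \mu}
#' coupled with the elliptic balance equation solved by [solve_potential()],
#' by explicit relaxation with an energy-guarded adaptive time step: whenever
#' a step increases the transport-cost functional the step is retried with
#' half the time step (up to `max_halvings` times over the run).
#' At equilibrium the support of \eqn{\mu^*} traces the optimal routing
#' network: \eqn{\beta = 1} is shortest-path-like (with \eqn{|\nabla u^*| = 1}
#' on the support), \eqn{\beta > 1} consolidates flow into branched,
#' tree-like structures.
#'
#' @param mesh a `tri_mesh`.
#' @param f forcing field from [evaluate_forcing()].
#' @param mu0 per-triangle initial conductivity, strictly positive; scalar
#'   recycled. Default 1 everywhere.
#' @param beta routing exponent, `1 <= beta < 2`.
#' @param dt initial time step.
#' @param tol convergence tolerance on the relative rate of change of mu.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`.
#' @param delta_floor small positive floor keeping the stiffness matrix
#'   invertible while mu decays on abandoned triangles.
#' @param max_halvings number of energy-guarded halvings of `dt` allowed.
#' @return a `dmk_continuous` object: `mu`, `u`, `grad_norm` (per-triangle
#'   \eqn{|\nabla u|}), `flux_magnitude` (\eqn{\mu|\nabla u|}), `iterations`,
#'   `converged`, `energy_trace`, `dt_final`.
#' @export
run_continuous_dmk <- function(mesh, f, mu0 = 1, beta = 1.1, dt = 0.1,
                               tol = 1e-4, max_iter = 2000L,
                               delta_floor = 1e-10, max_halvings = 10L) {
  m <- nrow(mesh$triangles)
  mu <- rep_len(as.numeric(mu0), m)
  if (any(mu <= 0)) stop("mu0 must be strictly positive everywhere", call. = FALSE)
  if (beta < 1) stop("beta < 1 (congestion regime) is not supported", call. = FALSE)
  if (dt <= 0 || tol <= 0) stop("dt and tol must be positive", call. = FALSE)

  basis <- p1_basis_gradients(mesh)
  u <- solve_potential(mesh, mu, f, basis)
  energy <- lyapunov_energy(mesh, mu, u, beta)
  energy_trace <- energy
  halvings <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- triangle_gradient(mesh, u, basis)
    gn <- sqrt(grad[, 1]^2 + grad[, 2]^2)
    repeat {
      mu_new <- mu + dt * ((mu * gn)^beta - mu)
      if (any(!is.finite(mu_new)))
        stop(sprintf("numerical failure (non-finite mu) at iteration %d", iter),
             call. = FALSE)
      mu_new <- pmax(mu_new, delta_floor)
      u_new <- solve_potential(mesh, mu_new, f, basis)
      energy_new <- lyapunov_energy(mesh, mu_new, u_new, beta)
      if (energy_new <= energy + 1e-12 * abs(energy_trace[1]) ||
          halvings >= max_halvings) break
      dt <- dt / 2
      halvings <- halvings + 1L
    }
    rate <- max(abs(mu_new - mu) / (dt * pmax(mu, delta_floor)))
    mu <- mu_new; u <- u_new; energy <- energy_new
    energy_trace <- c(energy_trace, energy)
    if (rate < tol) { converged <- TRUE; break }
  }
  grad <- triangle_gradient(mesh, u, basis)
  gn <- sqrt(grad[, 1]^2 + grad[, 2]^2)
  structure(list(mu = mu, u = u, grad_norm = gn, flux_magnitude = mu * gn,
                 iterations = iter, converged = converged,
                 energy_trace = energy_trace, dt_final = dt, beta = beta,
                 delta_floor = delta_floor),
            class = "dmk_continuous")
}

#' @export
print.dmk_continuous <- function(x, ...) {
  cat(sprintf(paste0("dmk_continuous: beta = %.3g, %d iterations (%s), ",
                     "max mu* = %.4g, energy = %.6g\n"),
              x$beta, x$iterations,
              if (x$converged) "converged" else "not converged",
              max(x$mu), x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}

#' Finite-element flux across a vertex cut
#'
#' For a vertex set `S`, returns the discrete flux leaving `S`,
#' \eqn{\sum_{i \in S} (A(\mu) u)_i}. If `S` contains the support of all
#' sources and no sink, this equals the injected mass (+1) up to the linear
#' solver residual; it is the discrete analogue of integrating the normal
#' flux over a curve separating sources from sinks.
#'
#' @param mesh a `tri_mesh`.
#' @param mu per-triangle conductivity.
#' @param u per-vertex potential.
#' @param vertex_set integer or logical index of the vertices in `S`.
#' @return the signed flux out of `S`.
#' @export
cut_flux <- function(mesh, mu, u, vertex_set) {
  A <- assemble_stiffness(mesh, mu)
  sum((A %*% u)[vertex_set])
}

#' Dump a continuous solution as plain-text tables
#'
#' Writes `<prefix>_triangles.tsv` (triangle id, barycenter x, y, mu, |grad u|),
#' `<prefix>_vertices.tsv` (vertex id, x, y, u) and `<prefix>_energy.csv`
#' (iteration, energy).
#'
#' @param solution a `dmk_continuous`.
#' @param mesh the mesh it was computed on.
#' @param prefix output path prefix.
#' @export
write_solution <- function(solution, mesh, prefix) {
  tri_tab <- data.frame(triangle = seq_along(solution$mu) - 1L,
                        x = mesh$barycenters[, 1], y = mesh$barycenters[, 2],
                        mu = solution$mu, grad_norm = solution$grad_norm)
  utils::write.table(tri_tab, paste0(prefix, "_triangles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  v_tab <- data.frame(vertex = seq_along(solution$u) - 1L,
                      x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                      u = solution$u)
  utils::write.table(v_tab, paste0(prefix, "_vertices.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(solution$energy_trace) - 1L,
                              energy = solution$energy_trace),
                   paste0(prefix, "_energy.csv"), row.names = FALSE)
  invisible(prefix)
}
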