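single_edge_problem <- function(beta_d = 1, ell = 1, mu0 = 1) {
  g <- spatial_graph(list(a = c(0, 0), b = c(1, 0)), rbind(c("a", "b")),
                     weight = mu0, length = ell)
  discrete_problem(g, c(a = 1, b = -1), beta_d = beta_d)
}

triangle_problem <- function(lengths, beta_d = 1) {
  g <- spatial_graph(list(a = c(0, 0), b = c(1, 0), c = c(0.5, 1)),
                     rbind(c("a", "b"), c("a", "c"), c("c", "b")),
                     weight = 1, length = lengths)
  discrete_problem(g, c(a = 1, b = -1, c = 0), beta_d = beta_d)
}

test_that("a single edge is forced to unit conductivity for any parameters", {
  for (beta_d in c(1, 1.3, 1.8)) for (ell in c(0.5, 2)) for (mu0 in c(0.2, 5)) {
    res <- run_discrete_dmk(single_edge_problem(beta_d, ell, mu0),
                            tol = 1e-10, max_iter = 5000)
    expect_lt(abs(res$mu_star - 1), 1e-6)
    expect_lt(abs(abs(res$flux) - 1), 1e-6)
  }
})

test_that("the filter routes mass along the shortest path of a triangle", {
  # equal lengths: direct edge a-b wins
  res <- run_discrete_dmk(triangle_problem(c(1, 1, 1)), tol = 1e-9,
                          max_iter = 20000)
  expect_lt(abs(res$mu_star[1] - 1), 1e-4)
  expect_lt(max(res$mu_star[2:3]), 1e-6)
  # long direct edge: the two-hop path through c wins (2 < 3)
  res2 <- run_discrete_dmk(triangle_problem(c(3, 1, 1)), tol = 1e-9,
                           max_iter = 20000)
  expect_lt(abs(res2$mu_star[2] - 1), 1e-4)
  expect_lt(abs(res2$mu_star[3] - 1), 1e-4)
  expect_lt(res2$mu_star[1], 1e-6)
})

test_that("the energy split of the single-edge equilibrium is 50/50", {
  prob <- single_edge_problem(beta_d = 1, ell = 1, mu0 = 1)
  res <- run_discrete_dmk(prob, tol = 1e-12, max_iter = 5000)
  en <- discrete_energy(prob, res$mu_star, unname(res$u_star))
  expect_equal(en$operating, 0.5, tolerance = 1e-6)
  expect_equal(en$infrastructure, 0.5, tolerance = 1e-6)
  expect_equal(en$operating_pct, 50, tolerance = 1e-4)
  # zero conductivity zeroes both terms
  en0 <- discrete_energy(prob, 0, c(0, 0))
  expect_equal(en0$total, 0)
})

test_that("invalid filter inputs are rejected", {
  g <- spatial_graph(list(a = c(0, 0), b = c(1, 0)), rbind(c("a", "b")))
  expect_error(discrete_problem(g, c(a = 1, b = -1), beta_d = 0.9),
               "not act as a filter")
  expect_error(discrete_problem(g, c(a = 1, b = -0.5)), "unbalanced")
  prob <- single_edge_problem()
  prob$beta_d <- 2
  expect_error(discrete_energy(prob, 1, c(0, 0)), "undefined")
})

test_that("discrete energy traces decrease and Kirchhoff holds at every iterate", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    edges <- random_connected_graph(n, extra = 3L)
    coords <- lapply(seq_len(n), function(i) runif(2))
    names(coords) <- paste0("n", seq_len(n))
    g <- spatial_graph(coords, cbind(paste0("n", edges[, 1]),
                                     paste0("n", edges[, 2])),
                       weight = runif(nrow(edges), 0.5, 2),
                       length = runif(nrow(edges), 0.5, 2))
    fl <- setNames(numeric(n), paste0("n", seq_len(n)))
    fl[1] <- 1; fl[n] <- -1
    prob <- discrete_problem(g, fl, beta_d = sample(c(1, 1.2, 1.5), 1))
    res <- run_discrete_dmk(prob, max_iter = 800)
    expect_monotone_energy(res$energy_trace)
    expect_lt(res$kirchhoff_residual, 1e-8)
    expect_true(all(res$mu_star >= 0))
  }
})

test_that("pruning keeps only edges above the threshold, with both weight modes", {
  g <- spatial_graph(list(a = c(0, 0), b = c(1, 0), c = c(0.5, 1)),
                     rbind(c("a", "b"), c("a", "c"), c("c", "b")),
                     weight = c(2, 3, 4), length = 1)
  prob <- discrete_problem(g, c(a = 1, b = -1, c = 0), beta_d = 1)
  res <- run_discrete_dmk(prob, tol = 1e-9, max_iter = 20000)
  bpw <- prune_and_reweight(res, g, delta_d = 1e-3, mode = "BPW")
  expect_equal(igraph::ecount(bpw), 1L)
  expect_equal(igraph::E(bpw)$weight, res$mu_star[1], tolerance = 1e-9)
  ibp <- prune_and_reweight(res, g, delta_d = 1e-3, mode = "IBP")
  expect_equal(igraph::E(ibp)$weight, 2)  # pre-extraction weight kept exactly
  # the initial condition defaults to the pre-extraction weights
  expect_equal(prob$mu0, c(2, 3, 4))
  # manual threshold example
  res_fake <- res; res_fake$mu_star <- c(1.0, 1e-5, 1e-5)
  kept <- prune_and_reweight(res_fake, g, delta_d = 1e-3, mode = "BPW")
  expect_equal(igraph::ecount(kept), 1L)
})

test_that("a beta_d > 1 filter yields acyclic active components", {
  set.seed(33)
  for (rep in 1:3) {
    n <- 8
    edges <- random_connected_graph(n, extra = 5L)
    coords <- lapply(seq_len(n), function(i) runif(2))
    names(coords) <- paste0("n", seq_len(n))
    g <- spatial_graph(coords, cbind(paste0("n", edges[, 1]),
                                     paste0("n", edges[, 2])),
                       weight = runif(nrow(edges), 0.5, 2),
                       length = runif(nrow(edges), 0.5, 2))
    fl <- setNames(numeric(n), paste0("n", seq_len(n)))
    fl[1] <- 1; fl[n] <- -1
    res <- run_discrete_dmk(discrete_problem(g, fl, beta_d = 1.3),
                            tol = 1e-8, max_iter = 20000)
    flt <- prune_and_reweight(res, g, delta_d = 1e-3, mode = "BPW")
    comp <- igraph::components(flt)
    expect_lte(igraph::ecount(flt), igraph::vcount(flt) - comp$no + 0)
  }
})

test_that("inactive components pass through unfiltered or are dropped", {
  coords <- list(a = c(0, 0), b = c(1, 0), x = c(0, 1), y = c(1, 1))
  g <- spatial_graph(coords, rbind(c("a", "b"), c("x", "y")), weight = 0.5)
  prob <- discrete_problem(g, c(a = 1, b = -1, x = 0, y = 0), beta_d = 1)
  res <- run_discrete_dmk(prob, tol = 1e-8, max_iter = 2000)
  expect_equal(res$mu_star[!res$active_edges], 0.5)  # untouched by the dynamics
  dropped <- prune_and_reweight(res, g, delta_d = 1e-3, drop_inactive = TRUE)
  expect_false("x" %in% igraph::V(dropped)$name)
  kept <- prune_and_reweight(res, g, delta_d = 1e-3, drop_inactive = FALSE)
  expect_true(all(c("x", "y") %in% igraph::V(kept)$name))
  expect_equal(igraph::E(kept)$weight[igraph::ecount(kept)], 0.5)
})
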