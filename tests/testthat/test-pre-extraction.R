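test_that("triangle selection applies the threshold and nests", {
  expect_equal(select_triangles(c(0.5, 0.001, 0.2), 0.01), c(1L, 3L))
  mu <- random_field(cached_mesh(8), seed = 1)
  expect_equal(select_triangles(mu, 0), seq_along(mu))
  s1 <- select_triangles(mu, 1e-4)
  s2 <- select_triangles(mu, 1e-2)
  expect_true(all(s2 %in% s1))
  expect_warning(select_triangles(mu, max(mu) * 2), "no triangle")
})

test_that("node sharing and edge sharing differ exactly on vertex-touching pairs", {
  m <- cached_mesh(2)
  # find a pair sharing a vertex but not an edge
  pair <- NULL
  for (i in seq_along(m$node_adjacency)) {
    cand <- setdiff(m$node_adjacency[[i]], m$edge_adjacency[[i]])
    if (length(cand)) { pair <- c(i, cand[1]); break }
  }
  expect_false(is.null(pair))
  mu <- rep(1e-6, nrow(m$triangles)); mu[pair] <- 1
  gI <- pre_extract(m, mu, delta = 0.5, rule = "I", weight_rule = "AVG")
  gII <- pre_extract(m, mu, delta = 0.5, rule = "II", weight_rule = "AVG")
  expect_equal(igraph::ecount(gI), 1L)
  expect_equal(igraph::ecount(gII), 0L)
  expect_equal(igraph::vcount(gII), 2L)
})

test_that("a 3-triangle strip reproduces the hand-computed ER and AVG weights", {
  m <- strip_mesh()
  mu <- c(1, 2, 3)
  gER <- pre_extract(m, mu, delta = 0, rule = "II", weight_rule = "ER")
  expect_equal(sort(unname(igraph::degree(gER))), c(1, 1, 2))
  w <- setNames(igraph::E(gER)$weight,
                apply(igraph::as_edgelist(gER), 1, paste, collapse = "-"))
  expect_equal(unname(w[grepl("t1", names(w))]), 1 / 1 + 2 / 2)   # A-B
  expect_equal(unname(w[grepl("t3", names(w))]), 2 / 2 + 3 / 1)   # B-C
  expect_equal(sum(igraph::E(gER)$weight), sum(mu))

  gAVG <- pre_extract(m, mu, delta = 0, rule = "II", weight_rule = "AVG")
  expect_equal(sort(igraph::E(gAVG)$weight), c(1.5, 2.5))
})

test_that("effective reweighing conserves the selected density", {
  m <- cached_mesh(8)
  for (seed in 1:5) {
    mu <- random_field(m, seed)
    delta <- stats::quantile(mu, 0.3)
    for (rule in c("I", "II")) {
      g <- pre_extract(m, mu, delta = delta, rule = rule, weight_rule = "ER")
      nz <- igraph::V(g)$triangle[igraph::degree(g) > 0]
      expect_lt(abs(sum(igraph::E(g)$weight) - sum(mu[nz])), 1e-12)
    }
  }
})

test_that("rule II degrees never exceed three", {
  m <- cached_mesh(8)
  mu <- random_field(m, seed = 3)
  g <- pre_extract(m, mu, delta = stats::median(mu), rule = "II",
                   weight_rule = "AVG")
  expect_true(all(igraph::degree(g) <= 3))
})

test_that("rule II edges are a subset of rule I edges", {
  m <- cached_mesh(8)
  mu <- random_field(m, seed = 4)
  delta <- stats::median(mu)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  expect_true(all(key(pre_extract(m, mu, delta, "II", "AVG")) %in%
                  key(pre_extract(m, mu, delta, "I", "AVG"))))
})

test_that("edges only join triangles that neighbour under the chosen rule", {
  m <- cached_mesh(4)
  mu <- random_field(m, seed = 5)
  for (rule in c("I", "II")) {
    g <- pre_extract(m, mu, delta = stats::median(mu), rule = rule,
                     weight_rule = "AVG")
    adj <- if (rule == "I") m$node_adjacency else m$edge_adjacency
    el <- igraph::as_edgelist(g, names = FALSE)
    t1 <- igraph::V(g)$triangle[el[, 1]]
    t2 <- igraph::V(g)$triangle[el[, 2]]
    for (k in seq_len(nrow(el)))
      expect_true(t2[k] %in% adj[[t1[k]]])
  }
})

test_that("rule III uses the grid vertices with mean-mu edge weights", {
  m <- strip_mesh()
  mu <- c(1, 2, 3)
  g <- pre_extract(m, mu, delta = 0, rule = "III", weight_rule = "AVG")
  expect_equal(igraph::vcount(g), 5L)   # all grid vertices of the strip
  # shared edge between A (mu=1) and B (mu=2): vertices 2-3 -> mean 1.5
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  w <- setNames(igraph::E(g)$weight, key)
  expect_equal(unname(w["v2 v3"]), 1.5)
  # boundary edge of A only: vertices 1-2 -> its own mu
  expect_equal(unname(w["v1 v2"]), 1)
  expect_error(pre_extract(m, mu, delta = 0, rule = "III", weight_rule = "ER"),
               "does not apply")
})

test_that("threshold monotonicity holds for all three rules", {
  m <- cached_mesh(4)
  mu <- random_field(m, seed = 6)
  deltas <- stats::quantile(mu, c(0.2, 0.6))
  for (rule in c("I", "II", "III")) {
    wr <- if (rule == "III") "AVG" else "ER"
    g1 <- pre_extract(m, mu, deltas[1], rule, wr)
    g2 <- pre_extract(m, mu, deltas[2], rule, wr)
    expect_true(all(igraph::V(g2)$name %in% igraph::V(g1)$name))
    key <- function(g) {
      el <- igraph::as_edgelist(g)
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
    expect_true(all(key(g2) %in% key(g1)))
  }
})

test_that("graphs round-trip through TSV and GraphML", {
  m <- cached_mesh(4)
  g <- pre_extract(m, random_field(m, seed = 7), delta = 1, rule = "I",
                   weight_rule = "ER")
  dir <- withr::local_tempdir()
  write_graph_tsv(g, file.path(dir, "g"))
  g2 <- read_graph_tsv(file.path(dir, "g"))
  expect_equal(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sum(igraph::E(g2)$weight), sum(igraph::E(g)$weight),
               tolerance = 1e-12)
  write_graphml(g, file.path(dir, "g.graphml"))
  g3 <- read_graphml(file.path(dir, "g.graphml"))
  expect_equal(igraph::vcount(g3), igraph::vcount(g))
  expect_equal(igraph::ecount(g3), igraph::ecount(g))
})
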