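test_that("eligibility follows the region supports", {
  g <- spatial_graph(list(a = c(0.5, 0.5), b = c(0.52, 0.5), c = c(0.9, 0.9)),
                     rbind(c("a", "b"), c("b", "c")))
  spec <- forcing_spec(list(
    forcing_region("disk", sign = +1, cx = 0.5, cy = 0.5, r = 0.1),
    forcing_region("rectangle", sign = -1, xmin = 0.8, xmax = 1,
                   ymin = 0.8, ymax = 1)))
  elig <- eligible_nodes(g, spec)
  expect_setequal(elig$sources, c("a", "b"))
  expect_setequal(elig$sinks, "c")
  far <- forcing_spec(list(
    forcing_region("disk", sign = +1, cx = 0.1, cy = 0.1, r = 0.01),
    forcing_region("disk", sign = -1, cx = 0.9, cy = 0.1, r = 0.01)))
  expect_error(eligible_nodes(g, far), "no eligible")
})

test_that("path endpoints pass the centrality criterion, interior nodes fail", {
  coords <- lapply(1:5, function(i) c((i - 1) / 4, 0.5))
  names(coords) <- paste0("n", 1:5)
  # the sink lives in a separate far-away component so the eligible sets
  # stay disjoint
  coords$s1 <- c(3, 3); coords$s2 <- c(3.2, 3)
  g <- spatial_graph(coords, rbind(cbind(paste0("n", 1:4), paste0("n", 2:5)),
                                   c("s1", "s2")))
  # brute-force normalized betweenness: on the path component the interior
  # nodes carry 3/6, 4/6, 3/6 of the endpoint pairs within their component
  bc <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  expect_equal(unname(bc[c("n1", "n5")]), c(0, 0))
  expect_equal(unname(bc[c("n2", "n3", "n4")]), c(3, 4, 3) / 15)
  sel <- select_terminals(g, list(sources = paste0("n", 1:5),
                                  sinks = c("s1", "s2")),
                          tau_bc = 0.1)
  # collinear layout: the degenerate hull keeps only the two extremes, and
  # the centrality test admits no interior node
  expect_setequal(sel$sources, c("n1", "n5"))
})

test_that("star leaves are kept and a central hub is rejected", {
  coords <- list(hub = c(0.5, 0.5), l1 = c(0, 0), l2 = c(1, 0),
                 l3 = c(1, 1), l4 = c(0, 1), s1 = c(3, 3), s2 = c(3.2, 3))
  g <- spatial_graph(coords, rbind(cbind("hub", paste0("l", 1:4)),
                                   c("s1", "s2")))
  sel <- select_terminals(g, list(sources = c("hub", paste0("l", 1:4)),
                                  sinks = c("s1", "s2")),
                          tau_bc = 0.1)
  expect_setequal(sel$sources, paste0("l", 1:4))
})

test_that("nodes in convex position are all hull-selected", {
  coords <- list(a = c(0, 0), b = c(1, 0), c = c(1, 1), d = c(0, 1),
                 e = c(0.5, 0.5))
  g <- spatial_graph(coords, rbind(c("a", "e"), c("b", "e"), c("c", "e"),
                                   c("d", "e")))
  sel <- select_terminals(g, list(sources = c("a", "b", "c", "d"), sinks = "e"),
                          tau_bc = 1e-9)
  # every point of a convex-position set is a hull vertex
  expect_setequal(sel$sources, c("a", "b", "c", "d"))
})

test_that("eligible tree leaves are always selected", {
  set.seed(11)
  g0 <- igraph::sample_tree(20)
  igraph::V(g0)$name <- paste0("n", 1:20)
  set.seed(12)
  igraph::V(g0)$x <- runif(20); igraph::V(g0)$y <- runif(20)
  g0 <- igraph::add_vertices(g0, 2, name = c("s1", "s2"),
                             x = c(3, 3.2), y = c(3, 3))
  g0 <- igraph::add_edges(g0, c("s1", "s2"))
  leaves <- paste0("n", which(igraph::degree(g0)[1:20] == 1))
  sel <- select_terminals(g0, list(sources = paste0("n", 1:20),
                                   sinks = c("s1", "s2")), tau_bc = 1e-6)
  expect_true(all(leaves %in% sel$sources))
})

test_that("contested nodes are dropped from both terminal sets with a warning", {
  coords <- list(a = c(0.5, 0.5), b = c(0.1, 0.5), c = c(0.9, 0.5))
  g <- spatial_graph(coords, rbind(c("a", "b"), c("a", "c")))
  expect_warning(
    sel <- select_terminals(g, list(sources = c("a", "b"), sinks = c("a", "c")),
                            tau_bc = 0.5),
    "both source and sink")
  expect_false("a" %in% sel$sources)
  expect_false("a" %in% sel$sinks)
})

test_that("fluxes balance within every component and split uniformly", {
  coords <- list(s1 = c(0, 0), s2 = c(0, 1), t1 = c(1, 0.5),
                 s3 = c(2, 0), t3 = c(3, 0), iso = c(4, 0), iso2 = c(5, 0))
  g <- spatial_graph(coords, rbind(c("s1", "t1"), c("s2", "t1"),
                                   c("s3", "t3"), c("iso", "iso2")),
                     weight = 1)
  ts <- assign_fluxes(g, sources = c("s1", "s2", "s3"), sinks = c("t1", "t3"))
  expect_equal(unname(ts$flux[c("s1", "s2")]), c(0.5, 0.5))
  expect_equal(unname(ts$flux["t1"]), -1)
  expect_equal(unname(ts$flux[c("s3", "t3")]), c(1, -1))
  for (cm in unique(ts$component))
    expect_lt(abs(sum(ts$flux[ts$component == cm])), 1e-15)
  # the component with no terminals is inactive with zero flux
  expect_equal(unname(ts$flux["iso"]), 0)
  expect_false(ts$component[["iso"]] %in% ts$active_components)
})

test_that("terminal reports round-trip through TSV", {
  coords <- list(a = c(0, 0), b = c(1, 0), c = c(0.5, 1))
  g <- spatial_graph(coords, rbind(c("a", "b"), c("b", "c")))
  ts <- assign_fluxes(g, "a", "c")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_terminals(ts, g, path)
  ts2 <- read_terminals(path)
  expect_setequal(ts2$sources, ts$sources)
  expect_setequal(ts2$sinks, ts$sinks)
  expect_equal(ts2$flux[names(ts$flux)], ts$flux)
})
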