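test_that("read_network parses edge lists, collapsing duplicates and loops", {
  f <- tempfile()
  writeLines(c("# comment", "a\tb", "b\tc", "c\ta"), f)
  g <- read_network(f)
  expect_setequal(network_nodes(g), c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 3)

  writeLines(c("a\tb", "b\ta", "a\tb"), f)
  expect_warning(g2 <- read_network(f), "2 duplicate")
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(g2$n_duplicates, 2)

  writeLines(c("a\ta", "a\tb"), f)
  expect_warning(g3 <- read_network(f), "1 self-loop")
  expect_setequal(network_nodes(g3), c("a", "b"))
  expect_equal(igraph::ecount(g3), 1)

  # extra columns (e.g. interaction scores) are ignored
  writeLines(c("a\tb\t0.35", "b\tc\t-0.1\textra"), f)
  expect_equal(igraph::ecount(read_network(f)), 2)
})

test_that("read_network rejects malformed and empty input with distinct errors", {
  f <- tempfile()
  writeLines(c("a\tb", "lonely"), f)
  expect_error(read_network(f), "line 2")
  writeLines(c("# only a comment", "   "), f)
  expect_error(read_network(f), "empty")
})

test_that("read_network expands SIF multi-target rows", {
  f <- tempfile()
  writeLines(c("a gi b c d", "b gi c"), f)
  g <- read_network(f, format = "sif")
  expect_setequal(network_nodes(g), c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 4)
  writeLines("a gi", f)
  expect_error(read_network(f, format = "sif"), "line 1")
})

test_that("network round-trips through the canonical edge-list writer", {
  g <- fix_cycle(7)
  f <- tempfile()
  write_network(g, f)
  g2 <- read_network(f)
  expect_identical(network_edges(g2), network_edges(g))
})

test_that("largest_connected_component selects by size then smallest label", {
  tri <- fix_complete(3)
  expect_setequal(network_nodes(largest_connected_component(tri)),
                  network_nodes(tri))
  g <- gene_network(rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  expect_setequal(network_nodes(largest_connected_component(g)),
                  c("a", "b", "c"))
  ties <- gene_network(rbind(c("b", "c"), c("a", "d")))
  expect_setequal(network_nodes(largest_connected_component(ties)),
                  c("a", "d"))
  expect_error(largest_connected_component(gene_network(matrix(character(), ncol = 2))),
               "empty")
})

test_that("shortest_path_lengths gives BFS distances, omitting unreachable nodes", {
  p <- fix_path(c("a", "b", "c"))
  expect_equal(shortest_path_lengths(p, "a"), c(a = 0L, b = 1L, c = 2L))
  d <- shortest_path_lengths(fix_cycle(5), "c01")
  expect_equal(sort(unname(d)), c(0L, 1L, 1L, 2L, 2L))
  g <- gene_network(rbind(c("a", "b"), c("x", "y")))
  expect_named(shortest_path_lengths(g, "a"), c("a", "b"))
  expect_error(shortest_path_lengths(g, "zz"), "unknown")
})

test_that("clustering, path length and diameter match closed forms", {
  expect_equal(global_clustering_coefficient(fix_complete(4)), 1.0)
  expect_equal(global_clustering_coefficient(fix_star(3)), 0.0)
  # K4 plus one pendant: 3 triangles, 15 triples
  k4p <- gene_network(rbind(t(combn(sprintf("k%02d", 1:4), 2L)),
                            c("k01", "pend")))
  expect_equal(global_clustering_coefficient(k4p), 12 / 15)

  expect_equal(average_path_length(fix_path(c("a", "b", "c"))), 4 / 3)
  expect_equal(average_path_length(fix_cycle(5)), 1.5)
  expect_equal(network_diameter(fix_cycle(6)), 3L)
  expect_equal(network_diameter(fix_complete(5)), 1L)

  disc <- gene_network(rbind(c("a", "b"), c("x", "y")))
  expect_error(average_path_length(disc), "largest_connected_component")
  expect_error(network_diameter(disc), "largest_connected_component")
  expect_error(average_path_length(gene_network(matrix(character(), ncol = 2),
                                                nodes = "solo")), ">= 2")
})

test_that("distance-based descriptors agree with a Floyd-Warshall oracle", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(8:25, 1)
    em <- oracle_random_graph(n, 0.15)
    if (nrow(em) == 0) next
    g <- largest_connected_component(gene_network(em))
    A <- adjacency_of(g)
    D <- oracle_floyd_warshall(A)
    v <- sample(network_nodes(g), 1)
    expect_equal(shortest_path_lengths(g, v)[rownames(D)],
                 setNames(as.integer(D[v, ]), rownames(D)))
    if (nrow(A) >= 2) {
      expect_equal(average_path_length(g), mean(D[upper.tri(D)]),
                   tolerance = 1e-12)
      expect_equal(network_diameter(g), as.integer(max(D)))
    }
    expect_equal(global_clustering_coefficient(g), oracle_transitivity(A),
                 tolerance = 1e-12)
  }
})

test_that("sphere cardinalities partition the graph and respect eccentricity", {
  expect_equal(sphere_cardinalities(fix_cycle(5), "c03", 2), c(2L, 2L))
  star <- fix_star(3)
  expect_equal(sphere_cardinalities(star, "hub", 2), c(3L, 0L))
  expect_equal(sphere_cardinalities(star, "leaf1", 2), c(1L, 2L))
  p4 <- fix_path(c("a", "b", "c", "d"))
  expect_equal(sphere_cardinalities(p4, "a", 3), c(1L, 1L, 1L))
  expect_error(sphere_cardinalities(p4, "a", 2), "eccentricity")
  # sum over spheres = n - 1 for every vertex
  g <- largest_connected_component(fix_cube())
  rho <- network_diameter(g)
  for (v in network_nodes(g)) {
    expect_equal(sum(sphere_cardinalities(g, v, rho)),
                 igraph::vcount(g) - 1L)
  }
})

test_that("descriptors are invariant under node relabeling", {
  set.seed(5)
  em <- oracle_random_graph(12, 0.3)
  g <- largest_connected_component(gene_network(em))
  nodes <- network_nodes(g)
  for (rep in 1:5) {
    perm <- setNames(sample(sprintf("z%02d", seq_along(nodes))), nodes)
    em2 <- network_edges(g)
    em2[] <- perm[em2]
    g2 <- gene_network(em2)
    expect_equal(global_clustering_coefficient(g2),
                 global_clustering_coefficient(g))
    expect_equal(average_path_length(g2), average_path_length(g))
    expect_equal(network_diameter(g2), network_diameter(g))
  }
})
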