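test_that("union graph merges pathways, dropping duplicates and self-loops", {
  g <- build_union_graph(list(
    cbind(c("A", "B"), c("B", "C")),
    cbind(c("B", "C"), c("C", "D"))
  ))
  expect_equal(network_size(g), 4)
  expect_equal(igraph::ecount(g$graph), 3)

  g2 <- build_union_graph(list(cbind(c("A", "A"), c("A", "B"))))
  expect_equal(igraph::ecount(g2$graph), 1)
  expect_setequal(network_nodes(g2), c("A", "B"))

  expect_error(build_union_graph(list()), "no edges")
  expect_error(build_union_graph(list(matrix("A", 1, 3))), "malformed|2")
})

test_that("union of random pathways matches pairwise-merge oracle", {
  set.seed(7)
  for (rep in 1:10) {
    pathways <- lapply(1:10, function(i) {
      nodes <- sample(LETTERS[1:5], 5)
      cbind(sample(nodes, 6, replace = TRUE), sample(nodes, 6, replace = TRUE))
    })
    pathways <- lapply(pathways, function(m) m[m[, 1] != m[, 2], , drop = FALSE])
    pathways <- Filter(function(m) nrow(m) > 0, pathways)
    g <- build_union_graph(pathways)
    # oracle: canonicalise each edge and merge pairwise with set union
    canon <- function(m) unique(apply(m, 1, function(e) paste(sort(e), collapse = "|")))
    merged <- Reduce(union, lapply(pathways, canon))
    expect_equal(igraph::ecount(g$graph), length(merged))
    expect_setequal(network_nodes(g), unique(unlist(strsplit(merged, "|", fixed = TRUE))))
  }
})

test_that("largest connected component keeps the biggest piece, ties lexicographic", {
  g <- gene_network(rbind(
    c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),  # 5 nodes
    c("X", "Y"), c("Y", "Z")                             # 3 nodes
  ))
  lcc <- largest_connected_component(g)
  expect_setequal(network_nodes(lcc), c("A", "B", "C", "D", "E"))

  connected <- gene_network(rbind(c("A", "B"), c("B", "C")))
  expect_setequal(network_nodes(largest_connected_component(connected)),
                  network_nodes(connected))

  tied <- gene_network(rbind(c("M", "N"), c("N", "O"), c("A", "B"), c("B", "C")))
  expect_setequal(network_nodes(largest_connected_component(tied)),
                  c("A", "B", "C"))
})

test_that("geodesic distances match hand cases and refuse disconnected input", {
  path <- gene_network(cbind(c("A", "B", "C"), c("B", "C", "D")))
  o <- geodesic_distances(path)
  expect_equal(o$d["A", "D"], 3L)
  expect_equal(o$diameter, 3L)

  k4 <- build_union_graph(list(t(combn(c("A", "B", "C", "D"), 2))))
  o4 <- geodesic_distances(k4)
  expect_true(all(o4$d[upper.tri(o4$d)] == 1L))
  expect_equal(o4$diameter, 1L)

  disc <- gene_network(rbind(c("A", "B"), c("X", "Y")))
  expect_error(geodesic_distances(disc), "disconnected|component")
})

test_that("distances agree with Floyd-Warshall on random connected graphs", {
  set.seed(11)
  for (rep in 1:10) {
    rg <- random_connected_edges(sample(5:30, 1))
    net <- gene_network(rg$edges)
    o <- geodesic_distances(net)
    fw <- oracle_floyd_warshall(rg$edges, rg$nodes)
    expect_equal(o$d[rg$nodes, rg$nodes], fw[rg$nodes, rg$nodes],
                 ignore_attr = TRUE)
    # oracle invariants: symmetry and triangle inequality on a sample
    expect_true(isSymmetric(unname(o$d)))
  }
})

test_that("neighborhoods exclude the center, respect the radius, and nest", {
  path <- gene_network(cbind(c("A", "B", "C"), c("B", "C", "D")))
  o <- geodesic_distances(path)
  expect_setequal(neighborhood(o, "B", 1), c("A", "C"))
  expect_setequal(neighborhood(o, "A", o$diameter), c("B", "C", "D"))
  expect_error(neighborhood(o, "A", 0), "radius")
  expect_error(neighborhood(o, "A", o$diameter + 1), "radius")

  set.seed(23)
  rg <- random_connected_edges(20)
  o2 <- geodesic_distances(gene_network(rg$edges))
  for (r in seq_len(o2$diameter - 1)) {
    a <- neighborhood(o2, "n01", r)
    b <- neighborhood(o2, "n01", r + 1)
    expect_true(all(a %in% b))
    # direct distance-filter oracle
    expect_setequal(a, setdiff(rg$nodes[o2$d["n01", ] <= r], "n01"))
  }
  expect_setequal(neighborhood(o2, "n05", o2$diameter), setdiff(rg$nodes, "n05"))

  # within= restricts to assayed genes
  expect_equal(neighborhood(o, "B", 1, within = c("C", "D")), "C")
})

test_that("network files round-trip through edge-list and SIF formats", {
  net <- gene_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  f <- tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f)
  expect_setequal(network_nodes(back), network_nodes(net))
  expect_equal(igraph::ecount(back$graph), igraph::ecount(net$graph))

  sif <- tempfile(fileext = ".sif")
  writeLines(c("# comment", "A\tpp\tB", "B\tpp\tC"), sif)
  s <- read_network(sif)
  expect_setequal(network_nodes(s), c("A", "B", "C"))
  expect_equal(igraph::ecount(s$graph), 2)

  bad <- tempfile()
  writeLines(c("A\tB", "oops"), bad)
  expect_error(read_network(bad), "malformed")
})
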