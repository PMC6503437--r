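test_that("kendall tau-b matches hand-worked and trivial cases", {
  expect_equal(kendall_tau_b(c(3, 2, 1), c(1, 2, 3)), -1)
  expect_equal(kendall_tau_b(1:3, 1:3), 1)
  # ties: x=(2,2,1), y=(1,1,2): C=0, D=2, n1=n2=1 -> -2/sqrt(2*2)
  expect_equal(kendall_tau_b(c(2, 2, 1), c(1, 1, 2)), -1)
  expect_true(is.na(kendall_tau_b(c(1, 1, 1), 1:3)))
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")
  expect_error(kendall_tau_b(c(1, NA), 1:2), "missing")
})

test_that("tau-b equals the pair-enumeration oracle and stats::cor on tied data", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(2:50, 1)
    x <- sample(1:5, n, replace = TRUE) + 0   # heavy ties
    y <- sample(1:4, n, replace = TRUE) + 0
    mine <- kendall_tau_b(x, y)
    ora <- oracle_tau_b(x, y)
    expect_identical(is.na(mine), is.na(ora))
    if (!is.na(mine)) {
      expect_equal(mine, ora, tolerance = 1e-12)
      ref <- suppressWarnings(cor(x, y, method = "kendall"))
      if (!is.na(ref)) expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
})

test_that("nested-prefix kernel equals the direct kernel at every radius", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(4:40, 1)
    d <- sort(sample(1:6, n, replace = TRUE))
    X <- matrix(sample(1:6, n * 5, replace = TRUE) + 0, n, 5)
    grp <- rle(d)
    nested <- genesurrounder:::tau_b_nested_cpp(X, grp$lengths)
    cum <- cumsum(grp$lengths)
    for (k in seq_along(cum)) {
      if (cum[k] < 2) next
      for (b in 1:5) {
        direct <- kendall_tau_b(X[1:cum[k], b], d[1:cum[k]])
        expect_identical(is.na(direct), is.na(nested[k, b]))
        if (!is.na(direct)) expect_equal(nested[k, b], direct, tolerance = 1e-12)
      }
    }
  }
})

test_that("observed discordance is -1 for a perfect decay and NA when degenerate", {
  # path p1-p2-...-p6: distances from p1 are 1..5
  nodes <- paste0("p", 1:6)
  net <- gene_network(cbind(nodes[-6], nodes[-1]))
  o <- geodesic_distances(net)
  de <- data.frame(gene = nodes, g = c(9, 5, 4, 3, 2, 1))
  expect_equal(observed_discordance(de, o, "p1", r = 5), -1)
  # constant g: all x tied -> undefined
  de2 <- data.frame(gene = nodes, g = rep(2, 6))
  expect_true(is.na(observed_discordance(de2, o, "p1", r = 5)))
  # too-small neighborhood
  expect_true(is.na(observed_discordance(de, o, "p1", r = 2)))
})

test_that("observed discordance equals the O(n^2) oracle on random graphs", {
  set.seed(37)
  for (rep in 1:10) {
    rg <- random_connected_edges(18)
    net <- gene_network(rg$edges)
    o <- geodesic_distances(net)
    de <- data.frame(gene = rg$nodes, g = rexp(18))
    r <- sample(seq_len(o$diameter), 1)
    nb <- neighborhood(o, "n01", r)
    if (length(nb) < 3) next
    expect_equal(observed_discordance(de, o, "n01", r),
                 oracle_tau_b(de$g[match(nb, de$gene)], as.numeric(o$d["n01", nb])),
                 tolerance = 1e-12)
  }
})

test_that("decay p-value curve: tails, degenerate radii, determinism", {
  set.seed(41)
  nodes <- paste0("p", 1:8)
  net <- gene_network(cbind(nodes[-8], nodes[-1]))
  o <- geodesic_distances(net)
  st <- toy_study(n_genes = 8, n_per_class = 5, seed = 43)
  rownames(st$exprs) <- nodes
  de <- de_statistic(st)

  dc1 <- decay_pvalue_curve(de, o, "p1", study = st, B = 100, seed = 19)
  dc2 <- decay_pvalue_curve(de, o, "p1", study = st, B = 100, seed = 19)
  expect_identical(dc1, dc2)
  expect_true(all(dc1$p_decay > 0 & dc1$p_decay <= 1))
  # radii with < 3 assayed neighbors are reported undefined with p = 1
  expect_equal(dc1$p_decay[dc1$n_neighbors < 3], rep(1, sum(dc1$n_neighbors < 3)))
  expect_true(all(is.na(dc1$D_obs[dc1$n_neighbors < 3])))
  expect_true(all(dc1$p_decay >= 1 / 101))

  # strict variant reproduces the plain lower-tail fraction
  pg <- genesurrounder:::permuted_de_matrix(st, B = 60, seed = 23)
  ds <- decay_pvalue_curve(de, o, "p1", perm_g = pg, strict = TRUE)
  dn <- decay_pvalue_curve(de, o, "p1", perm_g = pg, strict = FALSE)
  k <- which(ds$n_neighbors >= 3)[1]
  expect_lte(ds$p_decay[k], dn$p_decay[k])
})

test_that("decay p-value is invariant to monotone transforms of g (rank statistic)", {
  nodes <- paste0("p", 1:7)
  net <- gene_network(cbind(nodes[-7], nodes[-1]))
  o <- geodesic_distances(net)
  st <- toy_study(n_genes = 7, n_per_class = 4, seed = 51)
  rownames(st$exprs) <- nodes
  de <- de_statistic(st)
  pg <- genesurrounder:::permuted_de_matrix(st, B = 50, seed = 29)
  base <- decay_pvalue_curve(de, o, "p1", perm_g = pg)
  de2 <- de; de2$g <- de2$g^3
  pg2 <- pg^3  # same monotone transform of the null statistics
  trans <- decay_pvalue_curve(de2, o, "p1", perm_g = pg2)
  expect_equal(base$p_decay, trans$p_decay, tolerance = 1e-12)
  expect_equal(base$D_obs, trans$D_obs, tolerance = 1e-12)
})

test_that("label permutation leaves inter-gene correlations untouched", {
  st <- toy_study(n_genes = 6, seed = 61)
  perm <- permute_labels(st, seed = 3)
  expect_identical(cor(t(st$exprs)), cor(t(perm$exprs)))
})
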