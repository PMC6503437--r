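test_that("expression_study validates its inputs", {
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_s3_class(expression_study(m, c("x", "x", "y", "y")), "expression_study")
  expect_error(expression_study(m, c("x", "x", "x", "y")), "at least 2")
  expect_error(expression_study(m, c("x", "x", "y", "z")), "exactly 2")
  m2 <- m; rownames(m2) <- c("a", "a", "c")
  expect_error(expression_study(m2, c("x", "x", "y", "y")), "duplicate")
  # named phenotype must cover all samples
  colnames(m) <- paste0("S", 1:4)
  expect_error(expression_study(m, c(S1 = "x", S2 = "x", S3 = "y")), "S4")
})

test_that("spearman profile matches monotone cases and the midrank oracle", {
  exprs <- rbind(i = c(1, 2, 3, 4), up = c(10, 20, 30, 40), down = c(4, 3, 2, 1))
  st <- expression_study(exprs, c("a", "a", "b", "b"))
  prof <- spearman_profile(st, "i")
  expect_equal(unname(prof["up"]), 1)
  expect_equal(unname(prof["down"]), -1)
  expect_false("i" %in% names(prof))

  set.seed(5)
  genes <- sprintf("g%02d", 1:20)
  exprs <- matrix(sample(1:4, 20 * 8, replace = TRUE) + 0, nrow = 20,
                  dimnames = list(genes, NULL))  # heavy ties on purpose
  st <- expression_study(exprs, rep(c("a", "b"), each = 4))
  prof <- spearman_profile(st, "g01")
  for (j in names(prof)) {
    expect_equal(prof[[j]], oracle_spearman(exprs["g01", ], exprs[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  st <- toy_study(n_genes = 6, seed = 8)
  p1 <- spearman_profile(st, "t01")
  st2 <- st
  st2$exprs["t01", ] <- exp(st2$exprs["t01", ])         # monotone on center
  st2$exprs["t03", ] <- st2$exprs["t03", ]^3            # monotone (odd power)
  p2 <- spearman_profile(st2, "t01")
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("zero-variance genes yield rho 0 with a warning", {
  exprs <- rbind(i = c(1, 2, 3, 4), flat = c(5, 5, 5, 5), v = c(2, 1, 4, 3))
  st <- expression_study(exprs, c("a", "a", "b", "b"))
  expect_warning(prof <- spearman_profile(st, "i"), "zero-variance")
  expect_equal(unname(prof["flat"]), 0)
  expect_equal(unname(prof["v"]), oracle_spearman(exprs["i", ], exprs["v", ]))
})

test_that("de_statistic matches t.test and the textbook Welch oracle", {
  st <- toy_study(n_genes = 10, n_per_class = 6, seed = 31)
  de <- de_statistic(st)
  g1 <- st$phenotype == levels(st$phenotype)[1]
  for (k in c(1, 4, 10)) {
    x1 <- st$exprs[k, g1]; x2 <- st$exprs[k, !g1]
    ref <- t.test(x1, x2)
    ora <- oracle_welch_t(x1, x2)
    expect_equal(de$t[k], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(de$t[k], ora$t, tolerance = 1e-12)
    expect_equal(de$p_de[k], ref$p.value, tolerance = 1e-12)
    expect_equal(de$p_de[k], ora$p, tolerance = 1e-12)
  }
  expect_true(all(de$g >= 0))

  # pooled variant against t.test(var.equal = TRUE)
  dep <- de_statistic(st, var.equal = TRUE)
  ref <- t.test(st$exprs[2, g1], st$exprs[2, !g1], var.equal = TRUE)
  expect_equal(dep$t[2], unname(ref$statistic), tolerance = 1e-12)
})

test_that("de_statistic separates shifted groups and is ~0 under equality", {
  set.seed(77)
  n <- 40
  eps <- rnorm(2 * n, sd = 1e-3)
  exprs <- rbind(sep = c(rep(1, n), rep(5, n)) + eps,
                 null = rnorm(2 * n))
  st <- expression_study(exprs, rep(c("a", "b"), each = n))
  de <- de_statistic(st)
  expect_gt(de$g[de$gene == "sep"], 100)
  expect_lt(de$p_de[de$gene == "sep"], 1e-10)
  expect_lt(de$g[de$gene == "null"], 3)
})

test_that("label permutation preserves the class multiset and is seed-stable", {
  st <- toy_study(seed = 3)
  p1 <- permute_labels(st, seed = 99)
  p2 <- permute_labels(st, seed = 99)
  expect_identical(p1$phenotype, p2$phenotype)
  expect_identical(table(p1$phenotype), table(st$phenotype))
  expect_identical(p1$exprs, st$exprs)
})

test_that("permutations are uniform over arrangements", {
  # labels (a,a,b): 3 distinct arrangements, each should appear w.p. 1/3
  m <- matrix(rnorm(3), 1, 3, dimnames = list("g", NULL))
  st <- structure(list(exprs = m, phenotype = factor(c("a", "a", "b"))),
                  class = "expression_study")
  set.seed(123)
  n_draw <- 3000
  arr <- replicate(n_draw, paste(permute_labels(st)$phenotype, collapse = ""))
  freq <- table(arr) / n_draw
  expect_equal(length(freq), 3)
  se3 <- sqrt(1 / 3 * 2 / 3 / n_draw)
  expect_true(all(abs(freq - 1 / 3) < 3 * se3))
})

test_that("permuted |t| matrix matches per-column direct recomputation", {
  st <- toy_study(n_genes = 5, n_per_class = 4, seed = 13)
  pg <- genesurrounder:::permuted_de_matrix(st, B = 4, seed = 55)
  set.seed(55)
  for (b in 1:4) {
    lab <- st$phenotype[sample.int(length(st$phenotype))]
    sts <- st; sts$phenotype <- lab
    expect_equal(unname(pg[, b]), de_statistic(sts)$g, tolerance = 1e-12)
  }
})
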