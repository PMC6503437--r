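# Independent brute-force oracles used to validate the package's fast paths.

# Kendall tau-b by explicit enumeration of all pairs, with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0) tx <- tx + 1L
      if (dy == 0) ty <- ty + 1L
      if (dx != 0 && dy != 0) {
        if (sign(dx) == sign(dy)) conc <- conc + 1L else disc <- disc + 1L
      }
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt(n0 - tx) * sqrt(n0 - ty)
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

# Spearman via midranks followed by the textbook Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All-pairs shortest paths by Floyd-Warshall on an edge list.
oracle_floyd_warshall <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Welch two-sample t from the textbook formula (scalar, one gene).
oracle_welch_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1); v2 <- var(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Random connected graph: random spanning tree plus extra random edges.
random_connected_edges <- function(n_nodes, extra = n_nodes) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  tree <- cbind(nodes[vapply(2:n_nodes, function(i) sample.int(i - 1, 1), 1L)],
                nodes[2:n_nodes])
  more <- cbind(sample(nodes, extra, replace = TRUE),
                sample(nodes, extra, replace = TRUE))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  list(edges = rbind(tree, more), nodes = nodes)
}

# Small deterministic study used across module tests.
toy_study <- function(n_genes = 12, n_per_class = 5, seed = 42) {
  set.seed(seed)
  genes <- sprintf("t%02d", seq_len(n_genes))
  n <- 2 * n_per_class
  exprs <- matrix(rnorm(n_genes * n), nrow = n_genes,
                  dimnames = list(genes, sprintf("S%02d", seq_len(n))))
  expression_study(exprs, rep(c("a", "b"), each = n_per_class))
}
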