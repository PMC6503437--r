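#' Generate a connected benchmark network
#'
#' Standard graph families for validation: `path` and `star` give analytic
#' distance structure, `small_world` (Watts–Strogatz, neighborhood 2,
#' rewiring 0.05) gives realistic clustering, and `scale_free`
#' (Barabasi–Albert, 2 edges per new node) gives the heavy-tailed degree
#' distribution typical of pathway union graphs.
#'
#' @param kind one of `"path"`, `"star"`, `"small_world"`, `"scale_free"`.
#' @param n_nodes number of genes (>= 4).
#' @param seed optional integer for reproducibility.
#' @return a connected `gene_network` with node ids `g001, g002, ...`.
#' @export
make_network <- function(kind = c("path", "star", "small_world", "scale_free"),
                         n_nodes, seed = NULL) {
  kind <- match.arg(kind)
  if (n_nodes < 4L) stop("n_nodes must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  g <- switch(kind,
    path = igraph::make_ring(n_nodes, circular = FALSE),
    star = igraph::make_star(n_nodes, mode = "undirected"),
    small_world = {
      repeat {
        gg <- igraph::sample_smallworld(1, n_nodes, nei = 2, p = 0.05)
        gg <- igraph::simplify(gg)
        if (igraph::is_connected(gg)) break
      }
      gg
    },
    scale_free = igraph::sample_pa(n_nodes, m = 1, directed = FALSE)
  )
  igraph::V(g)$name <- sprintf(paste0("g%0", nchar(n_nodes), "d"),
                               seq_len(n_nodes))
  new_gene_network(g)
}

#' Planted-driver ground truth for synthetic studies
#'
#' Describes the structure planted by [make_study()]: a driver gene whose
#' expression is a latent factor, whose neighbors load on that factor with a
#' loading that decays geometrically with geodesic distance
#' (`lambda(d) = lambda0 * gamma^d`), and whose neighbors also carry a
#' class-mean shift that decays geometrically
#' (`delta(d) = delta0 * gamma_de^d`). Genes beyond `cutoff` hops are pure
#' noise with no class effect. This single-factor construction induces both
#' defining signatures of a dysregulation source — correlation with the
#' driver and distance-decaying differential expression — with closed-form
#' moments.
#'
#' @param driver gene id of the planted driver, or `NULL` to let
#'   [make_study()] pick the highest-degree node.
#' @param lambda0 factor loading at distance 1 scale (default 0.8).
#' @param gamma per-hop decay of the loading, in (0,1) (default 0.6).
#' @param delta0 class mean shift scale (default 1.5, in noise-sd units).
#' @param gamma_de per-hop decay of the shift, in (0,1) (default 0.6).
#' @param noise_sd independent noise standard deviation (default 1).
#' @param n_per_class samples per class, length-2 integer (default 30+30).
#' @param cutoff hop distance beyond which genes are pure noise (default 4).
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(driver = NULL, lambda0 = 0.8, gamma = 0.6,
                            delta0 = 1.5, gamma_de = 0.6, noise_sd = 1,
                            n_per_class = c(30L, 30L), cutoff = 4L) {
  stopifnot(gamma > 0, gamma < 1, gamma_de > 0, gamma_de < 1,
            lambda0 >= 0, delta0 >= 0, noise_sd > 0, cutoff >= 1)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 2L))
  structure(list(driver = driver, lambda0 = lambda0, gamma = gamma,
                 delta0 = delta0, gamma_de = gamma_de, noise_sd = noise_sd,
                 n_per_class = as.integer(n_per_class),
                 cutoff = as.integer(cutoff)),
            class = "synthetic_truth")
}

#' Simulate a two-class study with a planted driver
#'
#' Per sample, a latent factor `z ~ N(0,1)` is drawn. The driver's
#' expression is `z + noise`. A gene at geodesic distance `d <= cutoff` from
#' the driver gets `lambda(d) * z + noise + delta(d) * 1[case]`; genes
#' farther away are pure noise. Only a fraction of the network's genes are
#' assayed (the driver always is): the rest remain unassayed conduits, as in
#' real pathway networks where not every node is on the array.
#'
#' @param net a connected `gene_network`.
#' @param truth a [synthetic_truth()]; a `NULL` driver is replaced by the
#'   highest-degree node (ties broken lexicographically).
#' @param seed optional integer; same seed, same study, bit for bit.
#' @param assay_frac fraction of genes assayed (default 0.75).
#' @return an `expression_study` whose genes are the assayed subset, with
#'   the completed `synthetic_truth` attached as attribute `"truth"`.
#' @export
make_study <- function(net, truth = synthetic_truth(), seed = NULL,
                       assay_frac = 0.75) {
  stopifnot(inherits(truth, "synthetic_truth"), assay_frac > 0, assay_frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- network_nodes(net)
  if (is.null(truth$driver)) {
    # the planted dysregulation must be *local*: the driver needs genes
    # beyond its cutoff (eccentricity > cutoff, so the decay boundary is
    # observable) and its cutoff-ball should cover a minority of the
    # network (otherwise most of the correlation pool is its own signal
    # and the planted structure is global, not a localized source);
    # among such nodes take the best-connected one
    dmat <- igraph::distances(net$graph, algorithm = "unweighted")
    ecc <- apply(dmat, 1L, max)
    ball <- rowSums(dmat <= truth$cutoff)
    deg <- network_degree(net)
    eligible <- nodes[ecc > truth$cutoff & ball <= 0.25 * length(nodes)]
    if (length(eligible) == 0L) eligible <- nodes[ball == min(ball)]
    truth$driver <- min(eligible[deg[eligible] == max(deg[eligible])])
  }
  if (!truth$driver %in% nodes) stop(sprintf("driver '%s' not in network", truth$driver))

  n_assay <- max(3L, round(assay_frac * length(nodes)))
  assayed <- if (n_assay >= length(nodes)) nodes else {
    union(truth$driver, sample(setdiff(nodes, truth$driver), n_assay - 1L))
  }
  assayed <- nodes[nodes %in% assayed]  # keep network order

  n1 <- truth$n_per_class[1L]; n2 <- truth$n_per_class[2L]
  n <- n1 + n2
  labels <- factor(rep(c("control", "case"), c(n1, n2)),
                   levels = c("control", "case"))
  z <- rnorm(n)
  d_drv <- igraph::distances(net$graph, v = truth$driver,
                             algorithm = "unweighted")[1L, assayed]
  lam <- ifelse(d_drv <= truth$cutoff, truth$lambda0 * truth$gamma^d_drv, 0)
  lam[d_drv == 0] <- 1  # the driver is the factor itself
  del <- ifelse(d_drv <= truth$cutoff & d_drv > 0,
                truth$delta0 * truth$gamma_de^d_drv, 0)
  noise <- matrix(rnorm(length(assayed) * n, sd = truth$noise_sd),
                  nrow = length(assayed))
  exprs <- lam %o% z + noise + del %o% (as.integer(labels == "case"))
  dimnames(exprs) <- list(assayed, sprintf("S%03d", seq_len(n)))
  study <- expression_study(exprs, setNames(labels, colnames(exprs)))
  attr(study, "truth") <- truth
  study
}

#' Simulate a null study: no driver, no phenotype signal
#'
#' Every gene is independent Gaussian noise and the labels carry no
#' information; used to check the type-I calibration of all three p-values.
#'
#' @param net a `gene_network` (all its genes are assayed).
#' @param n_per_class samples per class (scalar or length-2).
#' @param sd noise standard deviation.
#' @param seed optional integer.
#' @return an `expression_study`.
#' @export
make_null_study <- function(net, n_per_class = 20L, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  nodes <- network_nodes(net)
  n <- sum(n_per_class)
  labels <- factor(rep(c("control", "case"), n_per_class),
                   levels = c("control", "case"))
  exprs <- matrix(rnorm(length(nodes) * n, sd = sd), nrow = length(nodes),
                  dimnames = list(nodes, sprintf("S%03d", seq_len(n))))
  expression_study(exprs, setNames(labels, colnames(exprs)))
}

#' Write a synthetic truth sidecar / read it back
#'
#' Flat two-column `key<TAB>value` text, so the planted parameters travel
#' with the generated data files.
#'
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @return `read_truth()` returns a `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  kv <- c(driver = truth$driver, lambda0 = truth$lambda0,
          gamma = truth$gamma, delta0 = truth$delta0,
          gamma_de = truth$gamma_de, noise_sd = truth$noise_sd,
          n_class1 = truth$n_per_class[1L], n_class2 = truth$n_per_class[2L],
          cutoff = truth$cutoff)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  kv <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("key", "value"))
  v <- setNames(kv$value, kv$key)
  synthetic_truth(
    driver = v[["driver"]],
    lambda0 = as.numeric(v[["lambda0"]]), gamma = as.numeric(v[["gamma"]]),
    delta0 = as.numeric(v[["delta0"]]),
    gamma_de = as.numeric(v[["gamma_de"]]),
    noise_sd = as.numeric(v[["noise_sd"]]),
    n_per_class = c(as.integer(v[["n_class1"]]), as.integer(v[["n_class2"]])),
    cutoff = as.integer(v[["cutoff"]])
  )
}

#' Generate and write a complete synthetic data set
#'
#' Front end used by the CLI `simulate` subcommand: builds a network and a
#' planted-driver study and writes the same file formats the pipeline reads
#' (`expression.tsv`, `phenotype.tsv`, `network.tsv`) plus the `truth.tsv`
#' sidecar.
#'
#' @param out_dir output directory (created if absent).
#' @param kind network family (see [make_network()]).
#' @param n_nodes network size.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @param assay_frac fraction of genes assayed.
#' @return invisibly, a list with the study, network and file paths.
#' @export
simulate_study <- function(out_dir, kind = "scale_free", n_nodes = 200L,
                           truth = synthetic_truth(), seed = 1L,
                           assay_frac = 0.75) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_network(kind, n_nodes, seed = seed)
  study <- make_study(net, truth, seed = seed + 1L, assay_frac = assay_frac)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    network = file.path(out_dir, "network.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_study(study, paths$expression, paths$phenotype)
  write_network(net, paths$network)
  write_truth(attr(study, "truth"), paths$truth)
  invisible(list(study = study, network = net, paths = paths))
}
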