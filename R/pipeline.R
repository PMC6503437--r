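# Stable per-gene seed so a gene's resampling stream depends on the master
# seed and the gene id only — scoring a subset of genes reproduces exactly
# the values of a full run.
gene_seed <- function(seed, id) {
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 131 + c) %% 2147483647
  as.integer((h + seed) %% 2147483647)
}

#' Run the full radius-scan analysis on in-memory objects
#'
#' The core of the method. For every assayed gene on the network's largest
#' connected component, computes the sphere-of-influence and
#' decay-of-differential-expression p-value curves over radii 1..D (D = the
#' component diameter), Fisher-combines them per radius, and reports each
#' gene's minimum combined p-value `p_GS`, its best radius, and a
#' Bonferroni significance call at level `alpha / D`.
#'
#' Network nodes that are not assayed stay in the graph as conduits — they
#' shape geodesic distances — but are never scored, never enter a
#' correlation profile, and never contribute to a neighborhood sum.
#'
#' The scan uses the same radius grid 1..D for every gene even where a
#' gene's eccentricity is smaller (its curves simply flatten once the
#' neighborhood saturates), keeping the Bonferroni factor D uniform.
#'
#' @param study an `expression_study` with complete data.
#' @param net a `gene_network`; reduced internally to its largest connected
#'   component.
#' @param B_sphere,B_decay numbers of resamplings / label permutations
#'   (default 1000 each).
#' @param alpha significance level for the Bonferroni call (default 0.05).
#' @param seed optional integer master seed; makes the whole run
#'   deterministic. Per-gene resampling streams are derived from it and the
#'   gene id, and one shared set of `B_decay` label permutations is drawn
#'   for the decay nulls.
#' @param genes optional character vector: score only these genes (they must
#'   be assayed and on the component). Scores are identical to a full run.
#' @param min_neighbors smallest neighborhood for the decay statistic.
#' @param var.equal pooled-variance t instead of Welch.
#' @param strict strict (unsmoothed) decay tail count.
#' @param verbose print network statistics and progress.
#' @return list of class `gs_fit` with elements `results` (ranked table:
#'   `rank`, `gene`, `p_gs`, `neglog10_p_gs`, `best_radius`, `significant`,
#'   `p_de`, `degree`), `curves` (long per-gene per-radius diagnostics),
#'   and `stats` (nodes, edges, diameter, scored genes, threshold, B's,
#'   seed).
#' @export
gene_surrounder <- function(study, net, B_sphere = 1000L, B_decay = 1000L,
                            alpha = 0.05, seed = NULL, genes = NULL,
                            min_neighbors = 3L, var.equal = FALSE,
                            strict = FALSE, verbose = FALSE) {
  lcc <- largest_connected_component(net)
  scored <- intersect(study_genes(study), network_nodes(lcc))
  if (length(scored) < 3L) {
    stop("fewer than 3 assayed genes on the network component")
  }
  lcc$assayed <- scored
  oracle <- geodesic_distances(lcc)
  D <- oracle$diameter
  if (D < 1L) stop("degenerate network (diameter 0)")
  threshold <- bonferroni_threshold(alpha, D)

  targets <- if (is.null(genes)) scored else {
    bad <- setdiff(genes, scored)
    if (length(bad)) {
      stop(sprintf("gene(s) not assayed on the network component: %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
    genes
  }
  targets <- sort(targets)

  if (verbose) {
    message(sprintf(
      "network: %d nodes, %d edges, diameter %d; scoring %d of %d assayed genes",
      network_size(lcc), igraph::ecount(lcc$graph), D,
      length(targets), length(scored)))
    message(sprintf(
      "B_sphere = %d, B_decay = %d, alpha = %g, -log10 Bonferroni threshold = %.2f, seed = %s",
      B_sphere, B_decay, alpha, threshold,
      if (is.null(seed)) "<none>" else seed))
  }

  sub <- study
  sub$exprs <- study$exprs[scored, , drop = FALSE]
  rho <- spearman_matrix(sub)
  destats <- de_statistic(sub, var.equal = var.equal)
  perm_g <- permuted_de_matrix(
    sub, B = B_decay,
    seed = if (is.null(seed)) NULL else gene_seed(seed, ".decay-permutations"),
    var.equal = var.equal)

  radii <- seq_len(D)
  scores <- vector("list", length(targets))
  curves <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    i <- targets[k]
    profile <- rho[i, setdiff(scored, i)]
    sp <- sphere_pvalue_curve(
      profile, oracle, i, radii = radii, B = B_sphere,
      seed = if (is.null(seed)) NULL else gene_seed(seed, i))
    dc <- decay_pvalue_curve(
      destats, oracle, i, radii = radii, perm_g = perm_g,
      min_neighbors = min_neighbors, strict = strict)
    sc <- scan_radii(sp, dc, D = D, alpha = alpha)
    sc$score$gene <- i
    curves[[k]] <- cbind(gene = i, sc$curve, stringsAsFactors = FALSE)
    scores[[k]] <- sc$score
  }
  results <- rank_genes(do.call(rbind, scores), destats = destats,
                        degrees = network_degree(lcc))
  structure(list(
    results = results,
    curves = do.call(rbind, curves),
    stats = list(
      nodes = network_size(lcc), edges = igraph::ecount(lcc$graph),
      diameter = D, n_scored = length(targets), alpha = alpha,
      neglog10_threshold = threshold, B_sphere = as.integer(B_sphere),
      B_decay = as.integer(B_decay), seed = seed)
  ), class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, n = 10L, ...) {
  s <- x$stats
  cat(sprintf("GeneSurrounder fit: %d genes scored on a %d-node network (diameter %d)\n",
              s$n_scored, s$nodes, s$diameter))
  cat(sprintf("B_sphere = %d, B_decay = %d; -log10 Bonferroni threshold = %.2f (alpha = %g)\n",
              s$B_sphere, s$B_decay, s$neglog10_threshold, s$alpha))
  cat(sprintf("significant genes: %d\n\n", sum(x$results$significant)))
  print(utils::head(x$results, n))
  invisible(x)
}

#' Gene-level family-wise error adjustment by outer label permutation
#'
#' Adjusts each gene's `p_GS` for the multiplicity of genes tested with the
#' min-p / max-statistic scheme: for each of `B_outer` outer label
#' permutations the entire analysis is re-run and the smallest `p_GS` across
#' genes recorded; a gene's adjusted p-value is the (add-one) fraction of
#' those minima at or below its observed `p_GS`. Preserves the inter-gene
#' dependency structure, but costs `B_outer` full re-runs — keep `B_outer`
#' and the inner `B`s small.
#'
#' @param study an `expression_study`.
#' @param net a `gene_network`.
#' @param B_outer number of outer permutations.
#' @param seed optional integer master seed.
#' @param ... passed to [gene_surrounder()] (e.g. smaller `B_sphere`,
#'   `B_decay`).
#' @return the observed results table with an extra `p_gs_adj` column.
#' @export
genewise_fwer <- function(study, net, B_outer = 50L, seed = NULL, ...) {
  fit <- gene_surrounder(study, net, seed = seed, ...)
  obs <- fit$results
  minima <- numeric(B_outer)
  for (b in seq_len(B_outer)) {
    perm <- permute_labels(
      study, seed = if (is.null(seed)) NULL else gene_seed(seed, paste0(".fwer", b)))
    pf <- gene_surrounder(perm, net,
                          seed = if (is.null(seed)) NULL else seed + b, ...)
    minima[b] <- min(pf$results$p_gs)
  }
  obs$p_gs_adj <- vapply(obs$p_gs,
                         function(p) (1 + sum(minima <= p)) / (B_outer + 1),
                         numeric(1))
  obs
}
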