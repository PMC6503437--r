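#' Combine the two per-radius p-values by Fisher's method
#'
#' `X^2 = -2(ln pS + ln pD)` referred to a chi-square distribution with 4
#' degrees of freedom (two independent p-values, two degrees of freedom
#' each). The two tests permute orthogonal axes — genes for the sphere test,
#' samples for the decay test — which is what justifies treating them as
#' independent.
#'
#' @param pS,pD p-values in `(0, 1]` (vectorised).
#' @return data frame with columns `X2` and `p_comb`.
#' @examples
#' fisher_combine(0.05, 0.05) # X2 ~ 11.98, p_comb ~ 0.0175
#' @export
fisher_combine <- function(pS, pD) {
  if (any(pS <= 0) || any(pD <= 0)) {
    stop("p-values must be strictly positive (add-one empirical estimators guarantee this)")
  }
  if (any(pS > 1) || any(pD > 1)) stop("p-values must be <= 1")
  X2 <- -2 * (log(pS) + log(pD))
  data.frame(X2 = X2, p_comb = pchisq(X2, df = 4, lower.tail = FALSE))
}

#' Bonferroni threshold for the radius scan
#'
#' The scan evaluates one combined test per radius, and the number of radii
#' is the network diameter D, so the significance level is `alpha / D`.
#' Reported on the `-log10` scale used in result tables.
#'
#' @param alpha significance level (default 0.05).
#' @param D network diameter.
#' @return `-log10(alpha / D)`.
#' @examples
#' bonferroni_threshold(0.05, 34) # 2.83
#' @export
bonferroni_threshold <- function(alpha = 0.05, D) {
  stopifnot(alpha > 0, alpha < 1, D >= 1)
  -log10(alpha / D)
}

#' Scan radii and score one gene
#'
#' Merges a gene's sphere and decay curves, Fisher-combines them at every
#' radius, and extracts the gene's score: `p_GS`, the minimum combined
#' p-value over radii; the smallest radius attaining it; and the
#' diameter-scaled Bonferroni significance call `p_GS <= alpha / D`.
#'
#' @param sphere a `sphere_result` from [sphere_pvalue_curve()].
#' @param decay a `decay_result` from [decay_pvalue_curve()] on the same
#'   radii.
#' @param D network diameter (the Bonferroni factor).
#' @param alpha significance level.
#' @return list with `score` (one-row data frame: `gene`, `p_gs`,
#'   `neglog10_p_gs`, `best_radius`, `significant`) and `curve` (per-radius
#'   data frame with both input p-values, `X2`, `p_comb`, and the assayed
#'   neighborhood size).
#' @export
scan_radii <- function(sphere, decay, D, alpha = 0.05) {
  if (!identical(sphere$radius, decay$radius)) {
    stop("sphere and decay curves were computed on different radii")
  }
  fc <- fisher_combine(sphere$p_sphere, decay$p_decay)
  curve <- data.frame(
    radius = sphere$radius,
    n_neighbors = sphere$n_neighbors,
    C_obs = sphere$C_obs,
    p_sphere = sphere$p_sphere,
    D_obs = decay$D_obs,
    p_decay = decay$p_decay,
    X2 = fc$X2,
    p_comb = fc$p_comb
  )
  best <- which.min(curve$p_comb)  # smallest radius attaining the minimum
  p_gs <- curve$p_comb[best]
  score <- data.frame(
    gene = attr(sphere, "gene") %||% NA_character_,
    p_gs = p_gs,
    neglog10_p_gs = -log10(p_gs),
    best_radius = curve$radius[best],
    significant = p_gs <= alpha / D,
    stringsAsFactors = FALSE
  )
  list(score = score, curve = curve)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank scored genes
#'
#' Orders genes by ascending `p_GS` (most disruptive first), breaking ties
#' lexicographically by gene id, and attaches the per-gene differential-
#' expression p-value and network degree for context.
#'
#' @param scores data frame with one row per gene (`gene`, `p_gs`,
#'   `neglog10_p_gs`, `best_radius`, `significant`).
#' @param destats optional [de_statistic()] frame (adds `p_de`).
#' @param degrees optional named degree vector (adds `degree`).
#' @return the ranked data frame with a `rank` column.
#' @export
rank_genes <- function(scores, destats = NULL, degrees = NULL) {
  out <- scores[order(scores$p_gs, scores$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(destats)) out$p_de <- destats$p_de[match(out$gene, destats$gene)]
  if (!is.null(degrees)) out$degree <- as.integer(degrees[out$gene])
  rownames(out) <- NULL
  cols <- c("rank", "gene", "p_gs", "neglog10_p_gs", "best_radius",
            "significant", "p_de", "degree")
  out[, intersect(cols, names(out)), drop = FALSE]
}

#' Cross-study concordance of two result tables
#'
#' Spearman rank correlation between the `p_gs` vectors of two studies over
#' their shared genes — the reproducibility measure used to compare the
#' method against plain differential expression. The correlation between the
#' `p_de` vectors is returned alongside as the reference point.
#'
#' @param resultsA,resultsB ranked result tables from [rank_genes()] or
#'   [gene_surrounder()] (need `gene`, `p_gs`, and optionally `p_de`).
#' @return list with `rho_gs`, `rho_de` (NA if either table lacks `p_de`),
#'   and `n_shared`.
#' @export
concordance <- function(resultsA, resultsB) {
  shared <- intersect(resultsA$gene, resultsB$gene)
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  a <- resultsA[match(shared, resultsA$gene), ]
  b <- resultsB[match(shared, resultsB$gene), ]
  rho_gs <- cor(a$p_gs, b$p_gs, method = "spearman")
  rho_de <- if (!is.null(a$p_de) && !is.null(b$p_de)) {
    cor(a$p_de, b$p_de, method = "spearman")
  } else NA_real_
  list(rho_gs = rho_gs, rho_de = rho_de, n_shared = length(shared))
}
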