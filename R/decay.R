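#' Kendall tau-b rank correlation
#'
#' Tau-b with tie correction, `(C - D) / sqrt((n0 - n1)(n0 - n2))`, where C/D
#' are concordant/discordant pair counts, `n0 = n(n-1)/2` and `n1`, `n2` are
#' the numbers of pairs tied in `x` and in `y`. Distances in a geodesic
#' neighborhood are small integers, so ties in `y` are the norm here and the
#' correction matters. Returns `NA` when every pair is tied in `x` or in `y`
#' (the coefficient is undefined).
#'
#' @param x,y numeric vectors of equal length (>= 2), no missing values.
#' @return scalar in `[-1, 1]`, or `NA`.
#' @examples
#' kendall_tau_b(c(3, 2, 1), 1:3) # -1
#' @export
kendall_tau_b <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  tau_b_cpp(x, y)
}

#' Observed decay-of-differential-expression discordance
#'
#' `D_i(r)`: Kendall tau-b between the differential-expression magnitudes
#' `g_j` of the assayed genes in the radius-r neighborhood of gene i and
#' their geodesic distances `d_ij`. Differential expression that decays with
#' distance yields negative values. Neighborhoods with fewer than
#' `min_neighbors` assayed genes, or with all-tied inputs (e.g. every
#' neighbor at distance 1), carry no rank information: the statistic is
#' returned as `NA`.
#'
#' @param destats data frame from [de_statistic()] (or any frame with `gene`
#'   and `g` columns) covering the assayed on-network genes.
#' @param oracle a `distance_oracle`.
#' @param i center gene id.
#' @param r radius.
#' @param min_neighbors smallest neighborhood for which the statistic is
#'   computed (default 3).
#' @return scalar tau-b, or `NA` if undefined.
#' @export
observed_discordance <- function(destats, oracle, i, r, min_neighbors = 3L) {
  nbhd <- neighborhood(oracle, i, r, within = destats$gene)
  if (length(nbhd) < min_neighbors) return(NA_real_)
  g <- destats$g[match(nbhd, destats$gene)]
  d <- as.numeric(oracle$d[i, nbhd])
  tau_b_cpp(g, d)
}

#' Decay-of-differential-expression p-value curve for one gene
#'
#' For each radius, the observed discordance `D_i(r)` is referred to its
#' phenotype-permutation null: the labels are permuted `B` times, the
#' gene-level statistics recomputed, and the discordance re-evaluated over
#' the same neighborhood. Because the expression matrix is untouched, the
#' permutation preserves all inter-gene correlations (the self-contained
#' null). Decay means *negative* discordance, so the p-value is lower-tail:
#' `(1 + #{D* <= D_obs}) / (B + 1)` by default; `strict = TRUE` uses the
#' unsmoothed strict fraction `#{D* < D_obs} / B` instead.
#'
#' Radii whose neighborhood is too small (< `min_neighbors`) or whose
#' observed tau is undefined are reported with `D = NA` / `D = 0` and
#' `p_decay = 1`: no evidence either way. Undefined null taus count as 0.
#'
#' @param destats data frame from [de_statistic()] restricted to assayed
#'   on-network genes.
#' @param oracle a `distance_oracle`.
#' @param i center gene id.
#' @param radii integer radii (default `1:diameter`).
#' @param perm_g genes-x-B matrix of permuted `|t|` statistics. Computing it
#'   is the expensive step, so the pipeline builds one matrix per run (via
#'   the internal generator seeded by `seed`) and shares it across all center
#'   genes — statistically valid because each column is one complete label
#'   permutation.
#' @param study the `expression_study`; required when `perm_g` is not given.
#' @param B number of permutations (used only when `perm_g` is not given).
#' @param seed optional integer (used only when `perm_g` is not given).
#' @param min_neighbors smallest usable neighborhood (default 3).
#' @param strict use the strict, unsmoothed tail fraction.
#' @param var.equal pooled-variance t for the permuted statistics.
#' @return a data frame of class `decay_result` with columns `radius`,
#'   `n_neighbors`, `D_obs`, `p_decay`; attribute `B`.
#' @export
decay_pvalue_curve <- function(destats, oracle, i, radii = NULL,
                               perm_g = NULL, study = NULL, B = 1000L,
                               seed = NULL, min_neighbors = 3L,
                               strict = FALSE, var.equal = FALSE) {
  if (is.null(radii)) radii <- seq_len(oracle$diameter)
  if (is.null(perm_g)) {
    if (is.null(study)) stop("supply either perm_g or study")
    perm_g <- permuted_de_matrix(study, B = B, seed = seed,
                                 var.equal = var.equal)
  }
  B <- ncol(perm_g)
  genes <- intersect(intersect(destats$gene, rownames(perm_g)), oracle$nodes)
  di <- oracle$d[i, ]
  out <- data.frame(radius = as.integer(radii), n_neighbors = 0L,
                    D_obs = NA_real_, p_decay = 1)
  nbhd_all <- genes[di[genes] > 0L]
  if (length(nbhd_all) >= min_neighbors) {
    # sort the full neighborhood by distance once; the nested kernel then
    # yields tau at every distance-group prefix in one sweep per column
    ord <- order(di[nbhd_all], nbhd_all)
    nbhd_all <- nbhd_all[ord]
    d_sorted <- as.integer(di[nbhd_all])
    grp <- rle(d_sorted)
    cum_n <- cumsum(grp$lengths)
    g_obs <- destats$g[match(nbhd_all, destats$gene)]
    tau_obs <- tau_b_nested_cpp(matrix(g_obs, ncol = 1L), grp$lengths)[, 1L]
    tau_null <- tau_b_nested_cpp(perm_g[nbhd_all, , drop = FALSE],
                                 grp$lengths)
    for (k in seq_along(radii)) {
      r <- radii[k]
      gi <- which(grp$values <= r)
      if (length(gi) == 0L) next
      gi <- gi[length(gi)]
      out$n_neighbors[k] <- cum_n[gi]
      if (cum_n[gi] < min_neighbors) next
      D_obs <- tau_obs[gi]
      if (is.na(D_obs)) next  # all-tied observed statistic: no evidence
      D_null <- tau_null[gi, ]
      D_null[is.na(D_null)] <- 0
      out$D_obs[k] <- D_obs
      out$p_decay[k] <- if (strict) {
        sum(D_null < D_obs) / B
      } else {
        (1 + sum(D_null <= D_obs)) / (B + 1)
      }
    }
  } else {
    out$n_neighbors <- vapply(radii, function(r) {
      sum(di[genes] > 0L & di[genes] <= r)
    }, integer(1))
  }
  attr(out, "B") <- as.integer(B)
  attr(out, "gene") <- i
  class(out) <- c("decay_result", "data.frame")
  out
}
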