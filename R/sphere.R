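#' Total absolute correlation of a neighborhood
#'
#' The sphere-of-influence observed statistic `C_i(r)`: the sum of absolute
#' Spearman correlations between the center gene and the genes in its
#' neighborhood. An empty neighborhood has total 0.
#'
#' @param profile named numeric vector of correlations (from
#'   [spearman_profile()]; must not contain the center gene).
#' @param nbhd character vector of gene ids within the radius.
#' @return non-negative scalar.
#' @export
total_abs_correlation <- function(profile, nbhd) {
  if (length(nbhd) == 0L) return(0)
  missing_ids <- setdiff(nbhd, names(profile))
  if (length(missing_ids)) {
    stop(sprintf("neighborhood gene(s) absent from profile: %s",
                 paste(utils::head(missing_ids, 5L), collapse = ", ")))
  }
  sum(abs(profile[nbhd]))
}

#' Resampled null totals for the sphere-of-influence test
#'
#' The competitive null: what would the total absolute correlation of a
#' neighborhood of size `n_r` look like if it were a random set of genes?
#' Each null value is the sum of `n_r` draws with replacement from the center
#' gene's own pool of absolute correlations with every other assayed
#' on-network gene.
#'
#' @param profile named numeric vector of correlations (center excluded).
#' @param n_r neighborhood size (>= 1).
#' @param B number of resamplings (default 1000).
#' @param seed optional integer for reproducibility.
#' @return numeric vector of `B` null totals.
#' @export
sphere_null <- function(profile, n_r, B = 1000L, seed = NULL) {
  if (length(profile) == 0L) stop("empty correlation profile")
  if (n_r < 1L) stop("n_r must be >= 1")
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pool <- abs(profile)
  draws <- sample(pool, n_r * B, replace = TRUE)
  colSums(matrix(draws, nrow = n_r, ncol = B))
}

#' Sphere-of-influence p-value curve for one gene
#'
#' For each radius r, compares the observed total absolute correlation
#' `C_i(r)` over the assayed neighborhood against `B` resampled null totals
#' of the same size. Upper-tail empirical p-values use the add-one estimator
#' `(1 + #{null >= observed}) / (B + 1)`, so p is never exactly 0. Radii with
#' an empty assayed neighborhood get p = 1.
#'
#' @param profile named numeric vector from [spearman_profile()], restricted
#'   to assayed on-network genes (the resampling pool).
#' @param oracle a `distance_oracle`.
#' @param i center gene id.
#' @param radii integer radii to evaluate (default `1:diameter`).
#' @param B number of resamplings.
#' @param seed optional integer; one seeded stream drives all radii of this
#'   gene.
#' @return a data frame of class `sphere_result` with columns `radius`,
#'   `n_neighbors` (assayed), `C_obs`, `p_sphere`; attribute `B`.
#' @export
sphere_pvalue_curve <- function(profile, oracle, i, radii = NULL,
                                B = 1000L, seed = NULL) {
  if (length(profile) == 0L) stop("empty correlation profile")
  if (is.null(radii)) radii <- seq_len(oracle$diameter)
  if (!is.null(seed)) set.seed(seed)
  pool <- abs(profile)
  assayed <- names(profile)
  di <- oracle$d[i, ]
  out <- data.frame(radius = as.integer(radii), n_neighbors = 0L,
                    C_obs = 0, p_sphere = 1)
  for (k in seq_along(radii)) {
    r <- radii[k]
    nbhd <- intersect(names(di)[di > 0L & di <= r], assayed)
    n_r <- length(nbhd)
    out$n_neighbors[k] <- n_r
    if (n_r == 0L) next
    C_obs <- sum(pool[nbhd])
    nulls <- colSums(matrix(sample(pool, n_r * B, replace = TRUE),
                            nrow = n_r, ncol = B))
    out$C_obs[k] <- C_obs
    out$p_sphere[k] <- (1 + sum(nulls >= C_obs)) / (B + 1)
  }
  attr(out, "B") <- as.integer(B)
  attr(out, "gene") <- i
  class(out) <- c("sphere_result", "data.frame")
  out
}
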