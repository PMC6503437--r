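#' Two-class expression studies
#'
#' An `expression_study` bundles a genes-by-samples expression matrix with a
#' binary phenotype label per sample. Gene ids must be unique and each
#' phenotype class needs at least two samples (the differential-expression
#' t-statistic is undefined otherwise).
#'
#' @param exprs numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param phenotype factor/character/vector of length `ncol(exprs)` with
#'   exactly two levels, or a named vector matched to colnames.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(exprs, phenotype) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs)) stop("expression matrix must be numeric")
  if (is.null(rownames(exprs))) stop("expression matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(exprs))) {
    dup <- unique(rownames(exprs)[duplicated(rownames(exprs))])
    stop(sprintf("duplicate gene ids: %s", paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (is.null(colnames(exprs))) {
    colnames(exprs) <- paste0("S", seq_len(ncol(exprs)))
  }
  if (!is.null(names(phenotype))) {
    missing_ids <- setdiff(colnames(exprs), names(phenotype))
    if (length(missing_ids)) {
      stop(sprintf("phenotype missing for sample(s): %s",
                   paste(missing_ids, collapse = ", ")))
    }
    phenotype <- phenotype[colnames(exprs)]
  }
  if (length(phenotype) != ncol(exprs)) {
    stop("phenotype length must equal the number of samples")
  }
  phenotype <- factor(as.character(phenotype))
  if (nlevels(phenotype) != 2L) {
    stop(sprintf("phenotype must have exactly 2 classes (got %d)", nlevels(phenotype)))
  }
  if (any(table(phenotype) < 2L)) {
    stop("each phenotype class needs at least 2 samples")
  }
  structure(list(exprs = exprs, phenotype = phenotype),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$phenotype)
  cat(sprintf("<expression_study> %d genes x %d samples (%s: %d, %s: %d)%s\n",
              nrow(x$exprs), ncol(x$exprs),
              names(tab)[1L], tab[1L], names(tab)[2L], tab[2L],
              if (anyNA(x$exprs)) sprintf(", %d NA cells", sum(is.na(x$exprs))) else ""))
  invisible(x)
}

#' @rdname expression_study
#' @param study an `expression_study`.
#' @export
study_genes <- function(study) rownames(study$exprs)

# Midrank (average-rank) transform of each gene row; the shared backbone of
# all Spearman computations in the package.
rank_rows <- function(exprs) {
  t(apply(exprs, 1L, rank))
}

#' Spearman correlation profile of one gene
#'
#' Spearman rank correlation between gene `i` and every other gene, computed
#' on all samples pooled (the sphere-of-influence test is phenotype-
#' independent). Ties are midranked. A zero-variance gene has no defined rank
#' correlation; its entries are set to 0 with a warning rather than dropped,
#' so neighborhood sizes stay comparable across genes.
#'
#' @param study an `expression_study` (complete data; impute first if needed).
#' @param i center gene id.
#' @param genes optional character vector: the universe of genes to correlate
#'   against (defaults to all genes in the study). `i` is always excluded.
#' @return named numeric vector of correlations in `[-1, 1]`.
#' @export
spearman_profile <- function(study, i, genes = NULL) {
  if (is.null(genes)) genes <- study_genes(study)
  if (!i %in% study_genes(study)) stop(sprintf("gene '%s' not assayed", i))
  genes <- setdiff(genes, i)
  x <- study$exprs[i, ]
  if (ncol(study$exprs) < 3L) stop("need at least 3 samples")
  if (anyNA(study$exprs[c(i, genes), ])) {
    stop("missing values present; run filter_missing() first")
  }
  mat <- study$exprs[genes, , drop = FALSE]
  rho <- drop(suppressWarnings(cor(rank(x), t(rank_rows(mat)), method = "pearson")))
  bad <- !is.finite(rho)
  if (any(bad)) {
    warning(sprintf("%d zero-variance gene(s); their correlations set to 0", sum(bad)))
    rho[bad] <- 0
  }
  if (sd(x) == 0) {
    warning(sprintf("center gene '%s' has zero variance; profile set to 0", i))
    rho[] <- 0
  }
  setNames(as.numeric(rho), genes)
}

# Full Spearman correlation matrix over a gene set (midrank-then-Pearson).
# Used by the pipeline so each gene's profile is a row lookup, not a re-scan.
spearman_matrix <- function(study, genes = NULL) {
  if (is.null(genes)) genes <- study_genes(study)
  mat <- study$exprs[genes, , drop = FALSE]
  if (anyNA(mat)) stop("missing values present; run filter_missing() first")
  rk <- rank_rows(mat)
  rho <- suppressWarnings(cor(t(rk), method = "pearson"))
  nvar <- apply(mat, 1L, sd) == 0
  if (any(nvar)) {
    warning(sprintf("%d zero-variance gene(s); their correlations set to 0", sum(nvar)))
    rho[nvar, ] <- 0
    rho[, nvar] <- 0
  }
  diag(rho) <- 1
  dimnames(rho) <- list(genes, genes)
  rho
}

# Vectorised two-sample t over all gene rows at once. Welch by default;
# var.equal = TRUE gives the pooled-variance variant.
welch_t_rows <- function(exprs, labels, var.equal = FALSE) {
  labels <- as.factor(labels)
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  x1 <- exprs[, g1, drop = FALSE]; x2 <- exprs[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var.equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, nrow(exprs))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  zero_var <- se2 == 0
  if (any(zero_var)) {
    # constant within both groups: no evidence if means agree, infinite
    # separation otherwise
    t[zero_var] <- ifelse(m1[zero_var] == m2[zero_var], 0,
                          sign(m1 - m2)[zero_var] * Inf)
    df[zero_var] <- n1 + n2 - 2
  }
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Per-gene differential-expression statistics
#'
#' The gene-level association magnitude `g_j` used by the decay-of-
#' differential-expression test: the absolute two-sample t statistic
#' (Welch by default), plus its two-sided p-value for reporting and
#' cross-study concordance.
#'
#' @param study an `expression_study`.
#' @param var.equal use the pooled-variance t instead of Welch.
#' @return a data frame with columns `gene`, `t`, `g` (= `|t|`), `p_de`.
#' @export
de_statistic <- function(study, var.equal = FALSE) {
  if (anyNA(study$exprs)) stop("missing values present; run filter_missing() first")
  res <- welch_t_rows(study$exprs, study$phenotype, var.equal = var.equal)
  if (any(res$t == 0 & res$p == 1 &
          apply(study$exprs, 1L, function(z) all(z == z[1L])))) {
    warning("zero-variance gene(s) present; their g statistic set to 0")
  }
  data.frame(gene = study_genes(study), t = res$t, g = abs(res$t),
             p_de = res$p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Permute phenotype labels
#'
#' Returns the same study with the phenotype labels randomly rearranged:
#' class sizes are preserved and the expression matrix is untouched, so all
#' inter-gene correlations survive — the self-contained null of the decay
#' test.
#'
#' @param study an `expression_study`.
#' @param seed optional integer; if given, `set.seed(seed)` is called so the
#'   permutation is reproducible.
#' @return an `expression_study` with permuted labels.
#' @export
permute_labels <- function(study, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  study$phenotype <- study$phenotype[sample.int(length(study$phenotype))]
  study
}

# B permuted label vectors -> matrix of permuted |t| statistics
# (genes x B). Drawn once per run and shared across all center genes and all
# radii: each column is one full label permutation, so every marginal null is
# exactly the single-gene permutation null.
permuted_de_matrix <- function(study, B, seed = NULL, var.equal = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(study$phenotype)
  out <- matrix(NA_real_, nrow = nrow(study$exprs), ncol = B,
                dimnames = list(study_genes(study), NULL))
  for (b in seq_len(B)) {
    lab <- study$phenotype[sample.int(n)]
    out[, b] <- abs(welch_t_rows(study$exprs, lab, var.equal = var.equal)$t)
  }
  out
}
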