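#' Read an expression study from delimited text
#'
#' The expression file is tab-delimited with a header: first column gene id,
#' remaining columns one per sample. The phenotype file has two columns
#' (sample id, class label) with a header. Samples are matched by id; every
#' expression sample must have a phenotype and vice versa. Missing cells may
#' be `NA` or empty.
#'
#' @param expr_path path to the expression matrix file.
#' @param pheno_path path to the phenotype file.
#' @return an `expression_study` (possibly with NAs; see
#'   [filter_missing()]).
#' @export
load_study <- function(expr_path, pheno_path) {
  for (p in c(expr_path, pheno_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  expr <- read.table(expr_path, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(expr) < 2L) stop("expression file needs a gene-id column plus samples")
  ids <- as.character(expr[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate gene ids in %s: %s", expr_path,
                 paste(utils::head(dup, 5L), collapse = ", ")))
  }
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!vapply(as.data.frame(mat), is.numeric, TRUE)]
    stop(sprintf("non-numeric expression values in column(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  rownames(mat) <- ids

  pheno <- read.table(pheno_path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(pheno) < 2L) stop("phenotype file needs (sample id, class) columns")
  labels <- setNames(as.character(pheno[[2L]]), as.character(pheno[[1L]]))

  unmatched <- setdiff(colnames(mat), names(labels))
  if (length(unmatched)) {
    stop(sprintf("sample(s) missing from phenotype file: %s",
                 paste(unmatched, collapse = ", ")))
  }
  extra <- setdiff(names(labels), colnames(mat))
  if (length(extra)) {
    stop(sprintf("phenotype sample(s) missing from expression file: %s",
                 paste(extra, collapse = ", ")))
  }
  expression_study(mat, labels)
}

#' Write an expression study as delimited text
#' @param study an `expression_study`.
#' @param expr_path,pheno_path output paths.
#' @export
write_study <- function(study, expr_path, pheno_path) {
  df <- data.frame(gene = study_genes(study), study$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample = colnames(study$exprs),
                   class = as.character(study$phenotype))
  write.table(ph, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, pheno_path))
}

#' Filter genes and samples with excessive missingness
#'
#' Drops genes whose fraction of missing values exceeds `gene_thresh`, then
#' samples whose missing fraction (over the surviving genes) exceeds
#' `sample_thresh` — gene filter first, and order matters. Any missing
#' values that survive are imputed by the gene-wise median
#' (`impute = "median"`, the default) or left in place
#' (`impute = "none"`, in which case downstream analyses will refuse to
#' run until the data are complete).
#'
#' @param study an `expression_study`.
#' @param gene_thresh,sample_thresh maximum tolerated missing fraction,
#'   in `[0, 1)` (default 0.25 each).
#' @param impute `"median"` or `"none"`.
#' @return a filtered (and possibly imputed) `expression_study`.
#' @export
filter_missing <- function(study, gene_thresh = 0.25, sample_thresh = 0.25,
                           impute = c("median", "none")) {
  impute <- match.arg(impute)
  stopifnot(gene_thresh >= 0, gene_thresh < 1,
            sample_thresh >= 0, sample_thresh < 1)
  x <- study$exprs
  keep_g <- rowMeans(is.na(x)) <= gene_thresh
  if (!any(keep_g)) stop("all genes exceed the missingness threshold")
  x <- x[keep_g, , drop = FALSE]
  keep_s <- colMeans(is.na(x)) <= sample_thresh
  if (sum(keep_s) < 4L) stop("fewer than 4 samples survive the missingness filter")
  x <- x[, keep_s, drop = FALSE]
  pheno <- study$phenotype[keep_s]
  if (impute == "median" && anyNA(x)) {
    med <- apply(x, 1L, median, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- med[idx[, 1L]]
  }
  expression_study(x, setNames(pheno, colnames(x)))
}

#' Restrict a study and network to each other
#'
#' The scored gene universe is the intersection of the assayed genes and the
#' network's largest connected component. The returned network keeps its
#' unassayed nodes — they still carry geodesic distance — but records the
#' assayed subset; the returned study is cut down to the scored genes.
#'
#' @param study an `expression_study`.
#' @param net a `gene_network`.
#' @return list with elements `study` (subset) and `network` (LCC with
#'   `assayed` set).
#' @export
restrict_to_network <- function(study, net) {
  lcc <- largest_connected_component(net)
  scored <- intersect(study_genes(study), network_nodes(lcc))
  if (length(scored) == 0L) {
    stop("no assayed genes on the network component (check identifier harmonization)")
  }
  lcc$assayed <- scored
  sub <- study
  sub$exprs <- study$exprs[scored, , drop = FALSE]
  list(study = sub, network = lcc)
}

#' Assemble and validate a pipeline configuration
#'
#' @param expr,pheno,network input file paths.
#' @param out_dir output directory.
#' @param b_sphere,b_decay resampling / permutation counts (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer master seed (default 17).
#' @param missing_thresh missingness threshold applied to both genes and
#'   samples (default 0.25).
#' @param genes optional character vector of genes to score.
#' @param var_equal pooled-variance t instead of Welch.
#' @return a validated `run_config` list.
#' @export
run_config <- function(expr, pheno, network, out_dir = ".",
                       b_sphere = 1000L, b_decay = 1000L, alpha = 0.05,
                       seed = 17L, missing_thresh = 0.25, genes = NULL,
                       var_equal = FALSE) {
  stopifnot(b_sphere >= 1, b_decay >= 1, alpha > 0, alpha < 1,
            missing_thresh >= 0, missing_thresh < 1)
  structure(list(expr = expr, pheno = pheno, network = network,
                 out_dir = out_dir, b_sphere = as.integer(b_sphere),
                 b_decay = as.integer(b_decay), alpha = alpha,
                 seed = as.integer(seed), missing_thresh = missing_thresh,
                 genes = genes, var_equal = isTRUE(var_equal)),
            class = "run_config")
}

#' Run the end-to-end file pipeline
#'
#' load -> missingness filter -> restrict to network -> radius-scan scoring
#' -> ranked `results.csv` + per-radius `curves.csv` + `run_log.txt` in
#' `out_dir`. Fully deterministic under the config seed. Errors from any
#' stage are re-signalled with the stage name prefixed.
#'
#' @param config a [run_config()].
#' @param verbose print progress.
#' @return the `gs_fit` object, invisibly.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  study <- stage("load", load_study(config$expr, config$pheno))
  net <- stage("load", read_network(config$network))
  study <- stage("filter", filter_missing(study, config$missing_thresh,
                                          config$missing_thresh))
  fit <- stage("score", gene_surrounder(
    study, net, B_sphere = config$b_sphere, B_decay = config$b_decay,
    alpha = config$alpha, seed = config$seed, genes = config$genes,
    var.equal = config$var_equal, verbose = verbose))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(config$out_dir, "results.csv")
  curves_path <- file.path(config$out_dir, "curves.csv")
  write_results(fit, res_path, curves_path)
  s <- fit$stats
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("B_sphere: %d", s$B_sphere),
    sprintf("B_decay: %d", s$B_decay),
    sprintf("network nodes: %d", s$nodes),
    sprintf("network edges: %d", s$edges),
    sprintf("network diameter: %d", s$diameter),
    sprintf("scored genes: %d", s$n_scored),
    sprintf("alpha: %g", s$alpha),
    sprintf("-log10 Bonferroni threshold (alpha/D): %.4f", s$neglog10_threshold),
    sprintf("significant genes: %d", sum(fit$results$significant)),
    sprintf("smallest attainable p_comb at these B: %.6g",
            fisher_combine(1 / (s$B_sphere + 1), 1 / (s$B_decay + 1))$p_comb)
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  if (verbose) message(paste(log_lines, collapse = "\n"))
  invisible(fit)
}

#' Write ranked results and per-radius diagnostics as CSV
#'
#' P-values are written in full precision; the ranked table also carries the
#' `-log10(p_GS)` column commonly used for reporting.
#'
#' @param fit a `gs_fit` from [gene_surrounder()].
#' @param results_path output CSV for the ranked table.
#' @param curves_path optional output CSV for the per-gene per-radius
#'   diagnostics.
#' @export
write_results <- function(fit, results_path, curves_path = NULL) {
  write.csv(fit$results, results_path, row.names = FALSE, quote = FALSE)
  if (!is.null(curves_path)) {
    write.csv(fit$curves, curves_path, row.names = FALSE, quote = FALSE)
  }
  invisible(results_path)
}
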