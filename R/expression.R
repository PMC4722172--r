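#' Preprocess an RNA-seq count matrix into a normalized expression matrix
#'
#' Applies the standard preparation chain for coexpression analysis:
#' (1) drop low-quality runs whose total mapped count falls below
#' `min_total_mapped`; (2) drop consistently low genes whose highest count
#' across the surviving runs falls below `min_peak_count`; (3) transform to
#' `log2(count + pseudocount)`; (4) quantile-normalize the runs within each
#' experiment; (5) mean-center each gene over all surviving runs.
#'
#' @param counts Non-negative integer matrix, genes in rows, sequencing runs
#'   in columns, with unique row and column names.
#' @param experiments Optional character vector naming the experiment of each
#'   run, either named by run id or in column order. `NULL` treats all runs as
#'   one experiment.
#' @param min_total_mapped Runs with column sum below this are removed
#'   (default 1e7 mapped reads).
#' @param min_peak_count Genes whose maximum count over surviving runs is
#'   below this are removed (default 100).
#' @param pseudocount Positive offset added before the base-2 logarithm
#'   (default 0.125, so an unobserved gene maps to -3).
#' @param quantile_normalize,center Logical switches for steps (4) and (5);
#'   both default `TRUE`. Disabling them exposes the raw log scale, mainly
#'   for diagnostics.
#' @return Numeric matrix of centered log2 expression (surviving genes x
#'   surviving runs) with attribute `"experiments"` carrying the run ->
#'   experiment assignment of the surviving runs.
#' @examples
#' cnt <- matrix(rpois(60, 2e6), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), paste0("r", 1:20)))
#' expr <- preprocess_counts(cnt, min_total_mapped = 0, min_peak_count = 0)
#' rowMeans(expr)  # ~0
#' @export
preprocess_counts <- function(counts, experiments = NULL,
                              min_total_mapped = 1e7,
                              min_peak_count = 100,
                              pseudocount = 0.125,
                              quantile_normalize = TRUE,
                              center = TRUE) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("'counts' is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and run column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in 'counts'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate run ids in 'counts'")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be > 0")

  experiments <- .resolve_experiments(experiments, colnames(counts))

  keep_run <- colSums(counts) >= min_total_mapped
  if (!any(keep_run))
    stop("all runs removed by the total mapped count filter (< ",
         format(min_total_mapped, scientific = FALSE), ")")
  counts <- counts[, keep_run, drop = FALSE]
  experiments <- experiments[keep_run]

  keep_gene <- apply(counts, 1L, max) >= min_peak_count
  if (!any(keep_gene))
    stop("all genes removed by the peak count filter (< ", min_peak_count, ")")
  counts <- counts[keep_gene, , drop = FALSE]

  expr <- log2(counts + pseudocount)

  if (quantile_normalize) {
    for (ex in unique(experiments)) {
      idx <- which(experiments == ex)
      expr[, idx] <- limma::normalizeQuantiles(expr[, idx, drop = FALSE],
                                               ties = FALSE)
    }
  }
  if (center) expr <- expr - rowMeans(expr)

  attr(expr, "experiments") <- experiments
  expr
}

.resolve_experiments <- function(experiments, run_ids) {
  if (is.null(experiments))
    return(stats::setNames(rep("experiment1", length(run_ids)), run_ids))
  experiments <- as.character(stats::setNames(experiments, names(experiments)))
  if (!is.null(names(experiments))) {
    if (!all(run_ids %in% names(experiments)))
      stop("missing experiment assignment for runs: ",
           paste(setdiff(run_ids, names(experiments)), collapse = ", "))
    experiments <- experiments[run_ids]
  } else {
    if (length(experiments) != length(run_ids))
      stop("'experiments' must be named by run id or match the run count")
    names(experiments) <- run_ids
  }
  experiments
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlates every pair of gene rows of an expression matrix. An optional
#' non-negative per-sample weight vector switches to the weighted Pearson
#' correlation (weighted means/covariances via [stats::cov.wt()]).
#' Zero-variance genes cannot be correlated and are dropped with a warning.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param sample_weights Optional numeric vector of non-negative weights, one
#'   per sample (column).
#' @return Symmetric correlation matrix with unit diagonal over the retained
#'   genes.
#' @export
correlation_matrix <- function(expr, sample_weights = NULL) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance genes: ",
            paste(rownames(expr)[v == 0], collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("fewer than 2 genes with nonzero variance")
  if (is.null(sample_weights)) {
    cc <- stats::cor(t(expr))
  } else {
    if (length(sample_weights) != ncol(expr) || any(sample_weights < 0))
      stop("'sample_weights' must be non-negative, one per sample")
    cc <- stats::cov.wt(t(expr), wt = sample_weights, cor = TRUE)$cor
    dimnames(cc) <- list(rownames(expr), rownames(expr))
  }
  cc
}

#' Convert a correlation matrix to a Mutual Rank coexpression table
#'
#' For each ordered gene pair (a, b), `rank_a(b)` is the rank of b among all
#' genes other than a, sorted by descending correlation with a (best = 1,
#' ties averaged). The Mutual Rank is the geometric mean
#' `MR(a, b) = sqrt(rank_a(b) * rank_b(a))`; low MR means strong, mutual
#' coexpression. MR is rank-based, so any strictly monotone transformation of
#' a gene's correlation profile leaves it unchanged.
#'
#' @param corr Symmetric numeric correlation-like matrix for >= 3 genes.
#' @return Symmetric matrix of MR values in `[1, n - 1]`, diagonal `NA` (a
#'   gene has no rank against itself).
#' @examples
#' cc <- rbind(c(1, .9, .5), c(.9, 1, .8), c(.5, .8, 1))
#' dimnames(cc) <- list(LETTERS[1:3], LETTERS[1:3])
#' mutual_rank(cc)  # MR(A,C) = 2, MR(B,C) = sqrt(2)
#' @export
mutual_rank <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) < 3L) stop("need at least 3 genes")
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("'corr' must be symmetric")
  cm <- corr
  diag(cm) <- NA_real_
  rk <- t(apply(-cm, 1L, rank, na.last = "keep"))
  mr <- sqrt(rk * t(rk))
  diag(mr) <- NA_real_
  dimnames(mr) <- dimnames(corr)
  mr
}

#' One-call pipeline from counts to a Mutual Rank table
#'
#' Convenience wrapper chaining [preprocess_counts()], [correlation_matrix()]
#' and [mutual_rank()].
#'
#' @inheritParams preprocess_counts
#' @param sample_weights Optional per-run weights forwarded to
#'   [correlation_matrix()] (runs removed by the quality filter are dropped
#'   from the weight vector by run id).
#' @param ... Further arguments to [preprocess_counts()].
#' @return Mutual Rank matrix (see [mutual_rank()]).
#' @export
coexpression_table <- function(counts, experiments = NULL,
                               sample_weights = NULL, ...) {
  expr <- preprocess_counts(counts, experiments = experiments, ...)
  if (!is.null(sample_weights) && !is.null(names(sample_weights)))
    sample_weights <- sample_weights[colnames(expr)]
  mutual_rank(correlation_matrix(expr, sample_weights = sample_weights))
}
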