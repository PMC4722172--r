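#' Published ATTED-II v8.0 dataset quality scores
#'
#' The score tables released with ATTED-II version 8.0: per-dataset codon
#' and reproducibility scores for the 14 coexpression datasets
#' (`"datasets"`), and the GO / codon / reproducibility scores across the
#' historical Arabidopsis dataset versions (`"arabidopsis_versions"`).
#' Scores are on their reporting scales: GO score in 1E-04 units (partial
#' AUC at FPR 0.01 x 1e4), codon score in 1E-02 units (median COXSIM x
#' 100), reproducibility score in 1E-01 units (median normalized maxCOXSIM
#' x 10). Bundled as plain-text reference data for cross-score concordance
#' analysis; `Mtr-m` has no reproducibility score (it was excluded from the
#' parallel view).
#'
#' @param which `"datasets"` or `"arabidopsis_versions"`.
#' @return `data.frame` of the requested table.
#' @export
atted_published_scores <- function(which = c("datasets",
                                             "arabidopsis_versions")) {
  which <- match.arg(which)
  fn <- switch(which,
               datasets = "atted_v8_dataset_scores.tsv",
               arabidopsis_versions = "atted_ath_version_scores.tsv")
  path <- system.file("extdata", fn, package = "coexkit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Cross-score concordance of dataset quality scores
#'
#' Pearson correlation between each pair of quality-score columns present in
#' a score table, over the rows where both scores are available. High
#' concordance between independent scores (annotation-based GO score,
#' annotation-free codon score, cross-dataset reproducibility score)
#' supports all of them as measures of coexpression data quality.
#'
#' @param scores `data.frame` with any subset of the columns `go_score`,
#'   `codon_score`, `reproducibility_score` (e.g. from
#'   [atted_published_scores()]).
#' @return Named numeric vector of correlations, one entry per score pair
#'   present (names like `"go_codon"`), with attribute `"n"` giving the row
#'   counts used.
#' @export
score_concordance <- function(scores) {
  cols <- intersect(c("go_score", "codon_score", "reproducibility_score"),
                    names(scores))
  if (length(cols) < 2L) stop("need at least two score columns")
  short <- c(go_score = "go", codon_score = "codon",
             reproducibility_score = "reproducibility")
  out <- numeric(0); ns <- integer(0)
  for (i in seq_len(length(cols) - 1L)) for (j in seq((i + 1L), length(cols))) {
    ok <- stats::complete.cases(scores[, c(cols[i], cols[j])])
    nm <- paste(short[cols[i]], short[cols[j]], sep = "_")
    out[nm] <- stats::cor(scores[[cols[i]]][ok], scores[[cols[j]]][ok])
    ns[nm] <- sum(ok)
  }
  attr(out, "n") <- ns
  out
}
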