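#' Read a gene-by-run count matrix from TSV
#'
#' Layout: first column gene id, header row of run ids. An optional second
#' header line whose first field is `#experiment` maps runs to experiment
#' ids in-file; alternatively supply a run-metadata TSV with columns
#' `run_id` and `experiment_id`.
#'
#' @param path Count matrix TSV path.
#' @param run_meta Optional run-metadata TSV path.
#' @return Integer matrix (genes x runs) with attribute `"experiments"`
#'   (named run -> experiment vector) when metadata was available.
#' @export
read_count_matrix <- function(path, run_meta = NULL) {
  head2 <- readLines(path, n = 2L)
  experiments <- NULL
  skip_expt <- length(head2) > 1L && grepl("^#experiment\t", head2[2L])
  header <- strsplit(head2[1L], "\t", fixed = TRUE)[[1L]]
  runs <- header[-1L]
  if (skip_expt) {
    ex <- strsplit(head2[2L], "\t", fixed = TRUE)[[1L]][-1L]
    experiments <- stats::setNames(ex, runs)
  }
  df <- utils::read.delim(path, skip = if (skip_expt) 2L else 1L,
                          header = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(df[[1L]], runs)
  storage.mode(m) <- "integer"
  if (!is.null(run_meta)) {
    meta <- utils::read.delim(run_meta, stringsAsFactors = FALSE)
    if (!all(c("run_id", "experiment_id") %in% names(meta)))
      stop("run metadata needs columns run_id and experiment_id")
    experiments <- stats::setNames(meta$experiment_id, meta$run_id)
  }
  attr(m, "experiments") <- experiments
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Count matrix (genes x runs).
#' @param path Output path.
#' @param experiments Optional run -> experiment vector written as a second
#'   `#experiment` header line.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, experiments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  if (!is.null(experiments))
    writeLines(paste(c("#experiment",
                       unname(experiments[colnames(counts)])),
                     collapse = "\t"), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read a gene x gene numeric matrix (MR table, expression table) from TSV
#'
#' Layout matches coexpression-table bulk downloads: gene ids in the first
#' row and first column.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene dimnames.
#' @export
read_mr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene x gene numeric matrix to TSV
#'
#' @param mr Numeric matrix with gene dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_table <- function(mr, path) {
  df <- data.frame(gene_id = rownames(mr), mr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene correspondence map from TSV
#'
#' @param path TSV path with columns source gene, target gene (header
#'   optional).
#' @return Named character vector source -> target; duplicated source genes
#'   keep the first record.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1L, 1L]) %in% c("source", "source_gene", "gene", "from"))
    df <- df[-1L, , drop = FALSE]
  df <- df[!duplicated(df[[1L]]), , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read gene -> GO annotations from a two-column TSV
#'
#' Compatible with a gene2go-like subset: the gene id and term id columns
#' may be named `gene`/`term`, `GeneID`/`GO_ID`, or simply be the first two
#' columns.
#'
#' @param path TSV path.
#' @return `data.frame(gene, term)`.
#' @export
read_go_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(cands, default) {
    hit <- intersect(cands, names(df))
    if (length(hit) > 0L) hit[1L] else names(df)[default]
  }
  g <- pick(c("gene", "gene_id", "GeneID"), 1L)
  t <- pick(c("term", "term_id", "GO_ID"), 2L)
  out <- data.frame(gene = as.character(df[[g]]),
                    term = as.character(df[[t]]),
                    stringsAsFactors = FALSE)
  unique(out)
}
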