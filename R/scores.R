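#' The 61 sense codons (stop codons TAA, TAG, TGA excluded)
#' @export
SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

#' Codon usage vector of a coding sequence
#'
#' Counts non-overlapping in-frame triplets from position 1 of the CDS over
#' the 61 sense codons; the three stop codons are excluded from the vector.
#' A trailing partial codon is dropped with a warning; codons containing
#' ambiguous bases are skipped with a warning.
#'
#' @param cds Character string or [Biostrings::DNAString] over {A,C,G,T}
#'   (ambiguity codes tolerated but skipped), length >= 3.
#' @return Named integer vector of length 61 (names = [SENSE_CODONS]).
#' @examples
#' codon_usage("ATGAAATAA")  # ATG:1, AAA:1; the stop TAA is not counted
#' @export
codon_usage <- function(cds) {
  s <- toupper(as.character(cds))
  L <- nchar(s)
  if (L < 3L) stop("CDS shorter than one codon")
  if (L %% 3L != 0L) {
    warning("CDS length ", L, " not a multiple of 3; trailing partial codon dropped")
    s <- substr(s, 1L, L - L %% 3L)
  }
  cnt <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(s), step = 3L)
  n_codons <- nchar(s) / 3L
  n_stop <- sum(cnt[c("TAA", "TAG", "TGA")])
  if (sum(cnt) < n_codons)
    warning(n_codons - sum(cnt), " codon(s) with ambiguous bases skipped")
  out <- cnt[SENSE_CODONS]
  storage.mode(out) <- "integer"
  out
}

#' Codon usage matrix for a set of genes
#'
#' One 61-dimensional codon usage vector per gene. Record names are parsed to
#' gene ids by their first whitespace-separated token; when several sequences
#' (isoforms) share a gene id, the longest sequence is used.
#'
#' @param cds [Biostrings::DNAStringSet] (or named character vector) of
#'   coding sequences.
#' @return Integer matrix, genes x 61 codons.
#' @export
codon_usage_matrix <- function(cds) {
  if (!methods::is(cds, "DNAStringSet"))
    cds <- Biostrings::DNAStringSet(cds)
  if (is.null(names(cds))) stop("CDS records must be named")
  gene <- sub("\\s.*$", "", names(cds))
  len <- Biostrings::width(cds)
  ord <- order(gene, -len)
  keep <- ord[!duplicated(gene[ord])]   # longest sequence per gene
  cds <- cds[keep]; gene <- gene[keep]
  m <- t(vapply(seq_along(cds), function(i) codon_usage(cds[[i]]),
                integer(length(SENSE_CODONS))))
  dimnames(m) <- list(gene, SENSE_CODONS)
  m[order(rownames(m)), , drop = FALSE]
}

#' Codon usage similarity table (MR of codon-usage correlations)
#'
#' Pearson-correlates the 61-dimensional codon usage vectors of every gene
#' pair and converts the correlations to Mutual Ranks, giving a codon
#' similarity table in the same format and units as a coexpression table.
#'
#' @param usage Codon usage matrix from [codon_usage_matrix()] (genes x 61).
#' @return Mutual Rank matrix (see [mutual_rank()]). Genes with constant
#'   codon vectors are excluded with a warning.
#' @export
codon_mr_table <- function(usage) {
  if (nrow(usage) < 3L) stop("need at least 3 genes")
  mutual_rank(correlation_matrix(usage))
}

#' Codon score of a coexpression dataset
#'
#' For every guide gene, COXSIM (identity correspondence, k = top
#' `k_fraction`) between the guide's coexpressed gene list and its codon
#' similarity list; the dataset score is the median COXSIM, reported in
#' 1E-02 units (median x 100). Agreement with annotation-free codon usage is
#' a quality proxy available for any species.
#'
#' @param coex Coexpression MR table.
#' @param codon Codon similarity MR table ([codon_mr_table()]).
#' @param k_fraction Prefix-depth fraction (default 0.01).
#' @return Numeric score (1E-02 units).
#' @export
codon_score <- function(coex, codon, k_fraction = 0.01) {
  shared <- intersect(rownames(coex), rownames(codon))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  if (length(shared) < 10L)
    warning("fewer than 10 guide genes; the median is unstable")
  vals <- vapply(shared, function(g) {
    lg <- .restricted_list(coex, g, shared)
    lr <- .restricted_list(codon, g, shared)
    k <- max(1L, ceiling(k_fraction * length(lg$genes)))
    as.numeric(coxsim(lg, lr, k = k))
  }, numeric(1))
  100 * stats::median(vals)
}

#' Select GO terms of intermediate size
#'
#' Keeps terms annotating between `min_genes` and `max_genes` genes
#' (inclusive) within the dataset's gene universe — a size window that holds
#' the information content of the selected terms roughly comparable.
#'
#' @param annotations `data.frame(gene, term)` of gene -> GO term links.
#' @param universe Gene ids of the dataset (annotations outside it are
#'   ignored); `NULL` uses all annotated genes.
#' @param min_genes,max_genes Inclusive size window (defaults 5 and 20).
#' @return Character vector of selected term ids.
#' @export
select_go_terms <- function(annotations, universe = NULL,
                            min_genes = 5L, max_genes = 20L) {
  ann <- unique(as.data.frame(annotations)[, c("gene", "term")])
  if (!is.null(universe)) ann <- ann[ann$gene %in% universe, , drop = FALSE]
  if (nrow(ann) == 0L) return(character(0))
  sizes <- table(ann$term)
  sort(names(sizes)[sizes >= min_genes & sizes <= max_genes])
}

#' GO score: partial ROC AUC of functional-pair prediction
#'
#' Over all unordered pairs of annotated genes (genes carrying at least one
#' selected GO term), a pair is positive iff the two genes share a selected
#' term. Pairs are ranked by ascending MR (strong coexpression first) and the
#' partial area under the ROC curve for false-positive rate in
#' `[0, fpr_cap]` is computed, unnormalized (maximum = `fpr_cap`), and
#' reported in 1E-04 units.
#'
#' @param coex Coexpression MR table.
#' @param annotations `data.frame(gene, term)`.
#' @param fpr_cap False-positive-rate cap (default 0.01).
#' @param min_genes,max_genes Term-size window for [select_go_terms()].
#' @return Numeric score (1E-04 units).
#' @export
go_score <- function(coex, annotations, fpr_cap = 0.01,
                     min_genes = 5L, max_genes = 20L) {
  terms <- select_go_terms(annotations, rownames(coex), min_genes, max_genes)
  if (length(terms) == 0L) stop("no GO terms in the size window")
  ann <- unique(as.data.frame(annotations)[, c("gene", "term")])
  ann <- ann[ann$term %in% terms & ann$gene %in% rownames(coex), ]
  genes <- sort(unique(ann$gene))
  if (length(genes) < 2L) stop("fewer than 2 annotated genes")
  inc <- matrix(FALSE, length(genes), length(terms),
                dimnames = list(genes, terms))
  inc[cbind(match(ann$gene, genes), match(ann$term, terms))] <- TRUE
  share <- tcrossprod(inc) > 0
  pr <- which(upper.tri(share), arr.ind = TRUE)
  label <- share[pr]
  score <- coex[cbind(match(genes[pr[, 1L]], rownames(coex)),
                      match(genes[pr[, 2L]], rownames(coex)))]
  if (all(label)) stop("all gene pairs are positive; ROC undefined")
  if (!any(label)) stop("no positive gene pairs; ROC undefined")
  1e4 * partial_auc(score, label, fpr_cap = fpr_cap)
}

#' Unnormalized partial area under the ROC curve
#'
#' Instances are ranked by ascending `score` (low = predicted positive, the
#' MR convention). Tied scores are collapsed into single ROC vertices, so
#' ties contribute diagonal segments; the area over false-positive rate
#' `[0, fpr_cap]` is computed by trapezoidal integration with linear
#' interpolation at the cap. The maximum possible value is `fpr_cap`.
#'
#' @param score Numeric vector (ascending = stronger prediction).
#' @param label Logical vector of true classes.
#' @param fpr_cap False-positive-rate cap in (0, 1].
#' @return Numeric partial AUC in `[0, fpr_cap]`.
#' @export
partial_auc <- function(score, label, fpr_cap = 0.01) {
  stopifnot(length(score) == length(label), fpr_cap > 0, fpr_cap <= 1)
  P <- sum(label); N <- sum(!label)
  if (P == 0L || N == 0L) stop("need both positive and negative instances")
  o <- order(score)
  y <- label[o]; s <- score[o]
  bound <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(y)[bound] / P)
  fpr <- c(0, cumsum(!y)[bound] / N)
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1L]
    y0 <- tpr[i]; y1 <- tpr[i + 1L]
    if (x0 >= fpr_cap) break
    if (x1 > fpr_cap) {                 # clip the segment at the cap
      y1 <- y0 + (y1 - y0) * (fpr_cap - x0) / (x1 - x0)
      x1 <- fpr_cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

#' Reference adequateness of a chosen reference guide gene
#'
#' Ratio of the Blastp bitscore from guide g to its reference r-hat over g's
#' self-score, approximating the evolutionary proximity of the reference; a
#' same-species identical reference gives 1 by definition.
#'
#' @param g Guide gene id.
#' @param r_hat Chosen reference gene id.
#' @param cross Bitscore table from g's species to the reference species
#'   (ignored when `r_hat` is `g` itself).
#' @param self Bitscore table of g's species against itself, holding the
#'   `(g, g)` self-score.
#' @return Numeric ratio in (0, 1] (values > 1 are possible and flagged with
#'   a warning).
#' @export
reference_adequateness <- function(g, r_hat, cross = NULL, self = NULL) {
  if (identical(g, r_hat)) return(1)
  score_of <- function(tab, q, s, what) {
    if (is.null(tab)) stop("missing bitscore table for ", what)
    hit <- tab$bitscore[tab$query == q & tab$subject == s]
    if (length(hit) == 0L)
      stop("missing bitscore for pair (", q, ", ", s, ")")
    max(hit)
  }
  num <- score_of(cross, g, r_hat, "the cross-species pair")
  den <- score_of(self, g, g, "the self-score")
  r <- num / den
  if (r > 1)
    warning("bitscore(", g, " -> ", r_hat, ") exceeds the self-score; ",
            "adequateness > 1")
  r
}

#' Reproducibility score of a coexpression dataset
#'
#' For every guide gene with a non-empty reference set, maxCOXSIM over the
#' references divided by the adequateness of the chosen reference; the score
#' is the median of these normalized values over the assessable guides,
#' reported in 1E-01 units (median x 10). Normalizing by adequateness
#' corrects for the evolutionary distance of the best available reference.
#'
#' @param dataset_id Id of the dataset under assessment.
#' @param datasets Named list of [coex_dataset()] objects (the dataset under
#'   assessment plus the reference datasets).
#' @param best_hits Named list of cross-species best-hit maps keyed
#'   `"<spA>-><spB>"`.
#' @param bitscores Named list of [bitscore_table()] objects keyed
#'   `"<spA>-><spB>"`, including the self tables `"<sp>-><sp>"`.
#' @param k_fraction Prefix-depth fraction (default 0.01).
#' @param guides Optional subset of guide genes to assess (default: every
#'   gene of the dataset's table).
#' @return Numeric score (1E-01 units), with attribute `"n_guides"` (number
#'   of assessable guides entering the median).
#' @export
reproducibility_score <- function(dataset_id, datasets, best_hits = list(),
                                  bitscores = list(), k_fraction = 0.01,
                                  guides = NULL) {
  own <- datasets[[dataset_id]]
  if (is.null(own)) stop("unknown dataset '", dataset_id, "'")
  if (is.null(guides)) guides <- rownames(own$mr)
  vals <- rep(NA_real_, length(guides))
  for (i in seq_along(guides)) {
    g <- guides[i]
    res <- max_coxsim(g, dataset_id, datasets, best_hits, k_fraction)
    if (!res$assessable) next
    ref_sp <- datasets[[res$best_dataset]]$species
    adq <- reference_adequateness(
      g, res$best_gene,
      cross = bitscores[[paste0(own$species, "->", ref_sp)]],
      self  = bitscores[[paste0(own$species, "->", own$species)]])
    vals[i] <- res$max_coxsim / adq
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no assessable guide genes")
  structure(10 * stats::median(vals), n_guides = length(vals))
}
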