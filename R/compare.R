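#' Similarity of two coexpression datasets
#'
#' COXSIM between the lists of every pair of corresponding guide genes
#' (guide in A, its counterpart under `fwd` in B); the dataset-level
#' similarity is the median over those guide pairs. The measure is not
#' exactly symmetric in A and B; see [similarity_matrix()] for the
#' symmetrized form.
#'
#' @param mr_a,mr_b Mutual Rank tables.
#' @param fwd,rev Cross-dataset gene maps (named character vectors;
#'   `NULL` = identity).
#' @param k_fraction Prefix-depth fraction (default 0.01).
#' @param guides Optional subset of guide genes of A.
#' @return Median COXSIM in `[0, 1]`.
#' @export
dataset_similarity <- function(mr_a, mr_b, fwd = NULL, rev = NULL,
                               k_fraction = 0.01, guides = NULL) {
  ga <- rownames(mr_a)
  if (!is.null(guides)) ga <- intersect(guides, ga)
  keep_a <- ga[.mapped_into(ga, fwd, rownames(mr_b))]
  all_a <- rownames(mr_a)[.mapped_into(rownames(mr_a), fwd, rownames(mr_b))]
  all_b <- rownames(mr_b)[.mapped_into(rownames(mr_b), rev, rownames(mr_a))]
  if (length(keep_a) == 0L) stop("no corresponding guide genes")
  vals <- vapply(keep_a, function(g) {
    r <- if (is.null(fwd)) g else unname(fwd[g])
    lg <- .restricted_list(mr_a, g, all_a)
    lr <- .restricted_list(mr_b, r, all_b)
    if (length(lg$genes) == 0L || length(lr$genes) == 0L) return(NA_real_)
    k <- max(1L, ceiling(k_fraction * length(lg$genes)))
    as.numeric(coxsim(lg, lr, fwd, k = k))
  }, numeric(1))
  stats::median(vals, na.rm = TRUE)
}

#' Pairwise similarity matrix over a set of coexpression datasets
#'
#' Computes [dataset_similarity()] in both directions for every dataset pair
#' and averages the two directions into a symmetric matrix (diagonal 1:
#' self-comparison under the identity map).
#'
#' @param datasets Named list of [coex_dataset()] objects.
#' @param best_hits Named list of cross-species best-hit maps keyed
#'   `"<spA>-><spB>"`.
#' @param k_fraction Prefix-depth fraction (default 0.01).
#' @param guides Optional named list: per dataset id, the guide subset to
#'   use (speeds up large tables).
#' @return List with `raw` (directed similarities, rows = target dataset)
#'   and `sym` (symmetrized matrix).
#' @export
similarity_matrix <- function(datasets, best_hits = list(),
                              k_fraction = 0.01, guides = NULL) {
  ids <- sort(names(datasets))
  raw <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(raw) <- 1
  for (a in ids) for (b in setdiff(ids, a)) {
    maps <- .pair_maps(datasets[[a]]$species, datasets[[b]]$species, best_hits)
    raw[a, b] <- dataset_similarity(datasets[[a]]$mr, datasets[[b]]$mr,
                                    maps$fwd, maps$rev, k_fraction,
                                    guides = guides[[a]])
  }
  list(raw = raw, sym = (raw + t(raw)) / 2)
}

#' Complete-linkage clustering of coexpression datasets
#'
#' Clusters datasets by complete-linkage agglomeration on distance
#' `1 - similarity` and returns the dendrogram as Newick text with branch
#' heights.
#'
#' @param sim Symmetric similarity matrix in `[0, 1]` with dataset ids as
#'   dimnames (e.g. the `sym` component of [similarity_matrix()]).
#' @return Newick string (class `character`) with attribute `"hclust"`
#'   carrying the underlying [stats::hclust] object.
#' @export
cluster_datasets <- function(sim) {
  if (nrow(sim) < 2L) stop("need at least 2 datasets")
  d <- 1 - sim
  if (any(!is.finite(d))) stop("non-finite distances")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(nwk, hclust = hc)
}

#' Geometric average Mutual Rank of a gene pair across datasets
#'
#' The pair's MR values in each table are combined by the geometric mean, the
#' natural average for a rank-ratio statistic. The gene ids may differ per
#' table (orthologous pairs across species).
#'
#' @param tables List of Mutual Rank tables.
#' @param genes_a,genes_b Character vectors giving the pair's two genes in
#'   each table (recycled if length 1).
#' @return Geometric mean MR, or `NA` (with attribute `"reason"`) when the
#'   pair is missing from any table.
#' @export
geometric_avg_mr <- function(tables, genes_a, genes_b) {
  n <- length(tables)
  genes_a <- rep_len(genes_a, n); genes_b <- rep_len(genes_b, n)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    tb <- tables[[i]]
    if (!(genes_a[i] %in% rownames(tb)) || !(genes_b[i] %in% rownames(tb)))
      return(structure(NA_real_,
                       reason = sprintf("pair (%s, %s) absent from table %d",
                                        genes_a[i], genes_b[i], i)))
    vals[i] <- tb[genes_a[i], genes_b[i]]
  }
  exp(mean(log(vals)))
}

#' Classify an ortholog pair's coexpression as conserved or lineage-specific
#'
#' Compares the pair's clade-averaged coexpression strengths (geometric
#' average MR per clade). Strong coexpression in both clades is conserved;
#' strong in one clade and weak in the other is lineage-specific; weak in
#' both is not coexpressed. The gap between `strong_mr` and `weak_mr` leaves
#' an indeterminate band that prevents overcalling borderline pairs. The
#' defaults (500 / 5000) refer to genome-scale tables where the background
#' MR peak sits near half the gene count (~10,000).
#'
#' @param dicot_avg,monocot_avg Geometric-average MR of the pair in the two
#'   clades (vectorized).
#' @param strong_mr MR below which coexpression counts as strong
#'   (default 500).
#' @param weak_mr MR above which coexpression counts as absent
#'   (default 5000).
#' @return Character vector with values `"conserved"`, `"dicot-specific"`,
#'   `"monocot-specific"`, `"not-coexpressed"` or `"indeterminate"`.
#' @export
classify_lineage <- function(dicot_avg, monocot_avg,
                             strong_mr = 500, weak_mr = 5000) {
  stopifnot(strong_mr < weak_mr)
  n <- max(length(dicot_avg), length(monocot_avg))
  d <- rep_len(dicot_avg, n); m <- rep_len(monocot_avg, n)
  out <- rep("indeterminate", n)
  out[d < strong_mr & m < strong_mr] <- "conserved"
  out[d < strong_mr & m > weak_mr] <- "dicot-specific"
  out[m < strong_mr & d > weak_mr] <- "monocot-specific"
  out[d > weak_mr & m > weak_mr] <- "not-coexpressed"
  out[is.na(d) | is.na(m)] <- NA_character_
  out
}

#' Lineage classification of ortholog-pair coexpression across datasets
#'
#' For every unordered pair of ortholog groups, computes the geometric
#' average MR over each clade's datasets and classifies the pair with
#' [classify_lineage()]. Pairs missing from any table are excluded.
#'
#' @param groups `data.frame` of ortholog groups, one column per species
#'   ([orthologous_groups()]).
#' @param datasets Named list of [coex_dataset()] objects covering the
#'   groups' species.
#' @param clades Named character vector species -> clade (exactly two clade
#'   labels; the first in sorted order is reported as `avg_a`).
#' @param strong_mr,weak_mr Thresholds for [classify_lineage()].
#' @return `data.frame(group_a, group_b, avg_a, avg_b, label)`, one row per
#'   classifiable ortholog-group pair; `group_*` index rows of `groups`.
#' @export
lineage_classification <- function(groups, datasets, clades,
                                   strong_mr = 500, weak_mr = 5000) {
  clade_levels <- sort(unique(clades))
  if (length(clade_levels) != 2L) stop("need exactly two clades")
  ids <- names(datasets)
  sp <- vapply(datasets, `[[`, character(1), "species")
  cl <- clades[sp]
  res <- list()
  ng <- nrow(groups)
  for (i in seq_len(ng - 1L)) for (j in seq((i + 1L), ng)) {
    avg <- stats::setNames(numeric(2), clade_levels)
    ok <- TRUE
    for (cv in clade_levels) {
      sel <- ids[cl == cv]
      v <- geometric_avg_mr(lapply(datasets[sel], `[[`, "mr"),
                            unlist(groups[i, sp[sel]]),
                            unlist(groups[j, sp[sel]]))
      if (is.na(v)) { ok <- FALSE; break }
      avg[cv] <- v
    }
    if (!ok) next
    res[[length(res) + 1L]] <- data.frame(
      group_a = i, group_b = j, avg_a = avg[1L], avg_b = avg[2L],
      label = classify_lineage(avg[1L], avg[2L], strong_mr, weak_mr),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(group_a = integer(), group_b = integer(),
                      avg_a = numeric(), avg_b = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "clades") <- clade_levels
  out
}
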