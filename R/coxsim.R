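#' Ranked coexpressed-gene list of a guide gene
#'
#' Extracts the guide gene's coexpression neighbours from a Mutual Rank table,
#' ordered by ascending MR (strongest coexpression first); ties are broken by
#' gene id so the order is fully deterministic. The guide itself is excluded.
#'
#' @param mr Mutual Rank matrix (see [mutual_rank()]).
#' @param guide Gene id present in `mr`.
#' @param dataset Optional dataset id recorded on the list.
#' @return Object of class `ranked_gene_list` with fields `guide`, `dataset`,
#'   `genes` (ordered ids) and `universe` (all gene ids of the table).
#' @export
ranked_gene_list <- function(mr, guide, dataset = NA_character_) {
  if (!guide %in% rownames(mr)) stop("guide gene '", guide, "' not in table")
  v <- mr[guide, ]
  v <- v[!is.na(v) & names(v) != guide]
  ord <- order(v, names(v))
  structure(list(guide = guide, dataset = dataset,
                 genes = names(v)[ord], universe = rownames(mr)),
            class = "ranked_gene_list")
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat("ranked_gene_list: guide", x$guide,
      if (!is.na(x$dataset)) paste0("(", x$dataset, ")"), "-",
      length(x$genes), "genes, top:",
      paste(utils::head(x$genes, 5L), collapse = ", "), "...\n")
  invisible(x)
}

#' Restrict two ranked lists to genes with counterparts in the other dataset
#'
#' Gene universes differ between datasets/species, so before comparing two
#' ranked lists each list is restricted to the genes whose mapped counterpart
#' exists in the other list's gene universe; the original order is preserved.
#'
#' @param list_g0,list_r0 [ranked_gene_list()] objects before restriction.
#' @param fwd Named character vector mapping genes of `list_g0`'s dataset to
#'   genes of `list_r0`'s dataset (`NULL` = identity).
#' @param rev The reverse-direction map (`NULL` = identity).
#' @return List with components `list_g` and `list_r` (restricted lists) and
#'   `empty` (`TRUE` when either restricted list has no genes left).
#' @export
restrict_lists <- function(list_g0, list_r0, fwd = NULL, rev = NULL) {
  keep_g <- .mapped_into(list_g0$genes, fwd, list_r0$universe)
  keep_r <- .mapped_into(list_r0$genes, rev, list_g0$universe)
  list_g <- list_g0; list_g$genes <- list_g0$genes[keep_g]
  list_r <- list_r0; list_r$genes <- list_r0$genes[keep_r]
  list(list_g = list_g, list_r = list_r,
       empty = length(list_g$genes) == 0L || length(list_r$genes) == 0L)
}

.mapped_into <- function(genes, map, universe) {
  if (is.null(map)) return(genes %in% universe)
  tgt <- unname(map[genes])
  !is.na(tgt) & tgt %in% universe
}

#' COXSIM: weighted prefix concordance of two ranked gene lists
#'
#' For prefix depths i = 1..k, `n(i)` counts genes among the top i of
#' `list_g` whose mapped counterpart lies in the top i of `list_r`. COXSIM is
#' `sum_i n(i) / sum_i i`, a value in `[0, 1]` that weights agreement near the
#' top of the lists most heavily and equals 1 exactly when the lists agree
#' (under the map) at every prefix depth up to k.
#'
#' @param list_g,list_r [ranked_gene_list()] objects, already restricted to a
#'   common correspondence (see [restrict_lists()]).
#' @param fwd Named character map from `list_g` genes to `list_r` genes
#'   (`NULL` = identity).
#' @param k Prefix depth; default the top 1% of `list_g`
#'   (`ceiling(0.01 * length)`, minimum 1).
#' @return Numeric COXSIM value with attribute `"k"`.
#' @examples
#' lg <- structure(list(guide = "g", genes = c("A", "B", "C"),
#'                      universe = c("A", "B", "C", "g")),
#'                 class = "ranked_gene_list")
#' lr <- structure(list(guide = "r", genes = c("B", "A", "D"),
#'                      universe = c("A", "B", "D", "r")),
#'                 class = "ranked_gene_list")
#' coxsim(lg, lr, k = 3)  # (0 + 2 + 2) / (1 + 2 + 3) = 2/3
#' @export
coxsim <- function(list_g, list_r, fwd = NULL, k = NULL) {
  ng <- length(list_g$genes)
  if (ng == 0L || length(list_r$genes) == 0L)
    stop("COXSIM undefined for empty gene lists")
  if (is.null(k)) k <- max(1L, ceiling(0.01 * ng))
  if (k < 1L) stop("'k' must be >= 1")
  if (k > ng) stop("'k' exceeds the guide list length (", ng, ")")
  mapped <- if (is.null(fwd)) list_g$genes[seq_len(k)] else
    unname(fwd[list_g$genes[seq_len(k)]])
  pos_r <- match(mapped, list_r$genes)
  entered <- pmax(seq_len(k), pos_r)            # depth at which the pair counts
  contrib <- pmax(0L, k - entered + 1L)
  contrib[is.na(contrib)] <- 0L
  value <- sum(contrib) / (k * (k + 1) / 2)
  attr(value, "k") <- as.integer(k)
  value
}

#' A coexpression dataset: id, species, Mutual Rank table
#'
#' Light container tying an MR table to its dataset id and species, used by
#' the reference-set and scoring machinery.
#'
#' @param id Dataset id (e.g. `"Ath-r"`).
#' @param species Species id (e.g. `"Ath"`).
#' @param mr Mutual Rank matrix.
#' @return Object of class `coex_dataset`.
#' @export
coex_dataset <- function(id, species, mr) {
  structure(list(id = id, species = species, mr = mr), class = "coex_dataset")
}

#' Build the reference guide-gene set R for a guide gene
#'
#' For every other dataset: if it belongs to the same species, the identical
#' gene is the reference (when present); for another species, the Blastp best
#' hit of the guide in that species is the reference (when present in that
#' dataset's table). Datasets where the counterpart is absent are skipped.
#'
#' @param g Guide gene id.
#' @param dataset_id Id of the guide's own dataset.
#' @param datasets Named list of [coex_dataset()] objects (all candidates,
#'   including the guide's own dataset, which is never used as reference).
#' @param best_hits Named list of best-hit maps keyed `"<spA>-><spB>"`, each a
#'   named character vector (query gene -> best-hit gene).
#' @return `data.frame(dataset, gene)` of references, ordered by dataset id;
#'   zero rows when the guide has no reference anywhere.
#' @export
build_reference_set <- function(g, dataset_id, datasets, best_hits = list()) {
  own <- datasets[[dataset_id]]
  if (is.null(own)) stop("unknown dataset '", dataset_id, "'")
  out <- list()
  for (id in sort(setdiff(names(datasets), dataset_id))) {
    d <- datasets[[id]]
    r <- if (identical(d$species, own$species)) g else {
      key <- paste0(own$species, "->", d$species)
      if (is.null(best_hits[[key]])) NA_character_ else
        unname(best_hits[[key]][g])
    }
    if (!is.na(r) && r %in% rownames(d$mr))
      out[[id]] <- data.frame(dataset = id, gene = r,
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(dataset = character(), gene = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' maxCOXSIM of a guide gene over its reference set
#'
#' Computes COXSIM between the guide's list and each reference's list (after
#' [restrict_lists()]) and keeps the maximum; ties are broken by dataset id.
#' A guide without any reference is returned as unassessable.
#'
#' @inheritParams build_reference_set
#' @param k_fraction Prefix-depth fraction of the restricted guide list
#'   (default 0.01, i.e. the top 1%).
#' @return Object of class `coxsim_result` with fields `guide`, `dataset`,
#'   `max_coxsim`, `best_dataset`, `best_gene`, `values` (per-reference
#'   COXSIM), `assessable`.
#' @export
max_coxsim <- function(g, dataset_id, datasets, best_hits = list(),
                       k_fraction = 0.01) {
  refs <- build_reference_set(g, dataset_id, datasets, best_hits)
  res <- structure(list(guide = g, dataset = dataset_id,
                        max_coxsim = NA_real_, best_dataset = NA_character_,
                        best_gene = NA_character_, values = numeric(0),
                        assessable = FALSE),
                   class = "coxsim_result")
  if (nrow(refs) == 0L) return(res)
  own <- datasets[[dataset_id]]
  lg0 <- ranked_gene_list(own$mr, g, dataset_id)
  vals <- stats::setNames(numeric(nrow(refs)), refs$dataset)
  for (i in seq_len(nrow(refs))) {
    d <- datasets[[refs$dataset[i]]]
    maps <- .pair_maps(own$species, d$species, best_hits)
    lr0 <- ranked_gene_list(d$mr, refs$gene[i], d$id)
    rl <- restrict_lists(lg0, lr0, maps$fwd, maps$rev)
    vals[i] <- if (rl$empty) NA_real_ else {
      k <- max(1L, ceiling(k_fraction * length(rl$list_g$genes)))
      as.numeric(coxsim(rl$list_g, rl$list_r, maps$fwd, k = k))
    }
  }
  res$values <- vals
  if (all(is.na(vals))) return(res)
  best <- which(vals == max(vals, na.rm = TRUE))[1L]  # refs sorted by dataset id
  res$max_coxsim <- unname(vals[best])
  res$best_dataset <- refs$dataset[best]
  res$best_gene <- refs$gene[best]
  res$assessable <- TRUE
  res
}

.pair_maps <- function(sp_a, sp_b, best_hits) {
  if (identical(sp_a, sp_b)) return(list(fwd = NULL, rev = NULL))
  list(fwd = best_hits[[paste0(sp_a, "->", sp_b)]],
       rev = best_hits[[paste0(sp_b, "->", sp_a)]])
}

#' Empirical COXSIM null distribution from unrelated guide pairs
#'
#' COXSIM values between arbitrary combinations of guide genes from two
#' datasets — almost all of which are functionally unrelated — form a
#' realistic null that retains the dependence structure of real coexpression
#' lists. The full all-pairs set is quadratic, so a seeded uniform subsample
#' of `max_pairs` combinations is drawn when needed.
#'
#' @param mr_a,mr_b Mutual Rank tables of the two datasets.
#' @param fwd,rev Cross-dataset gene maps (named character vectors; `NULL` =
#'   identity).
#' @param k_fraction Prefix-depth fraction (default 0.01).
#' @param max_pairs Maximum number of guide/reference combinations evaluated
#'   (default 1e6).
#' @param seed Optional integer seed for the subsample.
#' @return Object of class `null_distribution`: sorted numeric vector of
#'   COXSIM values with a `"description"` attribute. Fewer than 1000 samples
#'   triggers a warning (unstable tail quantiles).
#' @export
build_null <- function(mr_a, mr_b, fwd = NULL, rev = NULL, k_fraction = 0.01,
                       max_pairs = 1e6, seed = NULL) {
  ga <- rownames(mr_a)[.mapped_into(rownames(mr_a), fwd, rownames(mr_b))]
  gb <- rownames(mr_b)[.mapped_into(rownames(mr_b), rev, rownames(mr_a))]
  if (length(ga) == 0L || length(gb) == 0L)
    stop("no corresponding genes between the two datasets")
  keep_a <- ga; keep_b <- gb
  n_all <- length(ga) * length(gb)
  if (!is.null(seed)) set.seed(seed)
  if (n_all <= max_pairs) {
    idx <- cbind(rep(seq_along(ga), times = length(gb)),
                 rep(seq_along(gb), each = length(ga)))
  } else {
    idx <- cbind(sample.int(length(ga), max_pairs, replace = TRUE),
                 sample.int(length(gb), max_pairs, replace = TRUE))
  }
  lists_a <- lapply(ga, function(g) .restricted_list(mr_a, g, keep_a))
  lists_b <- lapply(gb, function(g) .restricted_list(mr_b, g, keep_b))
  k_of <- function(lg) max(1L, ceiling(k_fraction * length(lg$genes)))
  vals <- vapply(seq_len(nrow(idx)), function(i) {
    lg <- lists_a[[idx[i, 1L]]]; lr <- lists_b[[idx[i, 2L]]]
    if (length(lg$genes) == 0L || length(lr$genes) == 0L) return(NA_real_)
    as.numeric(coxsim(lg, lr, fwd, k = k_of(lg)))
  }, numeric(1))
  vals <- sort(vals[!is.na(vals)])
  if (length(vals) < 1000L)
    warning("fewer than 1000 null samples; tail quantiles are unstable")
  structure(vals, class = "null_distribution",
            description = sprintf("%d COXSIM values (k = top %g%%)",
                                  length(vals), 100 * k_fraction))
}

# ranked list restricted to a fixed keep-set, guide excluded
.restricted_list <- function(mr, guide, keep) {
  v <- mr[guide, ]
  v <- v[!is.na(v) & names(v) != guide]
  ord <- order(v, names(v))
  genes <- names(v)[ord]
  structure(list(guide = guide, dataset = NA_character_,
                 genes = genes[genes %in% keep], universe = rownames(mr)),
            class = "ranked_gene_list")
}

#' maxCOXSIM significance thresholds from an empirical null
#'
#' The threshold for level `alpha` is the smallest observed null value x with
#' empirical survival `P(COXSIM >= x) <= alpha / n_reference_lists`
#' (Bonferroni correction for taking the maximum over the reference lists).
#' When the corrected level is finer than the null resolution the threshold
#' is set just above the largest sample, with a warning.
#'
#' @param null [build_null()] output (or any numeric vector of null COXSIMs).
#' @param n_reference_lists Bonferroni divisor: number of reference gene
#'   lists compared per guide.
#' @param alphas Significance levels, most lenient first
#'   (default `c(0.1, 0.01, 0.001)`).
#' @return Named numeric vector of non-decreasing thresholds.
#' @export
coxsim_thresholds <- function(null, n_reference_lists = 1L,
                              alphas = c(0.1, 0.01, 0.001)) {
  if (length(null) == 0L) stop("empty null distribution")
  if (n_reference_lists < 1L) stop("'n_reference_lists' must be >= 1")
  s <- sort(as.numeric(null))
  n <- length(s)
  u <- unique(s)
  surv <- (n - match(u, s) + 1L) / n            # P(X >= u_i)
  th <- vapply(alphas, function(a) {
    target <- a / n_reference_lists
    hit <- which(surv <= target)
    if (length(hit) == 0L) {
      warning("corrected level ", format(target),
              " below the null resolution 1/", n,
              "; threshold set above the largest null sample")
      max(s) + 1e-9
    } else u[hit[1L]]
  }, numeric(1))
  stats::setNames(th, paste0("p<", alphas))
}

#' Star rating of a maxCOXSIM value against significance thresholds
#'
#' @param max_coxsim maxCOXSIM value (or vector of values).
#' @param thresholds Non-decreasing thresholds from [coxsim_thresholds()].
#' @return Integer number of thresholds met, 0 to `length(thresholds)`;
#'   `NA` input (unassessable guide) gives `NA`.
#' @export
coxsim_stars <- function(max_coxsim, thresholds) {
  vapply(max_coxsim, function(x)
    if (is.na(x)) NA_integer_ else sum(x >= thresholds), integer(1))
}

#' Attach empirical-null significance to a maxCOXSIM result
#'
#' @param result [max_coxsim()] output.
#' @param null [build_null()] output.
#' @param n_reference_lists Bonferroni divisor (number of reference lists).
#' @param alphas Significance levels (default `c(0.1, 0.01, 0.001)`).
#' @return The `coxsim_result` with `thresholds` and `stars` fields filled;
#'   unassessable guides keep `stars = NA` (rendered blank).
#' @export
significance <- function(result, null, n_reference_lists = 1L,
                         alphas = c(0.1, 0.01, 0.001)) {
  th <- coxsim_thresholds(null, n_reference_lists, alphas)
  result$thresholds <- th
  result$stars <- coxsim_stars(result$max_coxsim, th)
  result
}

#' @export
print.coxsim_result <- function(x, ...) {
  if (!x$assessable) {
    cat("coxsim_result:", x$guide, "- unassessable (no reference genes)\n")
  } else {
    cat(sprintf("coxsim_result: %s maxCOXSIM = %.4f (reference %s in %s)\n",
                x$guide, x$max_coxsim, x$best_gene, x$best_dataset))
    if (!is.null(x$stars))
      cat("  stars:", strrep("*", x$stars), sprintf("(%d)\n", x$stars))
  }
  invisible(x)
}
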