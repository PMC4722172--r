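#' Bitscore table between two species
#'
#' A set of (query gene, subject gene, bitscore) records, the minimal subset
#' of blast tabular output the toolkit consumes. Duplicate (query, subject)
#' records keep the maximum bitscore. Self records `(g, g)` are allowed and
#' carry the self-scores used by [reference_adequateness()].
#'
#' @param records `data.frame` with columns `query`, `subject`, `bitscore`
#'   (extra columns ignored).
#' @param query_species,subject_species Species ids of the two sides.
#' @return `data.frame` of class `bitscore_table` with attributes
#'   `query_species` and `subject_species`.
#' @export
bitscore_table <- function(records, query_species, subject_species) {
  records <- as.data.frame(records)[, c("query", "subject", "bitscore")]
  if (any(records$bitscore <= 0)) stop("bitscores must be > 0")
  records <- records[order(records$query, records$subject,
                           -records$bitscore), ]
  records <- records[!duplicated(records[, c("query", "subject")]), ]
  rownames(records) <- NULL
  structure(records, class = c("bitscore_table", "data.frame"),
            query_species = query_species, subject_species = subject_species)
}

#' Read a blast tabular (outfmt 6) file into a bitscore table
#'
#' Accepts either the full 12-column tabular format (qseqid, sseqid, ...,
#' bitscore in column 12) or a reduced 3-column (query, subject, bitscore)
#' file, with or without a header line.
#'
#' @param path File path.
#' @inheritParams bitscore_table
#' @return [bitscore_table()] object.
#' @export
read_blast_table <- function(path, query_species, subject_species) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("bitscore|bit_score", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) >= 12L) df <- df[, c(1L, 2L, 12L)]
  else if (ncol(df) == 3L) df <- df[, 1:3]
  else stop("expected 3 or >= 12 tab-separated columns in '", path, "'")
  names(df) <- c("query", "subject", "bitscore")
  df$bitscore <- as.numeric(df$bitscore)
  bitscore_table(df, query_species, subject_species)
}

#' Best hit of one gene in a bitscore table
#'
#' Subject with the maximal bitscore among the gene's records, excluding the
#' gene itself for same-species tables; ties are broken lexicographically.
#'
#' @param g Query gene id.
#' @param table [bitscore_table()] oriented from `g`'s species to the target.
#' @return Subject gene id, or `NA` when `g` has no (non-self) records.
#' @export
best_hit <- function(g, table) {
  same_sp <- identical(attr(table, "query_species"),
                       attr(table, "subject_species"))
  rec <- table[table$query == g, , drop = FALSE]
  if (same_sp) rec <- rec[rec$subject != g, , drop = FALSE]
  if (nrow(rec) == 0L) return(NA_character_)
  rec <- rec[order(-rec$bitscore, rec$subject), , drop = FALSE]
  rec$subject[1L]
}

#' Best-hit map for every query gene of a bitscore table
#'
#' @param table [bitscore_table()].
#' @return Named character vector, query gene -> best-hit subject.
#' @export
best_hit_map <- function(table) {
  same_sp <- identical(attr(table, "query_species"),
                       attr(table, "subject_species"))
  rec <- as.data.frame(table)
  if (same_sp) rec <- rec[rec$query != rec$subject, , drop = FALSE]
  rec <- rec[order(rec$query, -rec$bitscore, rec$subject), , drop = FALSE]
  rec <- rec[!duplicated(rec$query), , drop = FALSE]
  stats::setNames(rec$subject, rec$query)
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is a reciprocal best hit (RBH) iff a's best hit in the other
#' species is b and b's best hit is a. The pair set is symmetric in the two
#' input tables.
#'
#' @param table_ab Bitscore table from species A to species B.
#' @param table_ba Bitscore table from species B to species A.
#' @return `data.frame(a, b)` of RBH pairs, sorted by `a`.
#' @export
rbh_pairs <- function(table_ab, table_ba) {
  bh_ab <- best_hit_map(table_ab)
  bh_ba <- best_hit_map(table_ba)
  a <- names(bh_ab)
  b <- unname(bh_ab)
  ok <- !is.na(b) & b %in% names(bh_ba) & unname(bh_ba[b]) == a
  out <- data.frame(a = a[ok], b = b[ok], stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]
}

#' One-gene-per-species orthologous groups
#'
#' A group contains exactly one gene from each declared species and every
#' cross-species pair in the group is a reciprocal best hit (a full RBH
#' clique, the strictest multi-species reading of the RBH method).
#'
#' @param species Character vector of species ids (>= 2).
#' @param tables Named list of [bitscore_table()] objects keyed
#'   `"<spA>-><spB>"`, one per ordered species pair.
#' @return `data.frame` with one column per species, one row per group.
#' @export
orthologous_groups <- function(species, tables) {
  if (length(species) < 2L) stop("need at least 2 species")
  pair_key <- function(a, b) paste0(a, "->", b)
  for (a in species) for (b in setdiff(species, a))
    if (is.null(tables[[pair_key(a, b)]]))
      stop("missing bitscore table for species pair ", pair_key(a, b))
  rbh <- list()   # rbh[["A|B"]]: named map a -> b (and back under "B|A")
  combs <- utils::combn(species, 2L)
  for (j in seq_len(ncol(combs))) {
    a <- combs[1L, j]; b <- combs[2L, j]
    pr <- rbh_pairs(tables[[pair_key(a, b)]], tables[[pair_key(b, a)]])
    rbh[[paste0(a, "|", b)]] <- stats::setNames(pr$b, pr$a)
    rbh[[paste0(b, "|", a)]] <- stats::setNames(pr$a, pr$b)
  }
  anchor <- species[1L]
  groups <- list()
  for (g in sort(names(rbh[[paste0(anchor, "|", species[2L])]]))) {
    members <- stats::setNames(character(length(species)), species)
    members[anchor] <- g
    ok <- TRUE
    for (sp in species[-1L]) {
      m <- rbh[[paste0(anchor, "|", sp)]][g]
      if (is.na(m)) { ok <- FALSE; break }
      members[sp] <- unname(m)
    }
    if (!ok) next
    # every non-anchor cross pair must be RBH too (full clique)
    others <- species[-1L]
    if (length(others) > 1L) {
      oc <- utils::combn(others, 2L)
      for (j in seq_len(ncol(oc))) {
        a <- oc[1L, j]; b <- oc[2L, j]
        m <- rbh[[paste0(a, "|", b)]][members[a]]
        if (is.na(m) || m != members[b]) { ok <- FALSE; break }
      }
    }
    if (ok) groups[[length(groups) + 1L]] <- members
  }
  if (length(groups) == 0L)
    return(as.data.frame(stats::setNames(
      rep(list(character(0)), length(species)), species)))
  out <- as.data.frame(do.call(rbind, groups), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
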