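#' Build a coexpression network around query genes
#'
#' Node set = the queries plus, for each query, its `n_retrieved_per_query`
#' most strongly coexpressed genes (lowest MR). Every node then draws edges
#' to its `edges_per_gene` strongest-coexpressed partners within the node
#' set; edges are deduplicated. Constraining each gene to its top partners
#' keeps the network at medium density regardless of the query set.
#'
#' @param queries Character vector of query gene ids (all must be in `coex`).
#' @param coex Mutual Rank table.
#' @param n_retrieved_per_query Coexpressed genes retrieved per query
#'   (default 20).
#' @param edges_per_gene Strongest partners each node links to (default 3).
#' @return Object of class `coex_network`: list with `nodes`
#'   (`data.frame(gene, role)`, role `"query"` or `"retrieved"`) and `edges`
#'   (`data.frame(from, to, mr, supported)`, `from < to`, support flag `NA`
#'   until [flag_supported_edges()]).
#' @export
build_network <- function(queries, coex, n_retrieved_per_query = 20L,
                          edges_per_gene = 3L) {
  missing <- setdiff(queries, rownames(coex))
  if (length(missing) > 0L)
    stop("query genes absent from the table: ",
         paste(missing, collapse = ", "))
  retrieved <- unlist(lapply(queries, function(q) {
    v <- coex[q, ]
    v <- v[!is.na(v) & names(v) != q]
    names(v)[order(v, names(v))][seq_len(min(n_retrieved_per_query,
                                             length(v)))]
  }))
  nodes <- sort(unique(c(queries, retrieved)))
  role <- ifelse(nodes %in% queries, "query", "retrieved")
  edges <- list()
  for (g in nodes) {
    v <- coex[g, nodes]
    v <- v[!is.na(v) & names(v) != g]
    top <- names(v)[order(v, names(v))][seq_len(min(edges_per_gene,
                                                    length(v)))]
    for (h in top)
      edges[[paste(min(g, h), max(g, h))]] <-
        data.frame(from = min(g, h), to = max(g, h),
                   mr = unname(coex[g, h]), supported = NA,
                   stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) == 0L)
    data.frame(from = character(), to = character(), mr = numeric(),
               supported = logical(), stringsAsFactors = FALSE)
  else do.call(rbind, c(unname(edges[sort(names(edges))]),
                        list(make.row.names = FALSE)))
  structure(list(nodes = data.frame(gene = nodes, role = role,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat("coex_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "query"), "queries ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Flag edges supported by other coexpression datasets
#'
#' An edge is supported when the (orthologous) gene pair shows strong
#' coexpression (MR below `strong_mr`) in at least one other dataset —
#' the cross-platform evidence highlighted in drawn networks.
#'
#' @param net [build_network()] output.
#' @param tables List of other datasets' MR tables.
#' @param maps Optional list (parallel to `tables`) of gene maps from the
#'   network's dataset into each other dataset (`NULL` entries = identity).
#' @param strong_mr Support threshold (default 500).
#' @return The network with the `supported` edge column filled.
#' @export
flag_supported_edges <- function(net, tables, maps = NULL, strong_mr = 500) {
  if (is.null(maps)) maps <- vector("list", length(tables))
  net$edges$supported <- vapply(seq_len(nrow(net$edges)), function(i) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    for (j in seq_along(tables)) {
      m <- maps[[j]]
      aa <- if (is.null(m)) a else unname(m[a])
      bb <- if (is.null(m)) b else unname(m[b])
      tb <- tables[[j]]
      if (!is.na(aa) && !is.na(bb) &&
          aa %in% rownames(tb) && bb %in% rownames(tb) &&
          isTRUE(tb[aa, bb] < strong_mr)) return(TRUE)
    }
    FALSE
  }, logical(1))
  net
}

#' Convert a coexpression network to an igraph graph
#'
#' Vertices are ordered lexicographically (making downstream community
#' detection deterministic); `role`, `mr` and `supported` become vertex/edge
#' attributes and edge weight is `1/mr`.
#'
#' @param net [build_network()] output.
#' @return [igraph::graph] (undirected, simple).
#' @export
network_graph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$gene)
  igraph::V(g)$role <- net$nodes$role
  if (nrow(net$edges) > 0L) {
    igraph::E(g)$mr <- net$edges$mr
    igraph::E(g)$supported <- net$edges$supported
    igraph::E(g)$weight <- 1 / net$edges$mr
  }
  g
}

#' Detect subnetworks of a coexpression network
#'
#' Partitions the nodes into connected subnetworks. The default strategy is
#' greedy modularity maximization (agglomerative merging); `"components"`
#' simply takes connected components. Both are deterministic for a fixed
#' network. Singleton subnetworks are allowed.
#'
#' @param net [build_network()] output.
#' @param method `"greedy_modularity"` (default) or `"components"`.
#' @return List of objects of class `subnetwork` (fields `members`, sorted,
#'   and `enrichment`, `NULL` until [enrich()]), ordered by first member.
#' @export
detect_subnetworks <- function(net,
                               method = c("greedy_modularity", "components")) {
  method <- match.arg(method)
  if (nrow(net$nodes) == 0L) stop("empty network")
  g <- network_graph(net)
  membership <- if (method == "components" || igraph::ecount(g) == 0L)
    igraph::components(g)$membership
  else
    igraph::membership(igraph::cluster_fast_greedy(g, weights = NULL))
  parts <- split(names(membership), membership)
  parts <- lapply(parts, sort)
  parts <- parts[order(vapply(parts, `[`, character(1), 1L))]
  lapply(unname(parts), function(m)
    structure(list(members = m, enrichment = NULL), class = "subnetwork"))
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork:", length(x$members), "genes:",
      paste(utils::head(x$members, 6L), collapse = ", "),
      if (length(x$members) > 6L) "..." else "", "\n")
  if (!is.null(x$enrichment))
    print(utils::head(x$enrichment, 5L))
  invisible(x)
}

#' Category enrichment of a subnetwork (hypergeometric, Bonferroni)
#'
#' One-sided hypergeometric over-representation test of each category among
#' the subnetwork members against the background gene universe, Bonferroni-
#' corrected over the number of categories tested. Categories can be GO
#' terms, promoter heptamers, or any gene -> category-set assignment; GO
#' terms and heptamers should be tested as separate families.
#'
#' @param sub `subnetwork` object (or character vector of member genes).
#' @param categories Named list: gene id -> character vector of category ids.
#' @param background Character vector of background gene ids (must contain
#'   the members).
#' @return For a `subnetwork` input, the object with `enrichment` filled;
#'   otherwise the enrichment `data.frame(category, overlap, category_size,
#'   p, p_bonferroni)` sorted by corrected then raw p.
#' @export
enrich <- function(sub, categories, background) {
  members <- if (inherits(sub, "subnetwork")) sub$members else sub
  if (length(background) == 0L) stop("empty background")
  if (!all(members %in% background))
    stop("subnetwork members missing from the background")
  long <- data.frame(
    gene = rep(names(categories),
               vapply(categories, length, integer(1))),
    category = unlist(categories, use.names = FALSE),
    stringsAsFactors = FALSE)
  long <- unique(long[long$gene %in% background, , drop = FALSE])
  if (nrow(long) == 0L)
    stop("no categories represented in the background")
  cats <- sort(unique(long$category))
  N <- length(background); n <- length(members)
  K <- table(factor(long$category, levels = cats))
  x <- table(factor(long$category[long$gene %in% members], levels = cats))
  res <- data.frame(category = cats,
                    overlap = as.integer(x),
                    category_size = as.integer(K),
                    p = stats::phyper(as.integer(x) - 1L, as.integer(K),
                                      N - as.integer(K), n,
                                      lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  res$p_bonferroni <- pmin(1, res$p * length(cats))
  res <- res[order(res$p_bonferroni, res$p, res$category), , drop = FALSE]
  rownames(res) <- NULL
  if (inherits(sub, "subnetwork")) { sub$enrichment <- res; sub } else res
}

#' Heptamers present in a proximal promoter window
#'
#' Scans the `[-window, -1]` region of a promoter sequence (supplied 5'->3'
#' on the coding strand, position -1 adjacent to the start) and returns every
#' distinct 7-nucleotide word; windows containing ambiguous bases are
#' skipped. The category space is the 4^7 = 16384 possible heptamers.
#'
#' @param promoter Character string or [Biostrings::DNAString].
#' @param window Width of the proximal region scanned (default 300, i.e.
#'   positions -300..-1).
#' @param revcomp Also include the reverse complements of the observed
#'   heptamers (default `FALSE`; strand handling is a declared choice).
#' @return Sorted character vector of distinct heptamers (possibly empty).
#' @export
promoter_heptamers <- function(promoter, window = 300L, revcomp = FALSE) {
  s <- toupper(as.character(promoter))
  L <- nchar(s)
  if (L < 7L) {
    warning("promoter shorter than 7 nt; no heptamers")
    return(character(0))
  }
  s <- substr(s, max(1L, L - window + 1L), L)
  n <- nchar(s)
  w <- substring(s, 1:(n - 6L), 7:n)
  w <- w[grepl("^[ACGT]{7}$", w)]
  if (revcomp && length(w) > 0L)
    w <- c(w, as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(w))))
  sort(unique(w))
}

#' Heptamer category assignment for a set of promoters
#'
#' @param promoters Named [Biostrings::DNAStringSet] (or character vector)
#'   of promoter sequences; record names are parsed to gene ids by their
#'   first token.
#' @inheritParams promoter_heptamers
#' @return Named list gene -> character vector of heptamers, suitable for
#'   [enrich()].
#' @export
promoter_heptamer_sets <- function(promoters, window = 300L,
                                   revcomp = FALSE) {
  seqs <- as.character(promoters)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lapply(seqs, promoter_heptamers, window = window, revcomp = revcomp)
}

#' Write a coexpression network as GraphML
#'
#' Node role and edge MR / support flags are exported as attributes.
#'
#' @param net [build_network()] output (optionally after
#'   [flag_supported_edges()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- network_graph(net)
  if (igraph::ecount(g) > 0L) {
    sup <- igraph::E(g)$supported
    igraph::E(g)$supported <- ifelse(is.na(sup), "unknown",
                                     ifelse(sup, "yes", "no"))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a coexpression network as an edge-list TSV
#'
#' @inheritParams write_network_graphml
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
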