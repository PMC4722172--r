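# shared builders for the test suite; everything is generated in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# a ranked_gene_list without going through an MR table
rl <- function(genes, universe = genes, guide = "guide",
               dataset = NA_character_) {
  structure(list(guide = guide, dataset = dataset,
                 genes = genes, universe = unique(c(universe, guide))),
            class = "ranked_gene_list")
}

# random symmetric correlation-like matrix with unit diagonal
random_corr <- function(n, seed = NULL, prefix = "g") {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * 4L * n), n)
  cc <- cor(t(x))
  dimnames(cc) <- list(sprintf("%s%03d", prefix, 1:n),
                       sprintf("%s%03d", prefix, 1:n))
  cc
}

# random MR table via the package pipeline on random expression
random_mr <- function(n, n_samples = 20L, seed = NULL, prefix = "g") {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * n_samples), n,
              dimnames = list(sprintf("%s%03d", prefix, 1:n), NULL))
  mutual_rank(cor(t(x)))
}

# brute-force MR oracle: explicit double sort per ordered pair
oracle_mutual_rank <- function(corr) {
  n <- nrow(corr)
  rk <- matrix(NA_real_, n, n)
  for (a in 1:n) {
    others <- setdiff(1:n, a)
    v <- corr[a, others]
    # rank of each b among others by descending correlation, ties averaged
    r <- rank(-v)
    rk[a, others] <- r
  }
  mr <- sqrt(rk * t(rk))
  dimnames(mr) <- dimnames(corr)
  mr
}

# brute-force COXSIM oracle: literal prefix counting at every depth
oracle_coxsim <- function(genes_g, genes_r, map = NULL, k) {
  n_i <- integer(k)
  for (i in 1:k) {
    top_g <- genes_g[1:min(i, length(genes_g))]
    top_r <- genes_r[1:min(i, length(genes_r))]
    mapped <- if (is.null(map)) top_g else unname(map[top_g])
    n_i[i] <- sum(!is.na(mapped) & mapped %in% top_r)
  }
  sum(n_i) / sum(1:k)
}

# brute-force pAUC oracle: enumerate every threshold, trapezoid with
# explicit cap interpolation
oracle_pauc <- function(score, label, cap = 0.01) {
  P <- sum(label); N <- sum(!label)
  th <- sort(unique(score))
  fpr <- c(0, vapply(th, function(t) sum(score <= t & !label) / N, 0))
  tpr <- c(0, vapply(th, function(t) sum(score <= t & label) / P, 0))
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]; y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= cap) break
    if (x1 > cap) {
      y1 <- y0 + (y1 - y0) * (cap - x0) / (x1 - x0)
      x1 <- cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

# small fixture configuration used across tests (kept light for speed)
small_cfg <- function(seed = 11L, ...) {
  fixture_config(seed = seed, n_genes = 120L, n_runs = 24L,
                 module_size = 8L, n_conserved = 1L, n_per_clade = 1L,
                 n_low_genes = 3L, ...)
}

# full pipeline over every dataset of a fixture
fixture_mr_tables <- function(cfg) {
  ex <- gen_expression_datasets(cfg)
  mrs <- lapply(names(ex$counts), function(id)
    coexpression_table(ex$counts[[id]], ex$experiments[[id]]))
  names(mrs) <- names(ex$counts)
  list(mrs = mrs, truth = ex$truth, experiments = ex$experiments,
       counts = ex$counts)
}

fx_gene <- function(sp, idx) sprintf("%s_g%04d", sp, idx)
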