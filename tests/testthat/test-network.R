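# MR-like table with planted block structure for network tests
block_mr <- function(blocks, n_bg = 0, seed = 61) {
  set.seed(seed)
  n <- sum(blocks) + n_bg
  x <- matrix(rnorm(n * 15), n,
              dimnames = list(sprintf("g%02d", 1:n), NULL))
  start <- 1
  for (b in blocks) {
    f <- rnorm(15)
    for (i in start:(start + b - 1)) x[i, ] <- f + rnorm(15, sd = 0.05)
    start <- start + b
  }
  mutual_rank(cor(t(x)))
}

test_that("network construction saturates small node sets and deduplicates edges", {
  mr <- block_mr(4)
  net <- build_network("g01", mr, n_retrieved_per_query = 3)
  # 4 tight genes: every node's top-3 covers the other 3 -> complete graph
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 6)
  expect_equal(net$nodes$role, c("query", rep("retrieved", 3)))
  expect_true(all(net$edges$from < net$edges$to))
  expect_equal(anyDuplicated(net$edges[, c("from", "to")]), 0)
})

test_that("node sets smaller than edges_per_gene + 1 link to all others", {
  mr <- block_mr(3)
  net <- build_network("g01", mr, n_retrieved_per_query = 2,
                       edges_per_gene = 3)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)       # each node links to the other 2
  expect_error(build_network(c("g01", "nope"), mr), "nope")
})

test_that("subnetwork detection separates planted cliques joined by a bridge", {
  # two 5-cliques with one cross edge: modularity splits them apart
  mr <- block_mr(c(5, 5))
  net <- build_network(c("g01", "g06"), mr, n_retrieved_per_query = 4,
                       edges_per_gene = 3)
  # add the bridge by construction if absent: the blocks are so tight that
  # each node's top-3 stays within its block, so connect explicitly
  bridge <- data.frame(from = "g01", to = "g06",
                       mr = 50, supported = NA)
  net$edges <- unique(rbind(net$edges, bridge))
  subs <- detect_subnetworks(net)
  expect_equal(length(subs), 2)
  expect_equal(subs[[1]]$members, sprintf("g%02d", 1:5))
  expect_equal(subs[[2]]$members, sprintf("g%02d", 6:10))
  # partition covers all nodes
  expect_setequal(unlist(lapply(subs, `[[`, "members")), net$nodes$gene)
})

test_that("disconnected components are separate subnetworks, singletons allowed", {
  mr <- block_mr(c(4, 4))
  net <- build_network(c("g01", "g05"), mr, n_retrieved_per_query = 3,
                       edges_per_gene = 2)
  subs <- detect_subnetworks(net, method = "components")
  expect_gte(length(subs), 2)
  # a clique plus an isolated node: the clique survives as one subnetwork
  net2 <- build_network("g01", mr, n_retrieved_per_query = 3,
                        edges_per_gene = 3)
  net2$nodes <- rbind(net2$nodes,
                      data.frame(gene = "g08", role = "retrieved"))
  subs2 <- detect_subnetworks(net2)
  expect_true(any(vapply(subs2, function(s)
    identical(s$members, sprintf("g%02d", 1:4)), logical(1))))
  expect_true(any(vapply(subs2, function(s)
    identical(s$members, "g08"), logical(1))))
})

test_that("network construction is deterministic", {
  mr <- block_mr(c(5, 5), n_bg = 10)
  n1 <- build_network(c("g01", "g06"), mr)
  n2 <- build_network(c("g01", "g06"), mr)
  expect_identical(n1, n2)
  expect_identical(detect_subnetworks(n1), detect_subnetworks(n2))
})

test_that("enrichment p-values match exact combinatorics", {
  bg <- sprintf("g%02d", 1:20)
  cats <- setNames(rep(list("T"), 5), bg[1:5])
  # subnetwork = exactly the 5 carriers: p = 1 / C(20,5)
  res <- enrich(bg[1:5], cats, bg)
  expect_equal(res$p[res$category == "T"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(1 / choose(20, 5), 1 / 15504)
  # category absent from the subnetwork -> raw p = 1
  cats2 <- c(cats, setNames(list("U"), bg[6]))
  res2 <- enrich(bg[7:10], cats2, bg)
  expect_equal(res2$p[res2$category == "U"], 1)
  # corrected p never below raw p and capped at 1
  expect_true(all(res2$p_bonferroni >= res2$p))
  expect_true(all(res2$p_bonferroni <= 1))
  expect_error(enrich(bg[1:2], cats, character(0)), "background")
})

test_that("enrichment agrees with an exact combinatorial oracle on small instances", {
  set.seed(62)
  for (rep in 1:10) {
    N <- sample(10:30, 1)
    bg <- sprintf("b%02d", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    carriers <- sample(bg, K)
    members <- sample(bg, n)
    x <- sum(members %in% carriers)
    res <- enrich(members, setNames(rep(list("T"), K), carriers), bg)
    # oracle: sum the hypergeometric pmf by explicit combinatorics
    oracle <- sum(vapply(x:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
    expect_equal(res$p, oracle, tolerance = 1e-10)
  }
})

test_that("promoter heptamer scanning clips the window and handles edge cases", {
  set.seed(63)
  prom <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  h <- promoter_heptamers(prom)
  expect_lte(length(h), 294)              # 300 - 7 + 1 windows
  expect_equal(promoter_heptamers(strrep("A", 300)), "AAAAAAA")
  expect_warning(h0 <- promoter_heptamers("ACGT"), "shorter")
  expect_equal(h0, character(0))
  # only the last `window` nt are scanned
  prom2 <- paste0(strrep("C", 300), strrep("A", 300))
  expect_false("CCCCCCC" %in% promoter_heptamers(prom2, window = 300))
  # a planted motif inside [-300, -1] is recovered
  prom3 <- strrep("A", 300)
  substr(prom3, 151, 157) <- "TGACGTC"
  expect_true("TGACGTC" %in% promoter_heptamers(prom3))
})

test_that("a planted heptamer attains the smallest corrected p in its subnetwork", {
  cfg <- small_cfg(seed = 64)
  sq <- gen_sequences(cfg)
  truth <- sq$truth
  carriers <- fx_gene("Ath", truth$carriers)
  bg <- fx_gene("Ath", setdiff(seq_len(cfg$n_genes), truth$low_genes))
  sets <- promoter_heptamer_sets(sq$promoters[bg])
  res <- enrich(carriers, sets, bg)
  expect_equal(res$category[1], cfg$planted_heptamer)
  expect_lt(res$p_bonferroni[1], 0.05)
})

test_that("support flags mark edges strong in another dataset", {
  mr <- block_mr(c(4), n_bg = 4)
  net <- build_network("g01", mr, n_retrieved_per_query = 3)
  other <- mr          # same table: all edges supported at their own MR
  net2 <- flag_supported_edges(net, list(other), strong_mr = 500)
  expect_true(all(net2$edges$supported))
  # an unrelated weak table supports nothing
  weak <- mr; weak[] <- 1000; diag(weak) <- NA
  net3 <- flag_supported_edges(net, list(weak), strong_mr = 500)
  expect_false(any(net3$edges$supported))
})

test_that("network exports round-trip structure to GraphML and TSV", {
  mr <- block_mr(c(5, 5))
  net <- build_network(c("g01", "g06"), mr)
  net <- flag_supported_edges(net, list(mr))
  g1 <- file.path(tempdir(), "net.graphml")
  t1 <- file.path(tempdir(), "net.tsv")
  write_network_graphml(net, g1)
  write_network_edges(net, t1)
  gg <- igraph::read_graph(g1, format = "graphml")
  expect_equal(igraph::vcount(gg), nrow(net$nodes))
  expect_equal(igraph::ecount(gg), nrow(net$edges))
  ed <- read.delim(t1)
  expect_equal(nrow(ed), nrow(net$edges))
  expect_true(all(c("from", "to", "mr", "supported") %in% names(ed)))
})
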