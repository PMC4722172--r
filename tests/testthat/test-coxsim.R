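test_that("list restriction removes genes without counterparts, keeping order", {
  lg0 <- rl(c("A", "B", "X"), universe = c("A", "B", "X"))
  lr0 <- rl(c("b", "a"), universe = c("a", "b"))
  fwd <- c(A = "a", B = "b")            # X unmapped
  rev <- c(a = "A", b = "B")
  out <- restrict_lists(lg0, lr0, fwd, rev)
  expect_equal(out$list_g$genes, c("A", "B"))
  expect_equal(out$list_r$genes, c("b", "a"))
  expect_false(out$empty)

  # identity case: all genes mapped, lists unchanged
  la <- rl(c("A", "B"), universe = c("A", "B"))
  lb <- rl(c("B", "A"), universe = c("A", "B"))
  out2 <- restrict_lists(la, lb)
  expect_equal(out2$list_g$genes, la$genes)
  expect_equal(out2$list_r$genes, lb$genes)

  # degenerate: nothing maps
  out3 <- restrict_lists(lg0, lr0, c(Q = "q"), c(q = "Q"))
  expect_true(out3$empty)
  expect_length(out3$list_g$genes, 0)
})

test_that("COXSIM reproduces the hand-enumerated 3-gene example", {
  lg <- rl(c("A", "B", "C"))
  lr <- rl(c("B", "A", "D"))
  v <- coxsim(lg, lr, k = 3)            # n(i) = (0, 2, 2)
  expect_equal(as.numeric(v), 4 / 6)
  expect_equal(attr(v, "k"), 3L)
})

test_that("COXSIM hits its boundary values", {
  lg <- rl(paste0("g", 1:50))
  expect_equal(as.numeric(coxsim(lg, lg, k = 10)), 1)  # identical lists
  disjoint <- rl(paste0("h", 1:50))
  expect_equal(as.numeric(coxsim(lg, disjoint, k = 10)), 0)
  # default k is the top 1 percent, at least 1
  expect_equal(attr(coxsim(lg, lg), "k"), 1L)
  lg200 <- rl(paste0("g", 1:200))
  expect_equal(attr(coxsim(lg200, lg200), "k"), 2L)
  expect_error(coxsim(lg, lg, k = 0), "k")
  expect_error(coxsim(lg, lg, k = 51), "k")
  expect_error(coxsim(rl(character(0)), lg), "empty")
})

test_that("COXSIM equals the brute-force prefix-counting oracle on random pairs", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    univ <- paste0("u", 1:n)
    ga <- sample(univ)
    gb <- sample(univ)
    k <- sample(1:n, 1)
    got <- as.numeric(coxsim(rl(ga, univ), rl(gb, univ), k = k))
    expect_equal(got, oracle_coxsim(ga, gb, k = k))
  }
  # with a non-identity correspondence map
  for (rep in 1:20) {
    ga <- sample(paste0("a", 1:30))
    gb <- sample(paste0("b", 1:30))
    map <- setNames(paste0("b", 1:30), paste0("a", 1:30))
    k <- sample(1:30, 1)
    got <- as.numeric(coxsim(rl(ga), rl(gb), fwd = map, k = k))
    expect_equal(got, oracle_coxsim(ga, gb, map = map, k = k))
  }
})

test_that("COXSIM ignores reordering below the prefix depth k", {
  set.seed(7)
  ga <- sample(paste0("g", 1:40))
  gb <- sample(paste0("g", 1:40))
  k <- 5
  base <- as.numeric(coxsim(rl(ga), rl(gb), k = k))
  for (i in 1:10) {
    gb2 <- c(gb[1:k], sample(gb[(k + 1):40]))
    ga2 <- c(ga[1:k], sample(ga[(k + 1):40]))
    expect_equal(as.numeric(coxsim(rl(ga2), rl(gb2), k = k)), base)
  }
})

test_that("reference sets use same-species identity and cross-species best hits", {
  mr <- random_mr(10, seed = 1, prefix = "A_g")
  mr2 <- random_mr(10, seed = 2, prefix = "A_g")
  mrB <- random_mr(10, seed = 3, prefix = "B_g")
  ds <- list(
    "spA-1" = coex_dataset("spA-1", "spA", mr),
    "spA-2" = coex_dataset("spA-2", "spA", mr2),
    "spB-1" = coex_dataset("spB-1", "spB", mrB))
  bh <- list("spA->spB" = c(A_g001 = "B_g004"),
             "spB->spA" = c(B_g004 = "A_g001"))
  refs <- build_reference_set("A_g001", "spA-1", ds, bh)
  expect_equal(refs$dataset, c("spA-2", "spB-1"))
  expect_equal(refs$gene, c("A_g001", "B_g004"))

  # best hit absent from the reference dataset's table -> dataset skipped
  bh2 <- list("spA->spB" = c(A_g001 = "B_missing"))
  refs2 <- build_reference_set("A_g001", "spA-1", ds, bh2)
  expect_equal(refs2$dataset, "spA-2")

  # no other datasets -> empty reference set, guide unassessable
  refs3 <- build_reference_set("A_g001", "spA-1", ds["spA-1"], bh)
  expect_equal(nrow(refs3), 0)
  res <- max_coxsim("A_g001", "spA-1", ds["spA-1"], bh)
  expect_false(res$assessable)
  expect_true(is.na(res$max_coxsim))
})

test_that("maxCOXSIM takes the maximum over references and is monotone in references", {
  mr <- random_mr(20, seed = 4, prefix = "A_g")
  ds_all <- list(
    "d1" = coex_dataset("d1", "spA", mr),
    "d2" = coex_dataset("d2", "spA", mr),                 # identical copy
    "d3" = coex_dataset("d3", "spA", random_mr(20, seed = 5, prefix = "A_g")))
  g <- "A_g001"
  with_copy <- max_coxsim(g, "d1", ds_all)
  expect_equal(with_copy$max_coxsim, 1)                   # identical table
  expect_equal(with_copy$best_dataset, "d2")
  fewer <- max_coxsim(g, "d1", ds_all[c("d1", "d3")])
  expect_lte(fewer$max_coxsim, with_copy$max_coxsim)      # max can only grow
})

test_that("null distributions live in [0,1] and match a permutation oracle mean", {
  mr_a <- random_mr(300, n_samples = 15, seed = 6, prefix = "a")
  mr_b <- random_mr(300, n_samples = 15, seed = 7, prefix = "a")
  expect_warning(nl <- build_null(mr_a, mr_b, max_pairs = 600, seed = 1),
                 "fewer than 1000")
  expect_true(all(nl >= 0 & nl <= 1))
  expect_false(is.unsorted(nl))

  # independent permutation oracle: COXSIM of freshly permuted lists
  set.seed(8)
  k <- max(1L, ceiling(0.01 * 299))
  oracle <- replicate(600, {
    oracle_coxsim(sample(paste0("a", 1:299)), sample(paste0("a", 1:299)),
                  k = k)
  })
  se <- sqrt(var(oracle) / length(oracle) + var(nl) / length(nl))
  expect_lt(abs(mean(nl) - mean(oracle)), 3 * se)
})

test_that("empirical thresholds follow the survival rule with Bonferroni division", {
  nl <- structure(sort(c(rep(0, 90), seq(0.1, 1, length.out = 10))),
                  class = "null_distribution")
  # survival at 0.1 is 10/100 = 0.1 -> alpha = 0.1, one list
  th <- coxsim_thresholds(nl, n_reference_lists = 1, alphas = c(0.1, 0.05))
  expect_equal(unname(th[1]), 0.1)
  # alpha 0.1 over 2 lists -> target 0.05 -> survival must drop to <= 0.05
  th2 <- coxsim_thresholds(nl, n_reference_lists = 2, alphas = 0.1)
  expect_equal(unname(th2[1]), sort(unique(as.numeric(nl)))[7])  # surv 5/100
  expect_true(all(diff(suppressWarnings(coxsim_thresholds(nl, 1))) >= 0))
  # unreachable corrected level -> above the max sample, with warning
  expect_warning(th3 <- coxsim_thresholds(nl, 1000, alphas = 0.001),
                 "resolution")
  expect_gt(unname(th3[1]), max(nl))
})

test_that("star ratings match the published genome-scale thresholds", {
  th <- c("p<0.1" = 0.081, "p<0.01" = 0.189, "p<0.001" = 0.377)
  expect_equal(coxsim_stars(0.20, th), 2L)
  expect_equal(coxsim_stars(0.05, th), 0L)
  expect_equal(coxsim_stars(0.40, th), 3L)
  expect_true(is.na(coxsim_stars(NA_real_, th)))
})

test_that("stars are non-decreasing in maxCOXSIM against any fixed null", {
  set.seed(9)
  nl <- structure(sort(runif(2000)^3), class = "null_distribution")
  th <- suppressWarnings(coxsim_thresholds(nl, n_reference_lists = 3))
  x <- sort(runif(200))
  s <- coxsim_stars(x, th)
  expect_true(all(diff(s) >= 0))
})
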