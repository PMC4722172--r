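#' Configuration for the synthetic fixture generator
#'
#' The generator emulates the multi-species, multi-platform study design the
#' toolkit targets: two clades (dicot-like and monocot-like) with two species
#' each, and two coexpression datasets per species (an "-a" and a "-b"
#' platform). Planted coexpression modules are either conserved across all
#' species or active in one clade only; low-depth runs and low-expression
#' genes are planted to exercise the quality filters; sequences, GO
#' annotations and bitscore tables carry matching planted structure.
#' A single seed fixes every random draw.
#'
#' @param seed Integer master seed.
#' @param n_genes Genes per species (default 400).
#' @param n_runs Sequencing runs per dataset (default 48).
#' @param n_experiments Experiments the runs are grouped into for quantile
#'   normalization (default 4).
#' @param species Named character vector species id -> clade (default the
#'   Ath/Gma dicot, Osa/Zma monocot design).
#' @param datasets_per_species Datasets per species (default 2).
#' @param module_size Genes per planted module (default 10).
#' @param n_conserved Modules active in every species (default 2).
#' @param n_per_clade Modules active in one clade only, per clade
#'   (default 2).
#' @param within_cor Latent-factor correlation shared by module genes in an
#'   active dataset (default 0.8).
#' @param log2_sd Biological spread of a gene across runs on the log2 scale
#'   (default 2).
#' @param run_depth Target mapped reads of a good run (default 2e7).
#' @param low_depth Depth of planted low-quality runs, below the 1e7 filter
#'   (default 6e6).
#' @param n_low_runs Planted low-quality runs per dataset (default 2).
#' @param n_low_genes Planted low-expression genes per species whose peak
#'   count stays below 100 (default 5).
#' @param cds_codon_range Range of CDS lengths in sense codons
#'   (default 100-300).
#' @param n_isoforms Genes per species that also emit a shorter second
#'   isoform, exercising the longest-sequence rule (default 5).
#' @param promoter_length Promoter length in nt (default 300).
#' @param planted_heptamer 7-mer inserted into carrier promoters
#'   (default "TGACGTC").
#' @param carrier_fraction Fraction of the first conserved module's genes
#'   carrying the planted heptamer (default 1).
#' @param bitscore_noise Fraction of ortholog pairs whose reciprocity is
#'   broken in the bitscore tables (default 0).
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 17L,
                           n_genes = 400L, n_runs = 48L, n_experiments = 4L,
                           species = c(Ath = "dicot", Gma = "dicot",
                                       Osa = "monocot", Zma = "monocot"),
                           datasets_per_species = 2L,
                           module_size = 10L, n_conserved = 2L,
                           n_per_clade = 2L, within_cor = 0.8,
                           log2_sd = 2, run_depth = 2e7, low_depth = 6e6,
                           n_low_runs = 2L, n_low_genes = 5L,
                           cds_codon_range = c(100L, 300L),
                           n_isoforms = 5L,
                           promoter_length = 300L,
                           planted_heptamer = "TGACGTC",
                           carrier_fraction = 1,
                           bitscore_noise = 0) {
  clades <- sort(unique(species))
  if (length(clades) != 2L) stop("exactly two clades required")
  n_modules <- n_conserved + 2L * n_per_clade
  if (n_modules * module_size + n_low_genes > n_genes)
    stop("modules plus low-expression genes exceed n_genes")
  if (within_cor <= 0 || within_cor >= 1)
    stop("'within_cor' must be in (0, 1)")
  if (nchar(planted_heptamer) != 7L ||
      grepl("[^ACGT]", planted_heptamer))
    stop("'planted_heptamer' must be a 7-mer over ACGT")
  cfg <- as.list(environment())
  cfg$clades <- clades
  cfg$n_modules <- n_modules
  # module clade assignment: conserved modules first, then per-clade blocks
  cfg$module_clade <- c(rep("all", n_conserved),
                        rep(clades[1L], n_per_clade),
                        rep(clades[2L], n_per_clade))
  structure(cfg, class = "fixture_config")
}

.fx_genes <- function(cfg, sp) sprintf("%s_g%04d", sp, seq_len(cfg$n_genes))

# module of each gene index: 1..n_modules, NA for background;
# low-expression genes occupy the last n_low_genes indices
.fx_module_of <- function(cfg) {
  m <- rep(NA_integer_, cfg$n_genes)
  for (j in seq_len(cfg$n_modules))
    m[((j - 1L) * cfg$module_size + 1L):(j * cfg$module_size)] <- j
  m
}

.fx_low_idx <- function(cfg)
  (cfg$n_genes - cfg$n_low_genes + 1L):cfg$n_genes

#' Planted ground truth of a fixture configuration
#'
#' @param cfg [fixture_config()].
#' @return List with `modules` (`data.frame(index, module, clade)`, module
#'   `NA` for background genes; the gene of species S at index i is
#'   `<S>_g<i>`), `orthologs` (same index = planted ortholog across
#'   species), `low_genes` (indices planted below the peak-count filter),
#'   `carriers` (indices carrying the planted heptamer) and `clades`.
#' @export
planted_truth <- function(cfg) {
  mod <- .fx_module_of(cfg)
  clade <- ifelse(is.na(mod), NA_character_, cfg$module_clade[mod])
  carriers <- which(mod == 1L)
  carriers <- carriers[seq_len(max(1L, round(cfg$carrier_fraction *
                                             length(carriers))))]
  list(modules = data.frame(index = seq_len(cfg$n_genes), module = mod,
                            clade = clade, stringsAsFactors = FALSE),
       orthologs = seq_len(cfg$n_genes),
       low_genes = .fx_low_idx(cfg),
       carriers = carriers,
       clades = cfg$species)
}

#' Generate count matrices for every synthetic dataset
#'
#' Counts follow a latent-factor log-normal/Poisson scheme: each gene has a
#' baseline abundance; in datasets where its module is active, module genes
#' share a per-run latent factor with loading `sqrt(within_cor)`, producing
#' the planted within-module correlation after the log transform. Column
#' abundances are renormalized per run so each run hits its target depth,
#' with `n_low_runs` runs planted below the total-mapped-count filter and
#' `n_low_genes` genes planted below the peak-count filter.
#'
#' @param cfg [fixture_config()].
#' @return List with `counts` (named list of count matrices, one per
#'   dataset, e.g. `"Ath-a"`), `experiments` (named list of run ->
#'   experiment vectors) and `truth` ([planted_truth()]).
#' @export
gen_expression_datasets <- function(cfg) {
  set.seed(cfg$seed)
  truth <- planted_truth(cfg)
  mod <- truth$modules$module
  low <- truth$low_genes
  out_counts <- list()
  out_exp <- list()
  for (sp in names(cfg$species)) {
    clade <- cfg$species[[sp]]
    genes <- .fx_genes(cfg, sp)
    # baseline relative abundance, shared across the species' datasets
    w <- 2^stats::rnorm(cfg$n_genes, 0, 1.5)
    w[low] <- 1e-6 * sum(w[-low])          # peak count stays well below 100
    for (d in seq_len(cfg$datasets_per_species)) {
      id <- paste0(sp, "-", letters[d])
      runs <- sprintf("%s_run%02d", id, seq_len(cfg$n_runs))
      expt <- sprintf("exp%d", rep_len(seq_len(cfg$n_experiments),
                                       cfg$n_runs))
      names(expt) <- runs
      active <- !is.na(mod) & cfg$module_clade[ifelse(is.na(mod), 1L, mod)] %in%
        c("all", clade)
      fac <- matrix(stats::rnorm(cfg$n_modules * cfg$n_runs),
                    cfg$n_modules, cfg$n_runs)
      eps <- matrix(stats::rnorm(cfg$n_genes * cfg$n_runs),
                    cfg$n_genes, cfg$n_runs)
      x <- sqrt(1 - cfg$within_cor) * eps
      x[active, ] <- x[active, ] +
        sqrt(cfg$within_cor) * fac[mod[active], ]
      x[!active & !is.na(mod), ] <- eps[!active & !is.na(mod), ]
      x <- cfg$log2_sd * x
      x[low, ] <- 0.25 * x[low, ]          # keep planted low genes low
      q <- w * 2^x
      q <- sweep(q, 2L, colSums(q), "/")
      depth <- rep(cfg$run_depth, cfg$n_runs)
      if (cfg$n_low_runs > 0L)
        depth[seq_len(cfg$n_low_runs)] <- cfg$low_depth
      lambda <- sweep(q, 2L, depth, "*")
      cnt <- matrix(stats::rpois(length(lambda), lambda),
                    cfg$n_genes, cfg$n_runs,
                    dimnames = list(genes, runs))
      out_counts[[id]] <- cnt
      out_exp[[id]] <- expt
    }
  }
  list(counts = out_counts, experiments = out_exp, truth = truth)
}

#' Generate CDS and promoter sequences with planted structure
#'
#' CDS: an ATG start, a body drawn from the 61 sense codons (so internally
#' stop-free and divisible by 3) and a TAA stop. Genes of odd-numbered
#' modules draw their codons from a module-specific biased codon
#' distribution, so codon-usage similarity mirrors module membership for
#' half of the modules; all other genes draw from gene-specific
#' distributions. A few genes emit a second, shorter isoform under the same
#' gene id. Promoters are uniform random with the planted heptamer inserted
#' mid-window in carrier genes.
#'
#' @param cfg [fixture_config()].
#' @return List with `cds` and `promoters` (named
#'   [Biostrings::DNAStringSet], one entry per species gene, plus isoform
#'   records named `"<gene> iso2"`), and `truth`.
#' @export
gen_sequences <- function(cfg) {
  set.seed(cfg$seed + 1L)
  truth <- planted_truth(cfg)
  mod <- truth$modules$module
  biased <- !is.na(mod) & mod %% 2L == 1L      # codon-aligned modules
  module_probs <- lapply(seq_len(cfg$n_modules), function(j) {
    p <- stats::runif(61)^4
    p / sum(p)
  })
  draw_cds <- function(n_codons, prob) {
    body <- sample(SENSE_CODONS, n_codons - 1L, replace = TRUE, prob = prob)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  cds <- character(0); prom <- character(0)
  for (sp in names(cfg$species)) {
    genes <- .fx_genes(cfg, sp)
    for (i in seq_len(cfg$n_genes)) {
      ncod <- sample(seq(cfg$cds_codon_range[1L], cfg$cds_codon_range[2L]),
                     1L)
      prob <- if (biased[i]) module_probs[[mod[i]]] else {
        p <- stats::runif(61)^2; p / sum(p)
      }
      cds[[genes[i]]] <- draw_cds(ncod, prob)
      p <- paste(sample(c("A", "C", "G", "T"), cfg$promoter_length,
                        replace = TRUE), collapse = "")
      if (i %in% truth$carriers) {
        pos <- cfg$promoter_length - 150L      # inside [-300, -1]
        substr(p, pos, pos + 6L) <- cfg$planted_heptamer
      }
      prom[[genes[i]]] <- p
    }
    iso <- genes[seq_len(min(cfg$n_isoforms, cfg$n_genes))]
    for (g in iso) {
      short <- max(3L, nchar(cds[[g]]) %/% 6L * 3L)
      cds[[paste(g, "iso2")]] <- substr(cds[[g]], 1L, short)
    }
  }
  list(cds = Biostrings::DNAStringSet(cds),
       promoters = Biostrings::DNAStringSet(prom),
       truth = truth)
}

#' Generate pairwise Blastp-like bitscore tables
#'
#' Self tables carry maximal self-scores; cross-species tables give the
#' planted ortholog the highest (reciprocal) score plus lower-scoring decoy
#' hits. A configured fraction of ortholog pairs has its reciprocity broken
#' (the reverse direction's best hit is redirected to a decoy), lowering RBH
#' recall by exactly that fraction.
#'
#' @param cfg [fixture_config()].
#' @return List with `tables` (named list of [bitscore_table()] keyed
#'   `"<spA>-><spB>"`, including self tables) and `truth`.
#' @export
gen_bitscores <- function(cfg) {
  set.seed(cfg$seed + 2L)
  truth <- planted_truth(cfg)
  sps <- names(cfg$species)
  self_score <- lapply(sps, function(sp)
    round(stats::runif(cfg$n_genes, 300, 600)))
  names(self_score) <- sps
  # adequacy of the planted ortholog, per unordered species pair
  adequacy <- list()
  for (a in sps) for (b in sps) if (a < b) {
    same_clade <- cfg$species[[a]] == cfg$species[[b]]
    base <- if (same_clade) 0.7 else 0.5
    adequacy[[paste(a, b)]] <- stats::runif(cfg$n_genes, base - 0.1,
                                            base + 0.1)
  }
  n_break <- floor(cfg$bitscore_noise * cfg$n_genes)
  tables <- list()
  for (a in sps) {
    ga <- .fx_genes(cfg, a)
    tables[[paste0(a, "->", a)]] <- bitscore_table(
      data.frame(query = ga, subject = ga,
                 bitscore = self_score[[a]], stringsAsFactors = FALSE),
      a, a)
    for (b in setdiff(sps, a)) {
      gb <- .fx_genes(cfg, b)
      adq <- adequacy[[paste(min(a, b), max(a, b))]]
      best <- round(self_score[[a]] * adq)
      broken <- if (n_break > 0L && a > b) seq_len(n_break) else integer(0)
      subj_idx <- seq_len(cfg$n_genes)
      # redirect the broken queries' best hit away from the ortholog
      subj_idx[broken] <- (broken %% cfg$n_genes) + 1L
      decoy1 <- ((seq_len(cfg$n_genes) + 6L) %% cfg$n_genes) + 1L
      rec <- data.frame(
        query = rep(ga, 2L),
        subject = c(gb[subj_idx], gb[decoy1]),
        bitscore = c(best, round(0.4 * best)),
        stringsAsFactors = FALSE)
      rec <- rec[rec$query != rec$subject | a != b, ]
      tables[[paste0(a, "->", b)]] <- bitscore_table(rec, a, b)
    }
  }
  list(tables = tables, truth = truth)
}

#' Generate gene -> GO-term annotations with planted structure
#'
#' Every planted module gets a term annotating its genes (size inside the
#' 5-20 selection window); one term of size 4 and one of size 21 are emitted
#' to exercise the window's edges; background genes receive random terms.
#' Terms are shared across species through the planted ortholog indexing.
#'
#' @param cfg [fixture_config()].
#' @param n_background_terms Random background terms (default 30).
#' @return List with `annotations` (`data.frame(gene, term)` over all
#'   species' genes) and `truth`.
#' @export
gen_go <- function(cfg, n_background_terms = 30L) {
  set.seed(cfg$seed + 3L)
  truth <- planted_truth(cfg)
  mod <- truth$modules$module
  bg_idx <- which(is.na(mod))
  bg_idx <- setdiff(bg_idx, truth$low_genes)
  rows <- list()
  add <- function(idx, term) {
    for (sp in names(cfg$species))
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = .fx_genes(cfg, sp)[idx], term = term,
        stringsAsFactors = FALSE)
  }
  for (j in seq_len(cfg$n_modules))
    add(which(mod == j), sprintf("GO:MOD%04d", j))
  add(bg_idx[1:4],  "GO:EDGE0004")     # below the 5-gene window
  add(bg_idx[5:25], "GO:EDGE0021")     # above the 20-gene window
  for (t in seq_len(n_background_terms)) {
    size <- sample(3:25, 1L)
    add(sample(bg_idx, size), sprintf("GO:BG%05d", t))
  }
  ann <- unique(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  list(annotations = ann, truth = truth)
}

#' Lineage-classification thresholds at fixture scale
#'
#' The genome-scale defaults of [classify_lineage()] (strong MR < 500, weak
#' MR > 5000) presume tables of ~20k genes whose background MR distribution
#' peaks near half the gene count. A fixture table of `n_genes` genes has MR
#' bounded by `n_genes - 1`, so the thresholds must be restated at fixture
#' scale: strong coexpression is anything comfortably above the planted
#' module's internal rank range (module genes occupy each other's top
#' `module_size - 1` ranks) yet far below background, and weak is placed
#' well below the bulk of the background geometric-average MR distribution
#' (median near `exp(log(n) - 1)`, i.e. ~0.37 n, with a log-scale spread of
#' ~0.5 after averaging over four datasets — the two directed ranks of a
#' pair are driven by the same correlation and so do not halve the
#' variance). The fractions 0.04 and 0.10 of the gene count leave ~2 log-SD
#' margins on both sides for the default module size.
#'
#' @param cfg [fixture_config()].
#' @return Named numeric vector with `strong_mr` and `weak_mr`.
#' @export
fixture_lineage_thresholds <- function(cfg) {
  c(strong_mr = 0.04 * cfg$n_genes, weak_mr = 0.10 * cfg$n_genes)
}

#' Write a complete fixture set to disk
#'
#' Emits every input the toolkit consumes — count matrices with run
#' metadata, CDS and promoter FASTA, GO annotations, bitscore tables — plus
#' a `truth.json` describing the planted structure. All files are plain
#' text and round-trip through the package readers.
#'
#' @param cfg [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- gen_expression_datasets(cfg)
  sq <- gen_sequences(cfg)
  bs <- gen_bitscores(cfg)
  go <- gen_go(cfg)
  for (id in names(ex$counts)) {
    write_count_matrix(ex$counts[[id]],
                       file.path(dir, paste0(id, ".counts.tsv")))
    utils::write.table(
      data.frame(run_id = names(ex$experiments[[id]]),
                 experiment_id = unname(ex$experiments[[id]])),
      file.path(dir, paste0(id, ".runs.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  Biostrings::writeXStringSet(sq$cds, file.path(dir, "cds.fa"))
  Biostrings::writeXStringSet(sq$promoters, file.path(dir, "promoters.fa"))
  utils::write.table(go$annotations, file.path(dir, "go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(bs$tables)) {
    fn <- file.path(dir, paste0("bitscore.", sub("->", "_", key, fixed = TRUE),
                                ".tsv"))
    utils::write.table(as.data.frame(bs$tables[[key]]), fn,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- ex$truth
  truth$modules <- truth$modules[!is.na(truth$modules$module), ]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
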