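test_that("the ancestor generator conserves gene counts and ORF structure", {
  g <- simulate_ancestor(10, mean_gene_len = 300, seed = 71)
  expect_equal(sum(g$features$kind == "CDS"), 10)
  expect_true(all(g$features$status == "functional"))
  prots <- cds_proteins(g, quiet = TRUE)
  nts <- feature_seqs(g)
  # every gene is a clean ORF: starts ATG, ends on a stop, no internal stop
  expect_true(all(substr(nts, 1, 3) == "ATG"))
  expect_true(all(substr(nts, nchar(nts) - 2, nchar(nts)) %in%
                    c("TAA", "TAG", "TGA")))
  expect_equal(unname(nchar(prots)), unname(nchar(nts)) / 3 - 1)
})

test_that("realised GC tracks the requested fraction", {
  g <- simulate_ancestor(100, mean_gene_len = 900, gc_frac = 0.5, seed = 72)
  bases <- strsplit(g$contigs[[1]], "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_gt(genome_length(g), 80000)
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("generation is deterministic: same seed gives byte-identical files", {
  d <- withr::local_tempdir()
  for (run in 1:2) {
    g <- simulate_ancestor(15, seed = 73)
    write_genome(g, file.path(d, paste0("r", run, ".fa")),
                 file.path(d, paste0("r", run, ".gff3")))
  }
  expect_identical(readLines(file.path(d, "r1.fa")),
                   readLines(file.path(d, "r2.fa")))
  expect_identical(readLines(file.path(d, "r1.gff3")),
                   readLines(file.path(d, "r2.gff3")))
  g_a <- simulate_ancestor(15, seed = 73)
  g_b <- simulate_ancestor(15, seed = 74)
  expect_false(identical(g_a$contigs, g_b$contigs))
})

test_that("a no-op degradation returns the ancestor unchanged", {
  anc <- simulate_ancestor(12, seed = 75)
  deg <- degrade_genome(anc, degradation_params(
    deletion_frac = 0, pseudo_frac = 0, rng_seed = 76))
  expect_identical(deg$genome$contigs[[1]], anc$contigs[[1]])
  expect_equal(as.data.frame(deg$genome$features),
               as.data.frame(anc$features))
  expect_true(all(deg$truth$fates$fate == "retained"))
})

test_that("pseudogene counts fall in the binomial 99% interval", {
  anc <- simulate_ancestor(1000, mean_gene_len = 300, intergenic_len = 40,
                           seed = 77)
  deg <- degrade_genome(anc, degradation_params(
    deletion_frac = 0, pseudo_frac = 0.3, rng_seed = 78))
  n_pg <- sum(deg$truth$fates$fate == "pseudogenized")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(n_pg, ci[1])
  expect_lte(n_pg, ci[2])
  # fates partition the ancestral gene set
  expect_setequal(deg$truth$fates$feature_id, anc$features$feature_id)
  expect_true(all(deg$truth$fates$fate %in%
                    c("retained", "deleted", "pseudogenized")))
})

test_that("protected clusters receive no TE insertions", {
  anc <- simulate_ancestor(80, seed = 79,
                           cluster = list(category = "core_cluster",
                                          start = 30, n = 20))
  deg <- degrade_genome(anc, degradation_params(
    deletion_frac = 0, pseudo_frac = 0, te_pseudo_frac = 0,
    te_bursts = list(list(family_id = "IS5", n_copies = 120,
                          sub_rate = 0.02, trunc_prob = 0.2,
                          trunc_range = c(0.4, 0.9))),
    protected_categories = "core_cluster", rng_seed = 80))
  prot <- deg$truth$protected
  expect_equal(nrow(prot), 1)
  expect_gt(prot$end - prot$start, 20000)
  te <- deg$truth$te_copies
  expect_equal(nrow(te), 120)
  inside <- te$start >= prot$start & te$end <= prot$end
  expect_equal(sum(inside), 0)
})

test_that("TE insertion demands enough intergenic room", {
  anc <- simulate_ancestor(5, mean_gene_len = 300, intergenic_len = 5,
                           seed = 81)
  expect_error(degrade_genome(anc, degradation_params(
    deletion_frac = 0, pseudo_frac = 0,
    te_bursts = list(list(family_id = "IS5", n_copies = 10, sub_rate = 0,
                          trunc_prob = 0, trunc_range = c(0.4, 0.9))),
    tsd_len = 10, rng_seed = 82)), "exhausted")
})

test_that("simulated alignments match closed-form JC expectations", {
  tr2 <- ape::read.tree(text = "(A:0.05,B:0.05);")
  jc <- substitution_model("jc")
  aln <- simulate_alignment(tr2, jc, 1e5, seed = 83)
  pdiff <- mean(strsplit(aln$seqs[1], "")[[1]] !=
                  strsplit(aln$seqs[2], "")[[1]])
  want <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(want * (1 - want) / 1e5)
  expect_lt(abs(pdiff - want), 3 * se)
})

test_that("simulated base frequencies match the stationary distribution", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3);")
  pi <- c(0.4, 0.1, 0.2, 0.3)
  m <- substitution_model("gtr", freqs = pi)
  aln <- simulate_alignment(tr, m, 1e5, seed = 84)
  obs <- table(factor(strsplit(aln$seqs[["A"]], "")[[1]],
                      levels = c("A", "C", "G", "T"))) / 1e5
  for (b in 1:4) {
    se <- sqrt(pi[b] * (1 - pi[b]) / 1e5)
    expect_lt(abs(obs[[b]] - pi[b]), 4 * se)
  }
})

test_that("a unit rate multiplier leaves foreground and background balanced", {
  tree <- local({
    set.seed(85)
    tr <- ape::rcoal(6)
    tr$edge.length <- tr$edge.length /
      max(ape::node.depth.edgelength(tr)) * 0.2
    tr
  })
  fg <- luxerode:::pick_foreground_clade(tree, 2)
  a1 <- simulate_alignment(tree, substitution_model("jc"), 2000,
                           foreground = fg, rate_multiplier = 1, seed = 86)
  a2 <- simulate_alignment(tree, substitution_model("jc"), 2000, seed = 86)
  expect_identical(a1$seqs, a2$seqs)
})

test_that("pileup simulation respects its error and polymorphism model", {
  g <- c(chr = strrep("ACGT", 500))
  p0 <- simulate_pileup(g, mean_depth = 50, error_rate = 0, seed = 87)
  s0 <- site_frequencies(dplyr::filter(p0, depth > 0))
  expect_true(all(s0$alt_freq == 0))

  poly <- tibble::tibble(contig = "chr", pos = 1000, alt = "C", freq = 0.5)
  p1 <- simulate_pileup(g, mean_depth = 1000, error_rate = 0,
                        polymorphic_sites = poly, seed = 88)
  row <- dplyr::filter(p1, pos == 1000)
  f <- row$C / row$depth
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / row$depth))

  expect_error(simulate_pileup(g, polymorphic_sites = tibble::tibble(
    contig = "chr", pos = 99999, alt = "C", freq = 0.5), seed = 89),
    "outside")

  p2 <- simulate_pileup(g, mean_depth = 30, error_rate = 1e-3, seed = 90)
  p3 <- simulate_pileup(g, mean_depth = 30, error_rate = 1e-3, seed = 90)
  expect_identical(p2, p3)
  expect_true(all(p2$A + p2$C + p2$G + p2$T == p2$depth))
})
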