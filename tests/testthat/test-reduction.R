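test_that("a genome against itself pairs every CDS at identity 100", {
  g <- simulate_ancestor(25, seed = 121)
  pairs <- ortholog_pairs(g, g)
  expect_equal(nrow(pairs), 25)
  expect_true(all(pairs$gene_id_a == pairs$gene_id_b))
  expect_true(all(pairs$identity == 100))
  expect_equal(ani(pairs), 100)
})

test_that("orthologs of a 5%-substituted copy show ~95% nucleotide identity", {
  anc <- simulate_ancestor(40, seed = 122)
  mut <- anc
  mut$genome_id <- "derived"
  mut$contigs <- vapply(anc$contigs, function(s) {
    luxerode:::with_seed(123, luxerode:::mutate_seq(s, 0.05))
  }, character(1))
  pairs <- ortholog_pairs(anc, mut)
  # substitution-induced internal stops truncate a few proteins enough to
  # lose reciprocity; the bulk of loci must still pair
  expect_gte(nrow(pairs), 30)
  expect_lt(abs(mean(pairs$identity) - 95), 0.5)
})

test_that("genes deleted from one genome yield no ortholog pair", {
  anc <- simulate_ancestor(30, seed = 124)
  deg <- degrade_genome(anc, degradation_params(
    deletion_frac = 0.3, pseudo_frac = 0, rng_seed = 125))
  pairs <- ortholog_pairs(anc, deg$genome)
  deleted <- deg$truth$fates$feature_id[deg$truth$fates$fate == "deleted"]
  expect_gt(length(deleted), 0)
  expect_length(intersect(pairs$gene_id_a, deleted), 0)
  retained <- deg$truth$fates$feature_id[deg$truth$fates$fate == "retained"]
  expect_setequal(pairs$gene_id_a, retained)
})

test_that("ANI is the length-weighted mean identity and is symmetric", {
  pairs <- tibble::tibble(gene_id_a = c("a", "b"), gene_id_b = c("x", "y"),
                          identity = c(80, 60), aligned_len = c(1000, 1000))
  expect_equal(ani(pairs), 70)
  pairs$aligned_len <- c(1000, 3000)
  expect_equal(ani(pairs), 65)
  expect_equal(ani(pairs, weighted = FALSE), 70)
  expect_error(ani(pairs[0, ]), "no ortholog")

  anc <- simulate_ancestor(20, seed = 126)
  deg <- degrade_genome(anc, degradation_params(
    deletion_frac = 0.1, pseudo_frac = 0.1, rng_seed = 127))
  a_to_b <- ani(ortholog_pairs(anc, deg$genome))
  b_to_a <- ani(ortholog_pairs(deg$genome, anc))
  expect_equal(a_to_b, b_to_a, tolerance = 1e-9)
})

test_that("percent reduction is exact arithmetic with sign preserved", {
  expect_equal(round(reduction_stats(1662, 5200)), 68)
  expect_equal(round(reduction_stats(2316, 5200)), 55)
  expect_equal(reduction_stats(5200, 5200), 0)
  expect_lt(reduction_stats(6000, 5200), 0)
  # strictly decreasing in the target count
  vals <- vapply(c(1000, 2000, 3000), reduction_stats, 1,
                 reference_mean_count = 5200)
  expect_true(all(diff(vals) < 0))
})

test_that("category counts honour multi-tagging and pseudogene exclusion", {
  empty <- lux_genome("e", c(c1 = "ACGTACGTACGT"))
  expect_equal(nrow(category_counts(empty)), 0)

  ft <- tibble::tibble(
    feature_id = c("g1", "g2", "g3"), contig_id = "c1",
    start = c(1L, 101L, 201L), end = c(90L, 190L, 290L), strand = "+",
    kind = "CDS", status = c("functional", "functional", "pseudogene"),
    product = "",
    category_tags = list(c("motility", "cell_wall"), "motility",
                         "motility"))
  g <- lux_genome("toy", c(c1 = strrep("A", 300)), ft)
  cc <- category_counts(g)
  expect_equal(cc$n[cc$category == "motility"], 2)
  expect_equal(cc$n[cc$category == "cell_wall"], 1)
  expect_equal(sum(cc$n), 3) # one gene in two categories counts twice
  cc2 <- category_counts(g, include_pseudogenes = TRUE)
  expect_equal(cc2$n[cc2$category == "motility"], 3)
  # counts match a known tag multiset exactly
  g2 <- simulate_ancestor(50, seed = 128)
  want <- sort(table(unlist(g2$features$category_tags)))
  got <- category_counts(g2)
  expect_equal(setNames(got$n, got$category)[names(want)],
               unclass(want)[names(want)], ignore_attr = TRUE)
})

test_that("pathway completeness requires every enzyme as a functional gene", {
  ft <- tibble::tibble(
    feature_id = paste0("g", 1:4), contig_id = "c1",
    start = c(1L, 101L, 201L, 301L), end = c(90L, 190L, 290L, 390L),
    strand = "+", kind = "CDS",
    status = c("functional", "functional", "functional", "pseudogene"),
    product = c("thrA", "thrB", "lysA", "lysC"),
    category_tags = rep(list(character()), 4))
  g <- lux_genome("toy", c(c1 = strrep("A", 400)), ft)
  defs <- tibble::tibble(
    pathway_id = c("threonine", "threonine", "lysine", "lysine"),
    enzyme = c("thrA", "thrB", "lysA", "lysC"))
  pc <- pathway_completeness(g, defs)
  per <- pc$per_pathway
  expect_true(per$complete[per$pathway_id == "threonine"])
  # lysC present only as a pseudogene: pathway incomplete
  expect_false(per$complete[per$pathway_id == "lysine"])
  expect_equal(per$n_present[per$pathway_id == "lysine"], 1)
  expect_equal(pc$n_complete, 1)
  # removing one enzyme breaks exactly that pathway
  defs2 <- rbind(defs, tibble::tibble(pathway_id = "threonine",
                                      enzyme = "thrC"))
  pc2 <- pathway_completeness(g, defs2)
  expect_false(pc2$per_pathway$complete[
    pc2$per_pathway$pathway_id == "threonine"])
})

test_that("the bundled synthetic pathway fixture loads and evaluates", {
  path <- system.file("extdata", "aa_pathways_synthetic.tsv",
                      package = "luxerode")
  expect_true(nzchar(path))
  defs <- read_pathways(path)
  expect_true(all(c("pathway_id", "enzyme") %in% names(defs)))
  expect_gte(dplyr::n_distinct(defs$pathway_id), 5)
})
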