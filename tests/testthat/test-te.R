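test_that("an exact reference copy is classified to its family at identity 1", {
  ref <- is_family_reference()
  cls <- classify_transposases(
    setNames(ref$protein[ref$family_id == "IS5"], "copy1"), ref)
  expect_equal(cls$family_id, "IS5")
  expect_equal(cls$identity_to_ref, 1)
  expect_gte(cls$aligned_fraction_of_ref, 0.99)
})

test_that("proteins unrelated to every reference stay unassigned", {
  ref <- is_family_reference()
  set.seed(101)
  junk <- paste(sample(c("A", "G"), 200, replace = TRUE), collapse = "")
  cls <- classify_transposases(setNames(junk, "x"), ref)
  expect_true(is.na(cls$family_id))
})

test_that("decayed burst copies are assigned to the right family among decoys", {
  anc <- simulate_ancestor(60, seed = 102)
  deg <- degrade_genome(anc, degradation_params(
    deletion_frac = 0, pseudo_frac = 0, te_pseudo_frac = 0,
    te_bursts = list(list(family_id = "IS982", n_copies = 30,
                          sub_rate = 0.06, trunc_prob = 0.3,
                          trunc_range = c(0.4, 0.9))),
    rng_seed = 103))
  cls <- classify_transposases(deg$genome, is_family_reference())
  m <- match(deg$truth$te_copies$copy_id, cls$feature_id)
  assigned <- cls$family_id[m]
  expect_gte(mean(assigned == "IS982", na.rm = TRUE), 0.95)
  # census conservation: assigned + unassigned = proteome size
  expect_equal(sum(!is.na(cls$family_id)) + sum(is.na(cls$family_id)),
               nrow(cls))
  expect_equal(nrow(cls), sum(deg$genome$features$kind == "CDS"))
})

test_that("planted terminal inverted repeats are found at their coordinates", {
  set.seed(104)
  ir <- "GGATCCGTTAACGGA"
  core <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  flank <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
  contig <- paste0(flank, ir, core, rc(ir), flank)
  s <- nchar(flank) + 1L
  e <- nchar(flank) + 30 + nchar(core)
  hit <- find_terminal_irs(contig, s, e, window = 60)
  expect_false(is.null(hit))
  expect_equal(hit$length, 15)
  expect_equal(hit$up_start, s)
  expect_equal(hit$down_end, e)

  # one flank deleted: nothing to find
  contig2 <- paste0(flank, ir, core, flank)
  expect_null(find_terminal_irs(contig2, nchar(flank) + 1L,
                                nchar(flank) + 15 + nchar(core),
                                window = 60))
})

test_that("the IR finder matches quadratic brute force on small windows", {
  set.seed(105)
  for (rep in 1:15) {
    up <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
    contig <- paste0(up, strrep("N", 5), down)
    got <- find_terminal_irs(contig, 1, nchar(contig), window = 30,
                             min_len = 4, max_mismatch = 1)
    want_len <- brute_ir_len(up, down, max_mismatch = 1)
    if (want_len < 4) {
      expect_null(got)
    } else {
      expect_equal(got$length, want_len)
    }
  }
})

test_that("TE fraction is plain percentage arithmetic with guards", {
  expect_equal(round(te_fraction(691, 2447)), 28)
  expect_equal(te_fraction(0, 100), 0)
  expect_error(te_fraction(10, 0))
  expect_error(te_fraction(11, 10))
  expect_true(all(vapply(1:10, function(i) te_fraction(i, 10), 1) <= 100))
})

test_that("insertion-free regions are the maximal inter-TE intervals", {
  # no TEs: one region per contig spanning it
  g <- simulate_ancestor(10, seed = 106)
  r0 <- insertion_free_regions(g, character(), min_span = 1000)
  expect_equal(nrow(r0), 1)
  expect_equal(r0$start, 1)
  expect_equal(r0$end, genome_length(g))

  # TEs every 5 kb except one 25 kb gap: exactly one region at min_span 20k
  L <- 60000L
  contig <- strrep("A", L)
  pos <- c(seq(1000L, 25000L, by = 5000L), seq(50000L, 59000L, by = 5000L))
  ft <- tibble::tibble(
    feature_id = sprintf("te_%02d", seq_along(pos)), contig_id = "c1",
    start = pos, end = pos + 999L, strand = "+", kind = "CDS",
    status = "pseudogene", product = "transposase",
    category_tags = rep(list(character()), length(pos)))
  g2 <- lux_genome("g2", c(c1 = contig), ft)
  r2 <- insertion_free_regions(g2, ft$feature_id, min_span = 20000)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$start, 22000L) # last TE of the first run ends at 21999
  expect_equal(r2$end, 49999L)
})

test_that("protein distances: identity, Poisson correction, symmetry", {
  s <- c(a = "MKVLATGHEWRNDCQIPFYS", b = "MKVLATGHEWRNDCQIPFYS")
  D0 <- protein_distance_matrix(s)
  expect_equal(D0[1, 2], 0)
  # p = 0.1 -> -ln(0.9)
  x <- "AAAAAAAAAA"
  y <- "AAAAAAAAAV"
  Dp <- protein_distance_matrix(c(x = x, y = y), model = "p")
  expect_equal(Dp[1, 2], 0.1)
  Dpois <- protein_distance_matrix(c(x = x, y = y), model = "poisson")
  expect_equal(Dpois[1, 2], -log(0.9))
  set.seed(107)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  seqs <- setNames(vapply(1:4, function(i) {
    paste(sample(aas, 30, replace = TRUE), collapse = "")
  }, character(1)), paste0("s", 1:4))
  D <- protein_distance_matrix(seqs)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4-taxon worked case
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  back <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-10)

  # 3 taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj3 <- nj_tree(D3)
  b3 <- ape::cophenetic.phylo(nj3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(b3, D3, tolerance = 1e-10)

  # property: random additive trees up to 12 taxa
  set.seed(108)
  for (n in c(5, 8, 12)) {
    rt <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(rt)
    nj <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(nj, ape::unroot(rt))), 0)
    back <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
    expect_equal(back, D, tolerance = 1e-8)
    # cross-check against the reference NJ implementation
    expect_equal(as.numeric(ape::dist.topo(nj, ape::nj(D))), 0)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("an ultrametric matrix is reproduced within numerical tolerance", {
  set.seed(109)
  tr <- ape::rcoal(7)
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  back <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-10)
})

test_that("burst geometry verdicts match their constructions", {
  set.seed(110)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  founder <- paste(sample(aas, 200, replace = TRUE), collapse = "")
  mutate_p <- function(p, rate) {
    x <- strsplit(p, "")[[1]]
    n <- rbinom(1, length(x), rate)
    if (n > 0) {
      at <- sample(length(x), n)
      for (q in at) x[q] <- sample(setdiff(aas, x[q]), 1)
    }
    paste(x, collapse = "")
  }
  # star radiation of a long-diverged founder: single expansion. The
  # outgroups sit near the family ancestor; the genome's copies radiate
  # with shallow crowns from a founder separated by a long stem.
  burst_founder <- mutate_p(founder, 0.4)
  copies <- setNames(vapply(1:12, function(i) mutate_p(burst_founder, 0.03),
                            character(1)), sprintf("copy_%02d", 1:12))
  outg <- setNames(vapply(1:3, function(i) mutate_p(founder, 0.08),
                          character(1)), sprintf("og_%d", 1:3))
  b1 <- burst_test(copies, outg, family_id = "IS5")
  expect_equal(b1$verdict, "single_expansion")
  expect_true(b1$monophyletic)
  expect_gte(b1$burst_ratio, 3)

  # two independent radiations, each seeded from its own outgroup
  # lineage, so outgroup sequences separate the two copy clades
  lineage_a <- mutate_p(founder, 0.3)
  lineage_b <- mutate_p(founder, 0.3)
  founder_a <- mutate_p(lineage_a, 0.2)
  founder_b <- mutate_p(lineage_b, 0.2)
  copies2 <- c(
    setNames(vapply(1:6, function(i) mutate_p(founder_a, 0.03),
                    character(1)), sprintf("a_%02d", 1:6)),
    setNames(vapply(1:6, function(i) mutate_p(founder_b, 0.03),
                    character(1)), sprintf("b_%02d", 1:6)))
  outg2 <- c(og_root = founder, og_lineage_a = lineage_a,
             og_lineage_b = lineage_b)
  b2 <- burst_test(copies2, outg2, family_id = "IS982")
  expect_equal(b2$verdict, "multiple_expansions")
  expect_false(b2$monophyletic)

  # copies interleaved with outgroups at uniform depths: no expansion
  chain <- founder
  inter <- character(0)
  for (i in 1:12) {
    chain <- mutate_p(chain, 0.08)
    inter <- c(inter, chain)
  }
  copies3 <- setNames(inter[seq(1, 12, by = 2)], sprintf("c_%02d", 1:6))
  outg3 <- setNames(inter[seq(2, 12, by = 2)], sprintf("og_%02d", 1:6))
  b3 <- burst_test(copies3, outg3)
  expect_equal(b3$verdict, "no_expansion")

  # fewer than two copies
  b4 <- burst_test(copies[1], outg)
  expect_equal(b4$verdict, "no_expansion")
  expect_match(b4$note, "fewer")
})
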