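test_that("identical sequences align end to end with full similarity", {
  s <- "MKVLATGHEWRNDCQIPFYS"
  a <- align_proteins(s, s)
  expect_equal(a$n_identical, 20)
  expect_equal(a$n_aligned_columns, 20)
  expect_equal(a$n_similar / a$n_aligned_columns, 1.0)
  expect_equal(c(a$q_start, a$q_end, a$s_start, a$s_end), c(1, 20, 1, 20))
})

test_that("DP scores equal exhaustive path enumeration (global, length <= 8)", {
  mat <- toy_matrix()
  set.seed(11)
  for (rep in 1:12) {
    la <- sample(1:8, 1)
    lb <- sample(1:8, 1)
    a <- random_toy_seq(la)
    b <- random_toy_seq(lb)
    got <- align_proteins(a, b, matrix = mat, gap_open = 3, gap_extend = 1,
                          mode = "global")$score
    want <- brute_global_score(a, b, mat, 3, 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("DP scores equal exhaustive enumeration (local, length <= 6)", {
  mat <- toy_matrix()
  set.seed(12)
  for (rep in 1:6) {
    a <- random_toy_seq(sample(3:6, 1))
    b <- random_toy_seq(sample(3:6, 1))
    got <- align_proteins(a, b, matrix = mat, gap_open = 3, gap_extend = 1,
                          mode = "local")$score
    want <- brute_local_score(a, b, mat, 3, 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("local scores agree with Biostrings pairwiseAlignment", {
  set.seed(13)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  for (rep in 1:5) {
    a <- paste(sample(aas, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 45, replace = TRUE), collapse = "")
    got <- align_proteins(a, b)$score
    want <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(got, want)
  }
})

test_that("a mid-sequence deletion aligns both flanks with full identity", {
  set.seed(16)
  s <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                    200, replace = TRUE), collapse = "")
  q <- paste0(substr(s, 1, 50), substr(s, 151, 200))
  a <- align_proteins(q, s)
  expect_equal(a$q_start, 1)
  expect_equal(a$q_end, 100)
  expect_equal(a$s_start, 1)
  expect_equal(a$s_end, 200)
  expect_equal(a$n_identical, nchar(q))
})

test_that("alignment score is symmetric for symmetric matrices", {
  set.seed(14)
  for (rep in 1:6) {
    a <- random_toy_seq(sample(5:15, 1))
    b <- random_toy_seq(sample(5:15, 1))
    s1 <- align_proteins(a, b, matrix = toy_matrix(), gap_open = 3,
                         gap_extend = 1)$score
    s2 <- align_proteins(b, a, matrix = toy_matrix(), gap_open = 3,
                         gap_extend = 1)$score
    expect_equal(s1, s2)
  }
})

test_that("empty sequences are rejected", {
  expect_error(align_proteins("", "MKV"), "non-empty")
})

test_that("best_hit finds the query itself and breaks ties lexicographically", {
  s <- "MKVLATGHEWRNDCQIPFYSMKVLATGHEW"
  ref <- c(gene_b = s, gene_a = s)
  h <- best_hit(s, ref)
  expect_equal(h$subject_id, "gene_a")
  expect_equal(h$length_ratio, 1)
})

test_that("the true ortholog beats randomized decoys, with or without prefilter", {
  set.seed(15)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  q <- paste(sample(aas, 120, replace = TRUE), collapse = "")
  # ortholog: ~80% identity
  qc <- strsplit(q, "")[[1]]
  mut <- sample(120, 24)
  for (p in mut) qc[p] <- sample(setdiff(aas, qc[p]), 1)
  ortho <- paste(qc, collapse = "")
  decoys <- vapply(1:100, function(i) {
    paste(sample(aas, 120, replace = TRUE), collapse = "")
  }, character(1))
  ref <- c(setNames(decoys, sprintf("decoy_%03d", 1:100)),
           c(true_ortholog = ortho))
  h_exh <- best_hit(q, ref)
  expect_equal(h_exh$subject_id, "true_ortholog")
  h_pre <- best_hit(q, ref, index = kmer_index(ref), max_candidates = 10)
  expect_equal(h_pre$subject_id, "true_ortholog")
  # exhaustive cross-check: the winner's score dominates direct all-pairs
  all_scores <- vapply(ref, function(s) align_proteins(q, s)$score,
                       numeric(1))
  expect_equal(h_exh$score, max(all_scores))
})

test_that("queries below the score floor return no hit", {
  ref <- c(r1 = "WWWWWWWWWWWWWWWWWWWW")
  expect_null(best_hit("AGAGAGAGAG", ref, min_score = 50))
})
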