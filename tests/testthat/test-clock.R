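test_that("substitution models are reversible and properly normalised", {
  m <- substitution_model("gtr", rates = c(1, 2, 1, 1, 3, 1),
                          freqs = c(0.3, 0.2, 0.3, 0.2))
  # unit expected rate
  expect_equal(-sum(m$pi * diag(m$Q)), 1)
  # detailed balance pi_i Q_ij = pi_j Q_ji
  bal <- outer(m$pi, rep(1, 4)) * m$Q
  expect_equal(bal, t(bal), tolerance = 1e-12)
  # transition matrices are stochastic
  P <- luxerode:::model_pmat(m, 0.37)
  expect_equal(rowSums(P), rep(1, 4))
  expect_true(all(P >= 0))
  # non-symmetric exchangeabilities are rejected
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(substitution_model("custom", rates = bad), "symmetric")
})

test_that("discrete gamma categories have unit mean rate", {
  r <- luxerode:::discrete_gamma_rates(0.5, 4)
  expect_length(r, 4)
  expect_equal(mean(r), 1, tolerance = 1e-9)
  expect_true(all(diff(r) > 0))
})

test_that("pruning equals exhaustive summation over internal states", {
  set.seed(51)
  jc <- substitution_model("jc")
  gtr <- substitution_model("gtr", rates = c(1, 2, 1, 1, 3, 1),
                            freqs = c(0.35, 0.15, 0.25, 0.25))
  for (ntax in c(4, 5)) {
    tree <- ape::rtree(ntax)
    for (model in list(jc, gtr)) {
      aln <- simulate_alignment(tree, model, 50, seed = 52 + ntax)
      expect_equal(prune_likelihood(tree, aln, model),
                   brute_tree_loglik(tree, aln, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("a zero-length branch between identical sequences gives sum(log pi)", {
  tree <- ape::read.tree(text = "(A:0,B:0);")
  aln <- lux_alignment(c(A = "ACGTAC", B = "ACGTAC"))
  m <- substitution_model("gtr", freqs = c(0.4, 0.1, 0.2, 0.3))
  want <- sum(log(m$pi[c(1, 2, 3, 4, 1, 2)]))
  expect_equal(prune_likelihood(tree, aln, m), want, tolerance = 1e-9)
})

test_that("likelihood is invariant to root placement under reversibility", {
  set.seed(53)
  tree <- ape::rtree(6)
  m <- substitution_model("gtr", rates = c(2, 1, 1, 1, 4, 1))
  aln <- simulate_alignment(tree, m, 80, seed = 54)
  base <- prune_likelihood(tree, aln, m)
  for (og in tree$tip.label[c(2, 4)]) {
    rr <- ape::root(ape::unroot(tree), outgroup = og, resolve.root = TRUE)
    expect_equal(prune_likelihood(rr, aln, m), base, tolerance = 1e-8)
  }
})

test_that("duplicated columns double the log-likelihood (pattern weighting)", {
  set.seed(55)
  tree <- ape::rtree(5)
  m <- substitution_model("jc")
  aln <- simulate_alignment(tree, m, 40, seed = 56)
  dup <- lux_alignment(setNames(paste0(aln$seqs, aln$seqs),
                                names(aln$seqs)))
  expect_equal(prune_likelihood(tree, dup, m),
               2 * prune_likelihood(tree, aln, m), tolerance = 1e-8)
})

test_that("gamma-mixture likelihood matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(57)
  tree <- ape::rtree(6)
  m <- substitution_model("gtr", rates = c(1, 3, 1, 1, 3, 1),
                          freqs = c(0.3, 0.2, 0.2, 0.3), gamma_shape = 0.7)
  aln <- simulate_alignment(tree, m, 60, seed = 58)
  dat <- phangorn::phyDat(do.call(rbind, strsplit(aln$seqs, "")),
                          type = "DNA")
  fitp <- phangorn::pml(tree, dat, bf = c(0.3, 0.2, 0.2, 0.3),
                        Q = c(1, 3, 1, 1, 3, 1), k = 4, shape = 0.7)
  expect_equal(prune_likelihood(tree, aln, m), fitp$logLik,
               tolerance = 1e-6)
})

test_that("PAML-dialect amino-acid models load and evaluate", {
  set.seed(64)
  f <- withr::local_tempfile()
  writeLines(c(paste(runif(190, 0.1, 2), collapse = " "),
               paste(rep(0.05, 20), collapse = " ")), f)
  m <- read_paml_model(f)
  expect_equal(m$alphabet, "amino-acid")
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  P <- luxerode:::model_pmat(m, 0.3)
  expect_equal(rowSums(P), rep(1, 20), ignore_attr = TRUE)
  aln <- lux_alignment(c(A = "MKV", B = "MKV"), alphabet = "amino-acid")
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  expect_lt(prune_likelihood(tr, aln, m), 0)
  # truncated rate files are rejected
  g <- withr::local_tempfile()
  writeLines(paste(runif(50), collapse = " "), g)
  expect_error(read_paml_model(g), "190")
})

test_that("two-taxon global clock recovers the JC distance", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  jc <- substitution_model("jc")
  sim_tree <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- simulate_alignment(sim_tree, jc, 50000, seed = 59)
  fit <- fit_global_clock(tree, aln, jc)
  # total path length ~ 0.2; compare through the JC-inverted p distance
  pd <- mean(strsplit(aln$seqs[1], "")[[1]] != strsplit(aln$seqs[2], "")[[1]])
  d_hat <- -0.75 * log(1 - 4 * pd / 3)
  expect_equal(2 * fit$b, d_hat, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("identical sequences drive the clock rate to its floor", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  jc <- substitution_model("jc")
  aln <- lux_alignment(c(A = strrep("ACGT", 10), B = strrep("ACGT", 10),
                         C = strrep("ACGT", 10)))
  fit <- fit_global_clock(tree, aln, jc)
  expect_equal(fit$logL, 40 * log(0.25), tolerance = 1e-4)
})

test_that("clock fitting validates its inputs", {
  jc <- substitution_model("jc")
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- simulate_alignment(tree, jc, 100, seed = 60)
  expect_error(fit_global_clock(ape::unroot(tree), aln, jc), "rooted")
  expect_error(fit_local_clock(tree, aln, jc, c("A", "C")),
               "monophyletic")
  expect_warning(luxerode:::foreground_edges(tree, c("A", "B", "C", "D")),
                 "identifiable")
})

test_that("the local clock recovers a planted rate multiplier", {
  tree <- local({
    set.seed(61)
    tr <- ape::rcoal(8)
    tr$edge.length <- tr$edge.length /
      max(ape::node.depth.edgelength(tr)) * 0.15
    tr
  })
  fg <- luxerode:::pick_foreground_clade(tree, 3)
  jc <- substitution_model("jc")
  aln <- simulate_alignment(tree, jc, 4000, foreground = fg,
                            rate_multiplier = 3, seed = 62)
  f0 <- fit_global_clock(tree, aln, jc)
  f1 <- fit_local_clock(tree, aln, jc, fg, null_fit = f0)
  expect_gte(f1$logL, f0$logL - 1e-6)
  expect_gt(f1$r, 2)
  expect_lt(f1$r, 4.5)
  res <- lrt(f0, f1)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 1e-6)
})

test_that("likelihood-ratio arithmetic and chi-square tails are exact", {
  r <- lrt_from_loglik(-100, -90, df = 1)
  expect_equal(r$LR, 20)
  expect_equal(r$p, pchisq(20, 1, lower.tail = FALSE))
  r0 <- lrt_from_loglik(-100, -100, df = 1)
  expect_equal(r0$LR, 0)
  expect_equal(r0$p, 1)
  # numerical jitter below the null never yields a negative statistic
  rneg <- lrt_from_loglik(-100, -100.0000001, df = 2)
  expect_equal(rneg$LR, 0)
  expect_error(lrt_from_loglik(-100, -90, df = 0), "df")
})

test_that("clock tidiers expose branches and model summaries", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  jc <- substitution_model("jc")
  aln <- simulate_alignment(tree, jc, 200, seed = 63)
  fit <- fit_global_clock(tree, aln, jc)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(tree$edge))
  expect_true(all(td$duration >= 0))
  gl <- glance(fit)
  expect_named(gl, c("logL", "b", "r", "n_free_params", "converged"))
})
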