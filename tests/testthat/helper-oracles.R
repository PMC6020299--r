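# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation's algorithms: alignment scores come from
# exhaustive path enumeration, tree likelihoods from summation over all
# internal-state assignments, and inverted repeats from direct triple-loop
# search.

# ---- exhaustive affine-gap alignment ------------------------------------

# score of one explicit alignment path under affine gaps (a run of L gaps
# costs gap_open + L * gap_extend)
score_ops <- function(ops, a, b, mat, go, ge) {
  i <- 0
  j <- 0
  score <- 0
  last <- ""
  for (op in ops) {
    if (op == "M") {
      i <- i + 1
      j <- j + 1
      score <- score + mat[a[i], b[j]]
    } else if (op == "D") {
      i <- i + 1
      score <- score - ge - if (last == "D") 0 else go
    } else {
      j <- j + 1
      score <- score - ge - if (last == "I") 0 else go
    }
    last <- op
  }
  score
}

# exhaustive global alignment score by DFS over all monotone paths,
# carrying the score (not a DP table)
brute_global_score <- function(a, b, mat, go, ge) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a)
  n <- length(b)
  best <- -Inf
  dfs <- function(i, j, last, score) {
    if (i == m && j == n) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i < m && j < n) {
      dfs(i + 1, j + 1, "M", score + mat[a[i + 1], b[j + 1]])
    }
    if (i < m) {
      dfs(i + 1, j, "D", score - ge - if (last == "D") 0 else go)
    }
    if (j < n) {
      dfs(i, j + 1, "I", score - ge - if (last == "I") 0 else go)
    }
  }
  dfs(0, 0, "", 0)
  best
}

# exhaustive local score: best global score over all substring pairs,
# floored at the empty alignment (0)
brute_local_score <- function(a, b, mat, go, ge) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(ca)) {
    for (i2 in i1:length(ca)) {
      for (j1 in seq_along(cb)) {
        for (j2 in j1:length(cb)) {
          s <- brute_global_score(paste(ca[i1:i2], collapse = ""),
                                  paste(cb[j1:j2], collapse = ""),
                                  mat, go, ge)
          best <- max(best, s)
        }
      }
    }
  }
  best
}

# ---- exhaustive tree likelihood ----------------------------------------

brute_tree_loglik <- function(tree, aln, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  k <- length(model$states)
  P <- lapply(seq_len(nrow(tr$edge)), function(e) {
    luxerode:::model_pmat(model, tr$edge.length[e])
  })
  seqs <- do.call(rbind, strsplit(aln$seqs[tr$tip.label], ""))
  internals <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  tot <- 0
  for (s in seq_len(ncol(seqs))) {
    obs <- match(seqs[, s], model$states)
    lik <- 0
    for (gi in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[seq_len(ntip)] <- obs
      st[internals] <- grid[gi, ]
      pr <- model$pi[st[ntip + 1]]
      for (e in seq_len(nrow(tr$edge))) {
        pr <- pr * P[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
      }
      lik <- lik + pr
    }
    tot <- tot + log(lik)
  }
  tot
}

# ---- brute-force inverted repeat search --------------------------------

# longest u in `up` whose reverse complement occurs in `down` with at most
# max_mismatch mismatches; returns the maximal length only
brute_ir_len <- function(up, down, max_mismatch) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  down_rc <- rc(down)
  u <- strsplit(up, "")[[1]]
  v <- strsplit(down_rc, "")[[1]]
  best <- 0
  for (i in seq_along(u)) {
    for (j in seq_along(v)) {
      lim <- min(length(u) - i, length(v) - j) + 1
      for (L in seq_len(lim)) {
        mm <- sum(u[i:(i + L - 1)] != v[j:(j + L - 1)])
        if (mm <= max_mismatch && u[i + L - 1] == v[j + L - 1]) {
          best <- max(best, L)
        }
      }
    }
  }
  best
}

# random additive (binary unrooted) tree with strictly positive lengths
random_additive_tree <- function(n) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  tr
}

# a tiny reduced-alphabet scoring matrix for enumeration tests
toy_matrix <- function() {
  m <- matrix(-2, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  diag(m) <- 3
  m
}

random_toy_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
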