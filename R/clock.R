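# Global- vs local-clock maximum likelihood on a fixed rooted topology.
#
# The null model is a strict global clock: node times on an ultrametric
# tree (root time fixed at 1, tips at 0; the overall time scale is absorbed
# by the background rate b), with branch length = duration * b. The
# alternative adds a single rate multiplier r applied to every branch
# inside a designated foreground clade, including (by default) its stem
# branch. Likelihoods come from Felsenstein pruning over compressed site
# patterns with per-node scaling; optimisation is quasi-Newton (L-BFGS-B)
# on transformed parameters (logit of node-time proportions, log b, log r),
# with the local-clock fit initialised at the global-clock optimum so that
# the nesting inequality lnLA >= lnL0 holds by monotone descent.

# ---- alignment <-> pattern machinery -----------------------------------

aln_state_matrix <- function(alignment, model) {
  seqs <- alignment$seqs
  mat <- do.call(rbind, strsplit(seqs, ""))
  states <- matrix(match(mat, model$states) - 1L, nrow = nrow(mat))
  states[is.na(states)] <- -1L # gaps/ambiguity = missing
  rownames(states) <- names(seqs)
  states
}

compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = states[, first, drop = FALSE], weights = w)
}

# stack per-category, per-edge transition matrices into the flat array the
# C++ pruning core expects
pmat_stack <- function(model, branch_lengths) {
  k <- length(model$states)
  ncat <- length(model$cat_rates)
  ne <- length(branch_lengths)
  P <- numeric(k * k * ne * ncat)
  pos <- 1
  for (c in seq_len(ncat)) {
    rc <- model$cat_rates[c]
    for (e in seq_len(ne)) {
      P[pos:(pos + k * k - 1)] <- model_pmat(model, branch_lengths[e] * rc)
      pos <- pos + k * k
    }
  }
  P
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Site patterns are compressed (identical columns computed once and
#' weighted) and partial likelihoods rescaled per node, with discrete-gamma
#' categories averaged at equal weights.
#'
#' @param tree An `ape::phylo` with branch lengths in expected
#'   substitutions per site.
#' @param alignment A [lux_alignment()] whose ids cover the tree's tips.
#' @param model A [substitution_model()].
#' @return The log-likelihood (double).
#' @export
prune_likelihood <- function(tree, alignment, model) {
  missing <- setdiff(tree$tip.label, names(alignment$seqs))
  if (length(missing) > 0) {
    abort(paste0("alignment lacks taxa: ", paste(missing, collapse = ", ")))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  states <- aln_state_matrix(alignment, model)[tree$tip.label, , drop = FALSE]
  pat <- compress_patterns(states)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  P <- pmat_stack(model, tr$edge.length)
  prune_loglik_cpp(pat$states, pat$weights, tr$edge, P, model$pi,
                   model$cat_weights, ntip + tr$Nnode, root)
}

# ---- clock fitting ------------------------------------------------------

# edges (rows of tree$edge) whose child lies inside the clade spanned by
# the tips in `foreground`; optionally including the stem edge
foreground_edges <- function(tree, foreground, include_stem = TRUE) {
  tips <- match(foreground, tree$tip.label)
  if (anyNA(tips)) {
    abort(paste0("foreground taxa not in tree: ",
                 paste(foreground[is.na(tips)], collapse = ", ")))
  }
  ntip <- length(tree$tip.label)
  if (length(tips) == ntip) {
    warn(paste("foreground covers all taxa: rate multiplier r is not",
               "identifiable separately from the background rate b",
               "(only the product r*b is)"))
    return(seq_len(nrow(tree$edge)))
  }
  if (length(tips) == 1) {
    mrca <- tips
  } else {
    if (!ape::is.monophyletic(tree, foreground)) {
      abort("foreground clade is not monophyletic in the rooted topology")
    }
    mrca <- ape::getMRCA(tree, tips)
  }
  desc <- node_descendants(tree, mrca)
  idx <- which(tree$edge[, 2] %in% desc)
  if (include_stem) idx <- union(idx, which(tree$edge[, 2] == mrca))
  idx
}

# all nodes (internal + tips) strictly below `node`
node_descendants <- function(tree, node) {
  out <- integer()
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}

# node times (root = 1, tips = 0) from logit-scaled proportions s:
# t[node] = t[parent] * s[node] for internal non-root nodes, in preorder
times_from_s <- function(tree, s) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  tms <- numeric(ntip + nnode)
  tms[root] <- 1
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    ch <- pre[e, 2]
    if (ch > ntip) tms[ch] <- tms[pre[e, 1]] * s[ch - ntip - 1L]
  }
  tms
}

clock_branch_lengths <- function(tree, tms, b, r, fg_idx) {
  dur <- tms[tree$edge[, 1]] - tms[tree$edge[, 2]]
  dur <- pmax(dur, 1e-9)
  len <- dur * b
  if (length(fg_idx) > 0) len[fg_idx] <- len[fg_idx] * r
  len
}

fit_clock_engine <- function(tree, alignment, model, fg_idx, fit_r,
                             init = NULL, restarts = 1) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- nnode - 1L # root time fixed at 1
  tr_post <- ape::reorder.phylo(tree, "postorder")
  # map edge order between the caller's tree and the postorder copy
  post_of_orig <- match(paste(tr_post$edge[, 1], tr_post$edge[, 2]),
                        paste(tree$edge[, 1], tree$edge[, 2]))
  states <- aln_state_matrix(alignment, model)[tree$tip.label, , drop = FALSE]
  pat <- compress_patterns(states)
  root <- ntip + 1L
  nn_tot <- ntip + nnode

  unpack <- function(z) {
    s <- if (ns > 0) stats::plogis(z[seq_len(ns)]) else numeric()
    b <- exp(z[ns + 1L])
    r <- if (fit_r) exp(z[ns + 2L]) else 1
    list(s = s, b = b, r = r)
  }
  negll <- function(z) {
    p <- unpack(z)
    tms <- times_from_s(tree, p$s)
    len <- clock_branch_lengths(tree, tms, p$b, p$r, fg_idx)
    P <- pmat_stack(model, len[post_of_orig])
    -prune_loglik_cpp(pat$states, pat$weights, tr_post$edge, P, model$pi,
                      model$cat_weights, nn_tot, root)
  }

  if (is.null(init)) {
    # crude but deterministic: node-time proportions from subtree tip
    # counts, rate from mean pairwise difference
    depth_prop <- function(node) {
      nd <- sum(node_descendants(tree, node) <= ntip)
      max(nd - 1, 0.5) / max(ntip - 1, 1)
    }
    s0 <- numeric(ns)
    if (ns > 0) {
      pre <- ape::reorder.phylo(tree, "cladewise")$edge
      prop <- vapply((ntip + 2L):(ntip + nnode), depth_prop, numeric(1))
      parent <- vapply((ntip + 2L):(ntip + nnode), function(v) {
        pre[pre[, 2] == v, 1][1]
      }, numeric(1))
      pprop <- ifelse(parent == root, 1,
                      prop[match(parent, (ntip + 2L):(ntip + nnode))])
      s0 <- pmin(pmax(prop / pprop, 0.05), 0.95)
    }
    b0 <- init_rate_guess(states, model)
    init <- c(stats::qlogis(s0), log(b0), if (fit_r) 0)
  }
  lower <- c(rep(-12, ns), log(1e-9), if (fit_r) log(1e-3))
  upper <- c(rep(12, ns), log(1e3), if (fit_r) log(1e3))

  best <- NULL
  starts <- list(init)
  if (restarts > 1) {
    for (k in seq_len(restarts - 1)) {
      jit <- init + c(stats::rnorm(ns, 0, 1), stats::rnorm(1, 0, 0.5),
                      if (fit_r) stats::rnorm(1, 0, 0.5))
      starts[[k + 1]] <- pmin(pmax(jit, lower + 1e-6), upper - 1e-6)
    }
  }
  for (z0 in starts) {
    fit <- tryCatch(
      optim(z0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            # factr 1e5 ~ 1e-6 absolute logL tolerance at these magnitudes
            control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("clock optimisation failed from every start")
  p <- unpack(best$par)
  tms <- times_from_s(tree, p$s)
  len <- clock_branch_lengths(tree, tms, p$b, p$r, fg_idx)
  fitted_tree <- tree
  fitted_tree$edge.length <- len
  list(logL = -best$value, b = p$b, r = p$r, times = tms,
       tree = fitted_tree, converged = best$convergence == 0,
       par = best$par)
}

# quick rate scale: mean pairwise mismatch fraction, distance-corrected for
# the model's alphabet size, halved (root-to-tip)
init_rate_guess <- function(states, model) {
  n <- nrow(states)
  k <- length(model$states)
  pick <- utils::combn(seq_len(n), 2)
  if (ncol(pick) > 20) pick <- pick[, seq(1, ncol(pick), length.out = 20)]
  ps <- apply(pick, 2, function(ij) {
    a <- states[ij[1], ]
    b <- states[ij[2], ]
    ok <- a >= 0 & b >= 0
    if (!any(ok)) return(0)
    mean(a[ok] != b[ok])
  })
  p <- min(mean(ps), (k - 1) / k - 0.01)
  d <- -(k - 1) / k * log(1 - k / (k - 1) * p)
  max(d / 2, 1e-4)
}

#' Fit a strict global clock
#'
#' Maximises the likelihood over ultrametric node times and a single
#' background rate `b` on a fixed rooted topology (r fixed at 1).
#'
#' @param tree Rooted `ape::phylo` topology (branch lengths, if any, are
#'   ignored; root placement is an input).
#' @param alignment A [lux_alignment()].
#' @param model A [substitution_model()].
#' @param restarts Number of optimisation starts (the first is
#'   deterministic; extras are jittered).
#' @return An object of class `lux_clock_fit` with elements `logL`, `b`,
#'   `r` (= 1), `times` (node times, root = 1), `tree` (fitted branch
#'   lengths), `converged`, `n_free_params`, `foreground` (NULL).
#' @export
fit_global_clock <- function(tree, alignment, model, restarts = 1) {
  check_clock_inputs(tree, alignment)
  fit <- fit_clock_engine(tree, alignment, model, integer(), fit_r = FALSE,
                          restarts = restarts)
  structure(c(fit, list(
    foreground = NULL, include_stem = NA,
    n_free_params = (tree$Nnode - 1L) + 1L,
    model = model
  )), class = "lux_clock_fit")
}

#' Fit a local clock with one foreground rate multiplier
#'
#' Same as [fit_global_clock()] plus a free rate multiplier `r` (bounded
#' below at 1e-3) on every branch of a monophyletic foreground clade,
#' including its stem branch by default. Initialised at the global-clock
#' optimum (plus r set to 1), so `logL` can never fall below the null
#' fit's.
#'
#' @inheritParams fit_global_clock
#' @param foreground Character vector of tip labels forming a monophyletic
#'   clade in the rooted topology.
#' @param include_stem Scale the branch subtending the clade too (default
#'   TRUE; the stem usually carries most of the rate-separation signal).
#' @param null_fit Optional pre-computed global-clock fit to initialise
#'   from (avoids refitting).
#' @return A `lux_clock_fit` with free `r`.
#' @export
fit_local_clock <- function(tree, alignment, model, foreground,
                            include_stem = TRUE, restarts = 1,
                            null_fit = NULL) {
  check_clock_inputs(tree, alignment)
  fg_idx <- foreground_edges(tree, foreground, include_stem)
  init <- NULL
  if (!is.null(null_fit)) init <- c(null_fit$par, 0)
  fit <- fit_clock_engine(tree, alignment, model, fg_idx, fit_r = TRUE,
                          init = init, restarts = restarts)
  if (!is.null(null_fit) && fit$logL < null_fit$logL - 1e-6) {
    abort("optimiser failure: local-clock logL fell below the global fit")
  }
  structure(c(fit, list(
    foreground = foreground, include_stem = include_stem,
    n_free_params = (tree$Nnode - 1L) + 2L,
    model = model
  )), class = "lux_clock_fit")
}

check_clock_inputs <- function(tree, alignment) {
  if (!ape::is.rooted(tree)) abort("clock fitting needs a rooted topology")
  missing <- setdiff(tree$tip.label, names(alignment$seqs))
  if (length(missing) > 0) {
    abort(paste0("alignment lacks taxa: ", paste(missing, collapse = ", ")))
  }
}

#' @export
print.lux_clock_fit <- function(x, ...) {
  cat("<lux_clock_fit> logL ", format(x$logL, nsmall = 2),
      ", b ", format(x$b, digits = 4), sep = "")
  if (!is.null(x$foreground)) {
    cat(", r ", format(x$r, digits = 4), " (foreground: ",
        paste(x$foreground, collapse = ","), ")", sep = "")
  }
  cat(if (x$converged) ", converged" else ", NOT converged", "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested clock fits
#'
#' `LR = 2 (lnLA - lnL0)`, floored at zero, against the chi-square upper
#' tail with `df` equal to the difference in free parameter counts.
#'
#' @param fit_null,fit_alt `lux_clock_fit` objects (the alternative must
#'   nest the null).
#' @return A one-row tibble of class `lux_lrt`: LR, df, p, r, lnL0, lnLA.
#' @export
lrt <- function(fit_null, fit_alt) {
  df <- fit_alt$n_free_params - fit_null$n_free_params
  lrt_from_loglik(fit_null$logL, fit_alt$logL, df = df, r = fit_alt$r)
}

#' Likelihood-ratio test from log-likelihood values
#'
#' For testing model comparisons whose likelihoods were computed elsewhere
#' (e.g. published model-comparison tables).
#'
#' @param lnL0,lnLA Log-likelihoods of the null and alternative models
#'   (the alternative nests the null).
#' @param df Extra free parameters in the alternative (>= 1).
#' @param r Optional rate-multiplier estimate to carry along.
#' @return A one-row tibble of class `lux_lrt`: LR, df, p, r, lnL0, lnLA.
#' @export
lrt_from_loglik <- function(lnL0, lnLA, df = 1, r = NA_real_) {
  if (df < 1) abort("df must be >= 1 (models must differ)")
  LR <- max(0, 2 * (lnLA - lnL0))
  out <- tibble(LR = LR, df = as.integer(df),
                p = pchisq(LR, df = df, lower.tail = FALSE),
                r = r, lnL0 = lnL0, lnLA = lnLA)
  class(out) <- c("lux_lrt", class(out))
  out
}
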