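# Transposable-element census: family classification of transposase
# proteins against a reference set, completeness calling (aligned fraction
# + terminal inverted repeats), TE fraction of CDS, insertion-free-region
# detection, and burst detection on within-family transposase phylogenies.

#' Classify transposase proteins by IS family
#'
#' Assigns each protein to the best-scoring reference family, requiring
#' minimum identity and minimum coverage of the reference; proteins below
#' threshold stay unassigned. Identity is counted over aligned columns,
#' coverage as the aligned fraction of the reference protein.
#'
#' @param proteome Named character vector of proteins, or a [lux_genome()]
#'   (its CDS are translated).
#' @param is_reference Reference tibble with columns `family_id`, `protein`
#'   and `full_length_aa` (e.g. [is_family_reference()], a synthetic set).
#' @param min_identity,min_coverage Assignment thresholds (defaults 0.3 and
#'   0.3, common IS-annotation practice).
#' @param min_score Alignment score floor (default 100): long but
#'   low-scoring meandering local alignments of unrelated proteins can
#'   otherwise satisfy the identity and coverage thresholds by chance.
#' @param prefilter_k Shared-k-mer prefilter length (default 4); when no
#'   reference shares a k-mer with a translation the scan falls back to
#'   all references (family members diverged to ~45% identity can lose
#'   every exact k-mer by chance). Set to `NULL` to disable.
#' @param matrix,gap_open,gap_extend Aligner parameters.
#' @return Tibble of TE records: feature_id, family_id (NA when
#'   unassigned), identity_to_ref, aligned_fraction_of_ref, score, and
#'   `protein` (the conceptual translation the assignment was made with;
#'   the input for downstream within-family phylogenetics).
#' @export
classify_transposases <- function(proteome, is_reference,
                                  min_identity = 0.3, min_coverage = 0.3,
                                  min_score = 100, prefilter_k = 4,
                                  matrix = default_protein_matrix(),
                                  gap_open = 11, gap_extend = 1) {
  if (inherits(proteome, "lux_genome")) {
    # decayed transposase fragments are rarely in frame 0 and often carry
    # premature stops: score the three forward-frame conceptual
    # translations (stops as X) and keep the best
    ft <- filter(proteome$features, kind == "CDS")
    nts <- feature_seqs(proteome, ft$feature_id)
    prot_list <- frame_translations_all(nts)
  } else {
    prot_list <- lapply(proteome, function(p) p[nzchar(p)])
  }
  if (nrow(is_reference) == 0) abort("empty IS reference set")
  refs <- setNames(is_reference$protein, is_reference$family_id)
  ref_len <- setNames(is_reference$full_length_aa, is_reference$family_id)
  idx <- if (!is.null(prefilter_k)) kmer_index(refs, k = prefilter_k)
  alphabet <- rownames(matrix)
  rows <- vector("list", length(prot_list))
  for (i in seq_along(prot_list)) {
    out <- tibble(feature_id = names(prot_list)[i],
                  family_id = NA_character_,
                  identity_to_ref = NA_real_,
                  aligned_fraction_of_ref = NA_real_, score = NA_real_,
                  protein = NA_character_)
    best_score <- -Inf
    best <- NULL
    for (p in prot_list[[i]]) {
      cand <- if (is.null(idx)) seq_along(refs) else
        kmer_candidates(p, idx, max_candidates = length(refs))
      if (length(cand) == 0) cand <- seq_along(refs)
      qi <- encode_protein(p, alphabet)
      subs <- lapply(refs[cand], encode_protein, alphabet = alphabet)
      scores <- align_scores_batch_cpp(qi, subs, matrix, gap_open,
                                       gap_extend, TRUE)
      tied <- cand[scores == max(scores)]
      win <- tied[order(names(refs)[tied])][1]
      if (max(scores) > best_score) {
        best_score <- max(scores)
        best <- list(p = p, win = win)
      }
    }
    if (!is.null(best)) {
      aln <- align_proteins(best$p, refs[[best$win]], matrix = matrix,
                            gap_open = gap_open, gap_extend = gap_extend,
                            mode = "local")
      if (aln$n_aligned_columns > 0) {
        ident <- aln$n_identical / aln$n_aligned_columns
        cov <- (aln$s_end - aln$s_start + 1) / ref_len[[best$win]]
        if (ident >= min_identity && cov >= min_coverage &&
            aln$score >= min_score) {
          out$family_id <- names(refs)[best$win]
          out$identity_to_ref <- ident
          out$aligned_fraction_of_ref <- cov
          out$score <- aln$score
          out$protein <- best$p
        }
      }
    }
    rows[[i]] <- out
  }
  bind_rows(rows)
}

# conceptual translations of the three forward frames for every sequence,
# premature stops kept as X (scored 0 by the default matrix); returns a
# list (one character vector of frames per input)
frame_translations_all <- function(nts) {
  n <- str_length(nts)
  frames <- vector("list", 3)
  for (off in 0:2) {
    len <- ((n - off) %/% 3L) * 3L
    keep <- len >= 60
    aa <- rep(NA_character_, length(nts))
    if (any(keep)) {
      dss <- Biostrings::DNAStringSet(substr(nts[keep], off + 1L,
                                             off + len[keep]))
      aa[keep] <- gsub("*", "X", suppressWarnings(as.character(
        Biostrings::translate(dss, if.fuzzy.codon = "solve"))), fixed = TRUE)
    }
    frames[[off + 1]] <- aa
  }
  out <- lapply(seq_along(nts), function(i) {
    v <- c(frames[[1]][i], frames[[2]][i], frames[[3]][i])
    v[!is.na(v)]
  })
  setNames(out, names(nts))
}

frame_translations <- function(nt) {
  frame_translations_all(setNames(nt, "x"))[[1]]
}

#' Find terminal inverted repeats around a feature
#'
#' Searches a window at each end of the element for the longest sequence
#' pair (u, reverse-complement match) with at most `max_mismatch`
#' mismatches; reports nothing when no pair reaches `min_len`.
#'
#' @param contig_seq Contig sequence (single string).
#' @param start,end 1-based element coordinates (windows are clamped at
#'   contig ends).
#' @param window Window length at each end (default 100).
#' @param min_len Minimum repeat length (default 10).
#' @param max_mismatch Allowed mismatches (default 2).
#' @return A one-row tibble (up_start, up_end, down_start, down_end,
#'   length, mismatches) or `NULL`.
#' @export
find_terminal_irs <- function(contig_seq, start, end, window = 100,
                              min_len = 10, max_mismatch = 2) {
  L <- str_length(contig_seq)
  stopifnot(start >= 1, end <= L, start <= end)
  up_a <- start
  up_b <- min(start + window - 1L, end, L)
  down_b <- end
  down_a <- max(end - window + 1L, start)
  up <- encode_dna(substr(contig_seq, up_a, up_b))
  down <- substr(contig_seq, down_a, down_b)
  down_rc <- encode_dna(revcomp(down))
  res <- longest_ir_match_cpp(up, down_rc, as.integer(min_len),
                              as.integer(max_mismatch))
  if (!isTRUE(res$found)) return(NULL)
  # map the reverse-complement offset back to forward coordinates
  dlen <- str_length(down)
  d_end <- down_b - (res$down_rc_off - 1L)
  d_start <- d_end - res$len + 1L
  tibble(up_start = up_a + res$up_off - 1L,
         up_end = up_a + res$up_off + res$len - 2L,
         down_start = d_start, down_end = d_end,
         length = res$len, mismatches = res$mismatches)
}

encode_dna <- function(seq) {
  match(strsplit(str_to_upper(seq), "")[[1]], c("A", "C", "G", "T")) - 1L
}

#' TE percentage of coding sequences
#'
#' @param n_te_genes Number of TE genes.
#' @param n_total_cds Total CDS count (> 0; must be >= n_te_genes).
#' @return `100 * n_te_genes / n_total_cds`.
#' @export
te_fraction <- function(n_te_genes, n_total_cds) {
  stopifnot(n_total_cds > 0, n_te_genes >= 0, n_te_genes <= n_total_cds)
  100 * n_te_genes / n_total_cds
}

#' Insertion-free regions of a genome
#'
#' Maximal intervals between consecutive TE features (and contig ends) of
#' at least `min_span` bp, each annotated with the functional genes it
#' contains. In reduced genomes riddled with transposons these regions mark
#' gene clusters under selection against insertion.
#'
#' @param genome A [lux_genome()].
#' @param te_records Tibble with `feature_id` and a non-NA `family_id` for
#'   TE calls (e.g. from [classify_transposases()]), or a character vector
#'   of TE feature ids.
#' @param min_span Minimum region length in bp (default 20000).
#' @return Tibble: contig, start, end, length, n_functional, feature_ids
#'   (list column of the functional genes inside).
#' @export
insertion_free_regions <- function(genome, te_records, min_span = 20000) {
  te_ids <- if (is.character(te_records)) te_records else
    te_records$feature_id[!is.na(te_records$family_id)]
  ft <- genome$features
  te <- filter(ft, feature_id %in% te_ids)
  out <- list()
  for (cid in names(genome$contigs)) {
    L <- str_length(genome$contigs[[cid]])
    th <- arrange(filter(te, contig_id == cid), start)
    bounds_start <- c(1L, th$end + 1L)
    bounds_end <- c(th$start - 1L, L)
    for (i in seq_along(bounds_start)) {
      s <- bounds_start[i]
      e <- bounds_end[i]
      if (e - s + 1L < min_span) next
      inside <- filter(ft, contig_id == cid, status == "functional",
                       start >= s, end <= e, !feature_id %in% te_ids)
      out[[length(out) + 1]] <- tibble(
        contig = cid, start = s, end = e, length = e - s + 1L,
        n_functional = nrow(inside),
        feature_ids = list(inside$feature_id))
    }
  }
  if (length(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  length = integer(), n_functional = integer(),
                  feature_ids = list()))
  }
  bind_rows(out)
}

#' Pairwise protein distance matrix
#'
#' Global affine-gap alignment of every pair; distance is the mismatch
#' fraction p over aligned columns ("p"), or its Poisson correction
#' `-ln(1 - p)` ("poisson", the default). Saturated distances (p >= 1)
#' are capped at 10 with a message.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param model "poisson" or "p".
#' @param matrix,gap_open,gap_extend Aligner parameters.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
protein_distance_matrix <- function(seqs, model = c("poisson", "p"),
                                    matrix = default_protein_matrix(),
                                    gap_open = 11, gap_extend = 1) {
  model <- match.arg(model)
  n <- length(seqs)
  stopifnot(n >= 2)
  D <- base::matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  capped <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- align_proteins(seqs[[i]], seqs[[j]], matrix = matrix,
                          gap_open = gap_open, gap_extend = gap_extend,
                          mode = "global")
      p <- if (a$n_aligned_columns > 0)
        1 - a$n_identical / a$n_aligned_columns else 1
      d <- if (model == "p") p else if (p < 1) -log(1 - p) else NA_real_
      if (is.na(d) || d > 10) {
        d <- 10
        capped <- capped + 1
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (capped > 0) inform(paste0(capped, " saturated distance(s) capped at 10"))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. Negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch, preserving path lengths
#' between the joined pair's neighbours.
#'
#' @param D Symmetric distance matrix with at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  n <- nrow(D)
  stopifnot(n >= 3)
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  # active nodes carry their id in the growing edge list
  ntip <- n
  next_node <- 2L * ntip - 2L # internal ids count down from 2n-2
  node_id <- seq_len(ntip)
  edges <- base::matrix(0L, 0, 2)
  lens <- numeric(0)
  Dm <- D
  act <- seq_len(n)
  add_edge <- function(par, ch, len) {
    edges <<- rbind(edges, c(par, ch))
    lens <<- c(lens, len)
  }
  node_id <- seq_len(ntip)
  while (length(node_id) > 3) {
    m <- length(node_id)
    r <- rowSums(Dm)
    Qm <- (m - 2) * Dm - outer(r, r, "+")
    diag(Qm) <- Inf
    ij <- which(Qm == min(Qm), arr.ind = TRUE)[1, ]
    i <- min(ij)
    j <- max(ij)
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    # clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vj <- max(vj, 0)
    u <- next_node
    next_node <- next_node - 1L
    add_edge(u, node_id[i], vi)
    add_edge(u, node_id[j], vj)
    du <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    Dm <- rbind(cbind(Dm, du), c(du, 0))
    keep <- setdiff(seq_len(m + 1), c(i, j))
    Dm <- Dm[keep, keep, drop = FALSE]
    node_id <- c(node_id, u)[keep]
  }
  # star-join the last three around the basal node
  u <- next_node
  la <- 0.5 * (Dm[1, 2] + Dm[1, 3] - Dm[2, 3])
  lb <- 0.5 * (Dm[1, 2] + Dm[2, 3] - Dm[1, 3])
  lc <- 0.5 * (Dm[1, 3] + Dm[2, 3] - Dm[1, 2])
  add_edge(u, node_id[1], max(la, 0))
  add_edge(u, node_id[2], max(lb, 0))
  add_edge(u, node_id[3], max(lc, 0))
  # renumber into ape convention: tips 1..n, basal node n+1, then upward
  internal_old <- sort(unique(edges[edges > ntip]))
  map <- integer(2L * ntip - 2L)
  map[seq_len(ntip)] <- seq_len(ntip)
  map[internal_old] <- ntip + seq_along(internal_old)
  e2 <- base::matrix(map[edges], ncol = 2)
  tr <- list(edge = e2, edge.length = lens, tip.label = labels,
             Nnode = length(internal_old))
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Burst test on one family's transposase copies
#'
#' Builds a neighbor-joining tree (Poisson-corrected protein distances)
#' over the genome's copies of one family plus outgroup transposases,
#' roots it on the outgroup, and scores the expansion geometry: a single
#' burst shows the copies as one clade on a long stem with shallow crown
#' depths (`burst_ratio = stem_length / mean_crown_depth`).
#'
#' @param copies Named character vector of the genome's copies (proteins).
#' @param outgroup Named character vector of outgroup transposases (>= 1).
#' @param family_id Family label carried into the report.
#' @param ratio_single Burst-ratio threshold (default 3.0) above which a
#'   clade counts as an expansion.
#' @return A list of class `lux_burst`: family_id, n_copies,
#'   monophyletic, stem_length, mean_crown_depth, burst_ratio, verdict
#'   ("single_expansion", "multiple_expansions" or "no_expansion"),
#'   `clades` (per-copy-clade geometry) and `tree`.
#' @export
burst_test <- function(copies, outgroup, family_id = "TE",
                       ratio_single = 3.0) {
  stopifnot(length(outgroup) >= 1)
  if (length(copies) < 2) {
    return(structure(list(
      family_id = family_id, n_copies = length(copies),
      monophyletic = NA, stem_length = NA_real_,
      mean_crown_depth = NA_real_, burst_ratio = NA_real_,
      verdict = "no_expansion",
      note = "fewer than 2 copies: no expansion testable",
      clades = NULL, tree = NULL
    ), class = "lux_burst"))
  }
  if (is.null(names(copies)) || is.null(names(outgroup))) {
    abort("copies and outgroup must be named")
  }
  all_seqs <- c(copies, outgroup)
  D <- protein_distance_matrix(all_seqs)
  tr <- nj_tree(D)
  # root on one outgroup tip: always valid even when the outgroup
  # transposases are themselves paraphyletic in the NJ tree
  tr <- ape::root(tr, outgroup = names(outgroup)[1], resolve.root = TRUE)
  clades <- copy_clades(tr, names(copies), ratio_single)
  mono <- nrow(clades) == 1 && clades$n[1] == length(copies)
  if (mono) {
    stem <- clades$stem[1]
    crown <- clades$crown[1]
    ratio <- clades$ratio[1]
    verdict <- if (ratio >= ratio_single) "single_expansion" else
      "no_expansion"
  } else {
    stem <- NA_real_
    crown <- NA_real_
    ratio <- NA_real_
    expanding <- sum(clades$ratio >= ratio_single & clades$n >= 2)
    verdict <- if (expanding >= 2) "multiple_expansions" else "no_expansion"
  }
  structure(list(
    family_id = family_id, n_copies = length(copies),
    monophyletic = mono, stem_length = stem, mean_crown_depth = crown,
    burst_ratio = ratio, verdict = verdict, note = NULL,
    clades = clades, tree = tr
  ), class = "lux_burst")
}

# maximal clades consisting solely of copy tips, with stem length and mean
# crown depth for each
copy_clades <- function(tree, copy_names, ratio_single) {
  ntip <- length(tree$tip.label)
  is_copy_tip <- tree$tip.label %in% copy_names
  nn <- ntip + tree$Nnode
  # tips below each node
  below <- vector("list", nn)
  for (t in seq_len(ntip)) below[[t]] <- t
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    p <- post[e, 1]
    below[[p]] <- c(below[[p]], below[[post[e, 2]]])
  }
  pure <- map_lgl(below, ~ length(.x) > 0 && all(is_copy_tip[.x]))
  parent_of <- rep(NA_integer_, nn)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  maximal <- which(pure & (is.na(parent_of) | !pure[parent_of]))
  depths <- ape::node.depth.edgelength(tree)
  rows <- lapply(maximal, function(v) {
    eidx <- which(tree$edge[, 2] == v)
    stem <- if (length(eidx) == 1) tree$edge.length[eidx] else NA_real_
    tips <- below[[v]]
    crown <- mean(depths[tips] - depths[v])
    ratio <- if (length(tips) == 1) Inf else
      stem / max(crown, 1e-12)
    tibble(node = v, n = length(tips), stem = stem, crown = crown,
           ratio = ratio)
  })
  bind_rows(rows)
}

#' @export
print.lux_burst <- function(x, ...) {
  cat("<lux_burst> ", x$family_id, ": ", x$n_copies, " copies, verdict ",
      x$verdict, sep = "")
  if (!is.na(x$burst_ratio %||% NA)) {
    cat(" (stem/crown = ", format(x$burst_ratio, digits = 3), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Full TE census of a genome
#'
#' Classifies every CDS protein against the IS reference, calls terminal
#' inverted repeats and completeness per assigned copy (complete =
#' aligned fraction >= 0.9 of the reference AND IRs present), and
#' tabulates per-family counts and the TE percentage of CDS.
#'
#' @param genome A [lux_genome()].
#' @param is_reference Reference tibble (see [classify_transposases()]).
#' @param min_identity,min_coverage,min_score Family-assignment thresholds.
#' @param ir_window,ir_min_len,ir_max_mismatch IR-search parameters.
#' @param complete_min_fraction Aligned-fraction floor for completeness
#'   (default 0.9).
#' @return A list of class `lux_te_census`: `records` (per-copy tibble with
#'   family, identity, coverage, IR call, completeness, coordinates),
#'   `family_counts`, `n_te`, `n_cds`, `te_pct_of_cds`.
#' @export
te_census <- function(genome, is_reference = is_family_reference(),
                      min_identity = 0.3, min_coverage = 0.3,
                      min_score = 100, ir_window = 100, ir_min_len = 10,
                      ir_max_mismatch = 2, complete_min_fraction = 0.9) {
  cls <- classify_transposases(genome, is_reference,
                               min_identity = min_identity,
                               min_coverage = min_coverage,
                               min_score = min_score)
  hits <- filter(cls, !is.na(family_id))
  ft <- genome$features
  recs <- left_join(hits, select(ft, feature_id, contig_id, start, end,
                                 strand), by = "feature_id")
  if (nrow(recs) > 0) {
    ir <- pmap(list(recs$contig_id, recs$start, recs$end),
               function(cid, s, e) {
                 find_terminal_irs(genome$contigs[[cid]], s, e,
                                   window = ir_window, min_len = ir_min_len,
                                   max_mismatch = ir_max_mismatch)
               })
    recs$has_terminal_irs <- !map_lgl(ir, is.null)
    recs$completeness <- ifelse(
      recs$aligned_fraction_of_ref >= complete_min_fraction &
        recs$has_terminal_irs, "complete", "fragment")
  } else {
    recs$has_terminal_irs <- logical()
    recs$completeness <- character()
  }
  n_cds <- sum(ft$kind == "CDS")
  fam <- count(recs, family_id, name = "n") %>% arrange(-n)
  structure(list(
    records = recs,
    family_counts = fam,
    n_te = nrow(recs),
    n_cds = n_cds,
    n_complete = sum(recs$completeness == "complete"),
    te_pct_of_cds = te_fraction(nrow(recs), n_cds)
  ), class = "lux_te_census")
}

#' @export
print.lux_te_census <- function(x, ...) {
  cat("<lux_te_census> ", x$n_te, " TE genes / ", x$n_cds, " CDS (",
      round(x$te_pct_of_cds, 1), "%), ", x$n_complete, " complete\n",
      sep = "")
  if (nrow(x$family_counts) > 0) {
    f <- x$family_counts
    cat("  families: ",
        paste(f$family_id, f$n, sep = ":", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
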