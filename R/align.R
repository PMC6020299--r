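# Protein alignment primitive: optimal affine-gap dynamic programming
# (Gotoh), local (Smith-Waterman style) or global, used by the pseudogene
# caller, the transposase census and the ortholog finder.

aln_env <- new.env(parent = emptyenv())

#' Default protein scoring matrix
#'
#' BLOSUM62 with the `X` (unknown residue) row and column set to 0, so that
#' unknowns neither reward nor penalise.
#'
#' @return A numeric substitution matrix.
#' @export
default_protein_matrix <- function() {
  if (is.null(aln_env$blosum62x)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0
    m[, "X"] <- 0
    aln_env$blosum62x <- m
  }
  aln_env$blosum62x
}

encode_protein <- function(seq, alphabet) {
  chars <- strsplit(str_to_upper(seq), "")[[1]]
  idx <- match(chars, alphabet)
  # unknown letters (U, O, ...) behave like X
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Pairwise protein alignment with affine gaps
#'
#' Optimal dynamic-programming alignment under an affine gap model (a gap of
#' length L costs `gap_open + L * gap_extend`). Local mode returns the
#' maximal-scoring segment pair; global mode aligns the full sequences.
#'
#' @param query,subject Protein sequences (single character strings).
#' @param matrix Substitution matrix (default [default_protein_matrix()]).
#' @param gap_open,gap_extend Gap penalties (positive; defaults 11 and 1).
#' @param mode "local" or "global".
#' @return A list of class `lux_protein_alignment` with elements `score`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based residue coordinates of
#'   the aligned spans), `n_identical`, `n_similar` (aligned pairs with a
#'   positive substitution score), `n_aligned_columns` (residue-residue
#'   columns), `query_length`, `subject_length`, and the matched position
#'   vectors `q_idx`, `s_idx`.
#' @export
align_proteins <- function(query, subject, matrix = default_protein_matrix(),
                           gap_open = 11, gap_extend = 1,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!nzchar(query) || !nzchar(subject)) {
    abort("align_proteins: sequences must be non-empty")
  }
  alphabet <- rownames(matrix)
  qi <- encode_protein(query, alphabet)
  si <- encode_protein(subject, alphabet)
  res <- align_affine_cpp(qi, si, matrix, gap_open, gap_extend,
                          mode == "local")
  qx <- res$q_idx
  sx <- res$s_idx
  ncols <- length(qx)
  if (ncols > 0) {
    subscores <- matrix[cbind(qi[qx] + 1L, si[sx] + 1L)]
    n_id <- sum(qi[qx] == si[sx])
    n_sim <- sum(subscores > 0)
  } else {
    n_id <- 0L
    n_sim <- 0L
  }
  structure(list(
    score = res$score,
    q_start = if (ncols) qx[1] else 0L,
    q_end = if (ncols) qx[ncols] else 0L,
    s_start = if (ncols) sx[1] else 0L,
    s_end = if (ncols) sx[ncols] else 0L,
    n_identical = as.integer(n_id),
    n_similar = as.integer(n_sim),
    n_aligned_columns = as.integer(ncols),
    query_length = length(qi),
    subject_length = length(si),
    mode = mode,
    q_idx = qx,
    s_idx = sx
  ), class = "lux_protein_alignment")
}

#' @export
print.lux_protein_alignment <- function(x, ...) {
  cat("<lux_protein_alignment> score ", x$score, " (", x$mode, ")\n",
      "  query ", x$q_start, "..", x$q_end, " / ", x$query_length,
      "; subject ", x$s_start, "..", x$s_end, " / ", x$subject_length, "\n",
      "  identical ", x$n_identical, ", similar ", x$n_similar,
      ", aligned columns ", x$n_aligned_columns, "\n", sep = "")
  invisible(x)
}

#' Build a k-mer prefilter index over a reference proteome
#'
#' Used to shortlist candidate subjects before exact dynamic programming,
#' in the spirit of seeded database search. Candidates are ranked by the
#' number of distinct shared k-mers.
#'
#' @param reference Named character vector of protein sequences.
#' @param k K-mer length (default 4).
#' @return An opaque index object for [best_hit()].
#' @export
kmer_index <- function(reference, k = 4) {
  stopifnot(length(reference) > 0)
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  km <- lapply(str_to_upper(reference), kmers_of)
  ids <- rep(seq_along(reference), lengths(km))
  idx <- split(ids, unlist(km))
  structure(list(k = k, map = idx, n_ref = length(reference)),
            class = "lux_kmer_index")
}

kmer_candidates <- function(query, index, max_candidates, min_shared = 1) {
  k <- index$k
  n <- nchar(query)
  if (n < k) return(seq_len(index$n_ref))
  qk <- unique(substring(str_to_upper(query), 1:(n - k + 1), k:n))
  hits <- unlist(index$map[qk], use.names = FALSE)
  if (length(hits) == 0) return(integer())
  tab <- tabulate(hits, nbins = index$n_ref)
  cand <- which(tab >= min_shared)
  cand[order(-tab[cand], cand)][seq_len(min(length(cand), max_candidates))]
}

#' Best-scoring hit of a query protein against a reference proteome
#'
#' Scans the reference with score-only affine-gap alignment, then recomputes
#' the full alignment for the winner. Ties on score are broken by the
#' lexicographically smaller subject id. With an `index`, only the
#' `max_candidates` subjects sharing the most k-mers with the query are
#' scored (a seeded-search heuristic); without one the scan is exhaustive.
#'
#' @param query Protein sequence (single string).
#' @param reference Named character vector of reference proteins.
#' @param matrix,gap_open,gap_extend,mode See [align_proteins()].
#' @param min_score Score floor: below it the query has no hit (`NULL`
#'   return) and is treated as an orphan downstream.
#' @param index Optional [kmer_index()] built on `reference`.
#' @param max_candidates Shortlist size when `index` is given.
#' @param encoded Optional pre-encoded reference (from repeated calls
#'   against one proteome; see source of [call_pseudogenes()]).
#' @return A one-row tibble (subject_id, score, spans, counts, lengths,
#'   `length_ratio` = query_length/subject_length, `similarity_frac` =
#'   n_similar/n_aligned_columns), or `NULL` when no hit reaches
#'   `min_score`.
#' @export
best_hit <- function(query, reference, matrix = default_protein_matrix(),
                     gap_open = 11, gap_extend = 1, mode = "local",
                     min_score = 50, index = NULL, max_candidates = 40,
                     encoded = NULL) {
  if (length(reference) == 0) abort("best_hit: empty reference proteome")
  if (is.null(names(reference))) {
    abort("best_hit: reference must be a named vector")
  }
  cand <- if (is.null(index)) seq_along(reference) else
    kmer_candidates(query, index, max_candidates)
  if (length(cand) == 0) return(NULL)
  alphabet <- rownames(matrix)
  qi <- encode_protein(query, alphabet)
  subs <- if (is.null(encoded)) {
    lapply(reference[cand], encode_protein, alphabet = alphabet)
  } else {
    encoded[cand]
  }
  scores <- align_scores_batch_cpp(qi, subs, matrix, gap_open, gap_extend,
                                   mode == "local")
  top <- max(scores)
  if (top < min_score) return(NULL)
  tied <- cand[scores == top]
  win <- tied[order(names(reference)[tied])][1]
  aln <- align_proteins(query, reference[[win]], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend,
                        mode = mode)
  tibble(
    subject_id = names(reference)[win],
    score = aln$score,
    q_start = aln$q_start, q_end = aln$q_end,
    s_start = aln$s_start, s_end = aln$s_end,
    n_identical = aln$n_identical,
    n_similar = aln$n_similar,
    n_aligned_columns = aln$n_aligned_columns,
    query_length = aln$query_length,
    subject_length = aln$subject_length,
    length_ratio = aln$query_length / aln$subject_length,
    similarity_frac = if (aln$n_aligned_columns > 0)
      aln$n_similar / aln$n_aligned_columns else 0
  )
}
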