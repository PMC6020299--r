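# Pseudogene classification: a locus is a possible pseudogene when its
# translated product is shorter than 60% of its best reference hit, or shows
# less than 30% amino-acid similarity to it (strict inequalities). Loci with
# no hit above the score floor are orphans, not pseudogenes: the rule needs
# a reference to compare against.

#' Classify a locus from its best reference hit
#'
#' @param hit A one-row tibble from [best_hit()], or `NULL` for no hit.
#' @param theta_len Length-ratio threshold (default 0.60): pseudogene when
#'   `length_ratio < theta_len`. The ratio compares the full translated
#'   query length with the full subject protein length.
#' @param theta_sim Similarity threshold (default 0.30): pseudogene when
#'   `similarity_frac < theta_sim` (positives fraction over aligned
#'   columns).
#' @return "functional", "pseudogene" or "orphan".
#' @export
classify_locus <- function(hit, theta_len = 0.60, theta_sim = 0.30) {
  stopifnot(theta_len > 0, theta_sim >= 0)
  if (is.null(hit) || nrow(hit) == 0) return("orphan")
  if (hit$length_ratio < theta_len || hit$similarity_frac < theta_sim) {
    "pseudogene"
  } else {
    "functional"
  }
}

#' Call pseudogenes across a genome
#'
#' Translates every CDS, finds its best hit in a reference proteome, and
#' applies the length-ratio / similarity rule. The returned genome carries
#' the assigned statuses; the operation is idempotent.
#'
#' @param genome A [lux_genome()] with CDS features.
#' @param reference Named character vector of reference proteins (e.g. the
#'   proteome of a non-reduced relative).
#' @param theta_len,theta_sim Classification thresholds (see
#'   [classify_locus()]).
#' @param min_score Score floor for [best_hit()].
#' @param max_candidates Shortlist size for the k-mer prefilter; set to
#'   `Inf` for an exhaustive scan.
#' @param matrix,gap_open,gap_extend Aligner parameters.
#' @return A list of class `lux_pseudogene_calls`: `genome` (statuses set),
#'   `calls` (tibble: feature_id, best_subject, score, length_ratio,
#'   similarity_frac, status) and `summary` (n_total_cds, n_functional,
#'   n_pseudogene, n_orphan).
#' @export
call_pseudogenes <- function(genome, reference, theta_len = 0.60,
                             theta_sim = 0.30, min_score = 50,
                             max_candidates = 40,
                             matrix = default_protein_matrix(),
                             gap_open = 11, gap_extend = 1) {
  prots <- cds_proteins(genome)
  if (length(prots) == 0) abort("genome has no CDS features")
  idx <- if (is.finite(max_candidates) && length(reference) > max_candidates)
    kmer_index(reference) else NULL
  enc <- lapply(reference, encode_protein, alphabet = rownames(matrix))
  rows <- vector("list", length(prots))
  for (i in seq_along(prots)) {
    p <- prots[[i]]
    hit <- if (nzchar(p)) {
      best_hit(p, reference, matrix = matrix, gap_open = gap_open,
               gap_extend = gap_extend, min_score = min_score,
               index = idx, max_candidates = max_candidates, encoded = enc)
    } else NULL
    status <- classify_locus(hit, theta_len, theta_sim)
    rows[[i]] <- tibble(
      feature_id = names(prots)[i],
      best_subject = if (is.null(hit)) NA_character_ else hit$subject_id,
      score = if (is.null(hit)) NA_real_ else hit$score,
      length_ratio = if (is.null(hit)) NA_real_ else hit$length_ratio,
      similarity_frac = if (is.null(hit)) NA_real_ else hit$similarity_frac,
      status = status
    )
  }
  calls <- bind_rows(rows)
  ft <- genome$features
  m <- match(ft$feature_id, calls$feature_id)
  upd <- !is.na(m)
  ft$status[upd] <- calls$status[m[upd]]
  # orphans keep CDS status "unknown" in the genome: no evidence either way
  ft$status[upd][calls$status[m[upd]] == "orphan"] <- "unknown"
  genome$features <- ft
  summary <- list(
    n_total_cds = nrow(calls),
    n_functional = sum(calls$status == "functional"),
    n_pseudogene = sum(calls$status == "pseudogene"),
    n_orphan = sum(calls$status == "orphan")
  )
  structure(list(genome = genome, calls = calls, summary = summary),
            class = "lux_pseudogene_calls")
}

#' @export
print.lux_pseudogene_calls <- function(x, ...) {
  s <- x$summary
  cat("<lux_pseudogene_calls> ", s$n_total_cds, " CDS: ",
      s$n_functional, " functional, ", s$n_pseudogene, " pseudogene, ",
      s$n_orphan, " orphan\n", sep = "")
  invisible(x)
}
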