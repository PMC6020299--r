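# Genome-reduction summaries: reciprocal-best-hit orthologs and average
# nucleotide identity over shared coding loci, percent-reduction
# statistics, functional-category counts, and amino-acid-pathway
# completeness.

#' Reciprocal-best-hit ortholog pairs between two genomes
#'
#' Best hits are found by protein alignment score in both directions; a
#' pair is kept when each member is the other's best hit. Nucleotide
#' identity is computed from the codon-level back-mapping of the protein
#' alignment (three nucleotides per aligned residue pair).
#'
#' @param genome_a,genome_b [lux_genome()] objects with CDS.
#' @param min_score Score floor below which a CDS has no hit.
#' @param max_candidates k-mer prefilter shortlist size (see [best_hit()]).
#' @return Tibble of class `lux_ortholog_pairs`: gene_id_a, gene_id_b,
#'   identity (nucleotide %, 0-100), aligned_len (nt columns compared).
#' @export
ortholog_pairs <- function(genome_a, genome_b, min_score = 50,
                           max_candidates = 40) {
  prot_a <- cds_proteins(genome_a)
  prot_b <- cds_proteins(genome_b)
  prot_a <- prot_a[nzchar(prot_a)]
  prot_b <- prot_b[nzchar(prot_b)]
  if (length(prot_a) == 0 || length(prot_b) == 0) {
    abort("both genomes need translatable CDS")
  }
  fwd <- best_hit_table(prot_a, prot_b, min_score, max_candidates)
  rev <- best_hit_table(prot_b, prot_a, min_score, max_candidates)
  rbh <- fwd %>%
    left_join(rename(rev, back = subject_id),
              by = c("subject_id" = "query_id")) %>%
    filter(!is.na(back), back == query_id) %>%
    select(gene_id_a = query_id, gene_id_b = subject_id)
  nt_a <- feature_seqs(genome_a, rbh$gene_id_a)
  nt_b <- feature_seqs(genome_b, rbh$gene_id_b)
  stats <- pmap(list(rbh$gene_id_a, rbh$gene_id_b), function(ga, gb) {
    codon_identity(prot_a[[ga]], prot_b[[gb]], nt_a[[ga]], nt_b[[gb]])
  })
  out <- mutate(rbh,
                identity = map_dbl(stats, "identity"),
                aligned_len = map_int(stats, "aligned_len"))
  class(out) <- c("lux_ortholog_pairs", class(out))
  out
}

best_hit_table <- function(qs, refs, min_score, max_candidates) {
  idx <- if (length(refs) > max_candidates) kmer_index(refs) else NULL
  enc <- lapply(refs, encode_protein,
                alphabet = rownames(default_protein_matrix()))
  rows <- lapply(seq_along(qs), function(i) {
    h <- best_hit(qs[[i]], refs, min_score = min_score, index = idx,
                  max_candidates = max_candidates, encoded = enc)
    if (is.null(h)) return(NULL)
    tibble(query_id = names(qs)[i], subject_id = h$subject_id)
  })
  bind_rows(rows)
}

# nucleotide identity over the codons backing the aligned residue pairs
codon_identity <- function(pa, pb, nta, ntb) {
  a <- align_proteins(pa, pb, mode = "local")
  if (a$n_aligned_columns == 0) {
    return(list(identity = 0, aligned_len = 0L))
  }
  ca <- substring(nta, 3L * (a$q_idx - 1L) + 1L, 3L * a$q_idx)
  cb <- substring(ntb, 3L * (a$s_idx - 1L) + 1L, 3L * a$s_idx)
  xa <- strsplit(paste(ca, collapse = ""), "")[[1]]
  xb <- strsplit(paste(cb, collapse = ""), "")[[1]]
  list(identity = 100 * mean(xa == xb),
       aligned_len = length(xa))
}

#' Average nucleotide identity over ortholog pairs
#'
#' Length-weighted mean of per-pair nucleotide identities:
#' `sum(identity_i * len_i) / sum(len_i)`. Set `weighted = FALSE` for the
#' unweighted mean.
#'
#' @param pairs Tibble from [ortholog_pairs()] (needs `identity` and
#'   `aligned_len`).
#' @param weighted Length-weight the mean (default TRUE).
#' @return ANI as a percentage.
#' @export
ani <- function(pairs, weighted = TRUE) {
  if (nrow(pairs) == 0) abort("ani: no ortholog pairs")
  if (weighted) {
    sum(pairs$identity * pairs$aligned_len) / sum(pairs$aligned_len)
  } else {
    mean(pairs$identity)
  }
}

#' Percent reduction of a count against a reference mean
#'
#' `100 * (1 - target / reference)`; negative when the target exceeds the
#' reference.
#'
#' @param target_count Count in the reduced genome.
#' @param reference_mean_count Mean count among non-reduced relatives
#'   (> 0).
#' @return Percent reduction (double).
#' @export
reduction_stats <- function(target_count, reference_mean_count) {
  stopifnot(reference_mean_count > 0)
  100 * (1 - target_count / reference_mean_count)
}

#' Gene counts per functional category
#'
#' Counts functional genes per category tag; a gene tagged in several
#' categories contributes to each (so the column total can exceed the gene
#' count). Untagged genes are tallied as "uncategorized".
#'
#' @param genome A [lux_genome()].
#' @param category_map Optional tibble (feature_id, category) adding tags
#'   to those in the genome's features.
#' @param include_pseudogenes Also count pseudogenes (default FALSE).
#' @return Tibble: category, n.
#' @export
category_counts <- function(genome, category_map = NULL,
                            include_pseudogenes = FALSE) {
  ft <- filter(genome$features, kind == "CDS")
  if (!include_pseudogenes) ft <- filter(ft, status == "functional")
  if (nrow(ft) == 0) return(tibble(category = character(), n = integer()))
  tags <- ft$category_tags
  if (!is.null(category_map)) {
    extra <- split(category_map$category, category_map$feature_id)
    tags <- map2(tags, ft$feature_id, function(tg, id) {
      union(tg, extra[[id]] %||% character())
    })
  }
  tags <- map(tags, ~ if (length(.x) == 0) "uncategorized" else .x)
  tibble(category = unlist(tags)) %>%
    count(category, name = "n") %>%
    arrange(category)
}

#' Read pathway definitions from TSV
#'
#' Two columns: `pathway_id` and `enzyme` (one row per required enzyme,
#' ordered). A small synthetic amino-acid-synthesis fixture ships with the
#' package (`system.file("extdata", "aa_pathways_synthetic.tsv", package =
#' "luxerode")`).
#'
#' @param path TSV path.
#' @return Tibble (pathway_id, enzyme).
#' @export
read_pathways <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pathway_id", "enzyme") %in% names(tab))) {
    abort("pathway TSV needs columns pathway_id, enzyme")
  }
  as_tibble(tab[, c("pathway_id", "enzyme")])
}

#' Pathway completeness against functional gene products
#'
#' A pathway is complete when every required enzyme label matches at least
#' one functional gene (by product or feature id); enzymes present only as
#' pseudogenes do not count.
#'
#' @param genome A [lux_genome()].
#' @param pathway_defs Tibble (pathway_id, enzyme).
#' @return A list of class `lux_pathways`: `per_pathway` tibble
#'   (pathway_id, n_present, n_required, complete) and `n_complete`.
#' @export
pathway_completeness <- function(genome, pathway_defs) {
  ft <- filter(genome$features, kind == "CDS", status == "functional")
  labels <- unique(c(ft$feature_id, ft$product))
  per <- pathway_defs %>%
    group_by(pathway_id) %>%
    summarise(n_present = sum(enzyme %in% labels),
              n_required = n(),
              complete = n_present == n_required,
              .groups = "drop")
  structure(list(per_pathway = per, n_complete = sum(per$complete)),
            class = "lux_pathways")
}

#' @export
print.lux_pathways <- function(x, ...) {
  cat("<lux_pathways> ", x$n_complete, "/", nrow(x$per_pathway),
      " pathways complete\n", sep = "")
  invisible(x)
}
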