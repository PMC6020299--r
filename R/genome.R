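#' Construct an annotated genome
#'
#' The central data model: contig sequences plus a tibble of typed features
#' (CDS, rRNA, tRNA) with a functional/pseudogene status. Coordinates are
#' 1-based inclusive and always refer to the forward strand.
#'
#' @param genome_id Character label for the genome.
#' @param contigs Named character vector of contig sequences (A/C/G/T plus
#'   IUPAC ambiguity codes, which are preserved).
#' @param features Tibble with columns `feature_id`, `contig_id`, `start`,
#'   `end`, `strand` ("+"/"-"), `kind` ("CDS", "rRNA" or "tRNA"), `status`
#'   ("functional", "pseudogene" or "unknown"), `product` and
#'   `category_tags` (list column of character vectors). Missing columns are
#'   filled with defaults.
#' @param source Free-text provenance note.
#'
#' @return An object of class `lux_genome`.
#' @export
lux_genome <- function(genome_id, contigs, features = NULL, source = "") {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) > 0) {
    abort("contigs must be a uniquely named character vector")
  }
  contigs <- setNames(str_to_upper(as.character(contigs)), names(contigs))
  features <- as_feature_table(features)
  g <- structure(
    list(genome_id = genome_id, contigs = contigs, features = features,
         source = source),
    class = "lux_genome"
  )
  validate_genome(g)
}

feature_cols <- c("feature_id", "contig_id", "start", "end", "strand",
                  "kind", "status", "product", "category_tags")

as_feature_table <- function(features) {
  if (is.null(features)) {
    features <- tibble(
      feature_id = character(), contig_id = character(),
      start = integer(), end = integer(), strand = character(),
      kind = character(), status = character(), product = character(),
      category_tags = list()
    )
  }
  features <- as_tibble(features)
  if (!"status" %in% names(features)) features$status <- "unknown"
  if (!"product" %in% names(features)) features$product <- ""
  if (!"category_tags" %in% names(features)) {
    features$category_tags <- rep(list(character()), nrow(features))
  }
  missing <- setdiff(feature_cols, names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features[, feature_cols]
}

validate_genome <- function(g) {
  ft <- g$features
  if (nrow(ft) == 0) return(g)
  if (anyDuplicated(ft$feature_id) > 0) {
    abort(paste0("duplicated feature_id: ",
                 paste(unique(ft$feature_id[duplicated(ft$feature_id)]),
                       collapse = ", ")))
  }
  bad <- ft$start > ft$end
  if (any(bad)) {
    abort(paste0("start > end for feature(s): ",
                 paste(ft$feature_id[bad], collapse = ", ")))
  }
  unknown_contig <- !ft$contig_id %in% names(g$contigs)
  if (any(unknown_contig)) {
    abort(paste0("feature(s) on unknown contig: ",
                 paste(ft$feature_id[unknown_contig], collapse = ", ")))
  }
  clen <- setNames(str_length(g$contigs), names(g$contigs))[ft$contig_id]
  outside <- ft$start < 1L | ft$end > clen
  if (any(outside)) {
    abort(paste0("feature coordinates outside contig: ",
                 paste(ft$feature_id[outside], collapse = ", ")))
  }
  is_cds_fun <- ft$kind == "CDS" & ft$status == "functional"
  badlen <- is_cds_fun & ((ft$end - ft$start + 1L) %% 3L != 0L)
  if (any(badlen)) {
    warn(paste0("functional CDS with length not divisible by 3: ",
                paste(ft$feature_id[badlen], collapse = ", ")))
  }
  g
}

#' @export
print.lux_genome <- function(x, ...) {
  cat("<lux_genome> ", x$genome_id, "\n", sep = "")
  cat("  contigs:  ", length(x$contigs), " (",
      format(sum(str_length(x$contigs)), big.mark = ","), " bp)\n", sep = "")
  ft <- x$features
  cat("  features: ", nrow(ft), sep = "")
  if (nrow(ft) > 0) {
    tab <- table(ft$kind)
    cat(" [", paste(names(tab), tab, sep = ":", collapse = ", "), "]",
        sep = "")
    ps <- sum(ft$status == "pseudogene")
    cat("; pseudogene status: ", ps, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Total genome length in bp
#' @param genome A `lux_genome`.
#' @return Integer number of base pairs summed over contigs.
#' @export
genome_length <- function(genome) {
  sum(str_length(genome$contigs))
}

#' Extract feature sequences
#'
#' Returns the nucleotide sequence of each requested feature, reverse
#' complemented for minus-strand features so that CDS sequences read
#' 5' to 3'.
#'
#' @param genome A `lux_genome`.
#' @param feature_id Character vector of feature ids (default: all features).
#' @return Named character vector of sequences.
#' @export
feature_seqs <- function(genome, feature_id = NULL) {
  ft <- genome$features
  if (!is.null(feature_id)) {
    miss <- setdiff(feature_id, ft$feature_id)
    if (length(miss) > 0) {
      abort(paste0("unknown feature_id: ", paste(miss, collapse = ", ")))
    }
    ft <- ft[match(feature_id, ft$feature_id), ]
  }
  if (nrow(ft) == 0) return(setNames(character(), character()))
  seqs <- substring(genome$contigs[ft$contig_id], ft$start, ft$end)
  neg <- ft$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  setNames(seqs, ft$feature_id)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate the CDS features of a genome
#'
#' Translates every CDS to protein. Sequences are trimmed to a whole number
#' of codons; translation stops at the first stop codon. CDS whose
#' translation is interrupted by an internal stop are kept (truncated at the
#' stop) and their count is reported via a message.
#'
#' @param genome A `lux_genome`.
#' @param quiet Suppress the internal-stop message.
#' @return Named character vector of protein sequences (names: feature_id).
#' @export
cds_proteins <- function(genome, quiet = FALSE) {
  ft <- filter(genome$features, kind == "CDS")
  if (nrow(ft) == 0) return(setNames(character(), character()))
  nts <- feature_seqs(genome, ft$feature_id)
  translate_cds(nts, quiet = quiet)
}

translate_cds <- function(nts, quiet = FALSE) {
  keep_len <- (str_length(nts) %/% 3L) * 3L
  trimmed <- substr(nts, 1L, keep_len)
  nonempty <- keep_len >= 3L
  aa <- rep("", length(nts))
  if (any(nonempty)) {
    dss <- Biostrings::DNAStringSet(trimmed[nonempty])
    prot <- suppressWarnings(
      as.character(Biostrings::translate(dss, if.fuzzy.codon = "solve"))
    )
    aa[nonempty] <- prot
  }
  # cut at first stop; count internal stops (a stop before the final codon)
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  internal <- stop_pos > 0 & stop_pos < nchar(aa)
  if (any(internal) && !quiet) {
    inform(paste0(sum(internal),
                  " CDS translated to the first internal stop codon"))
  }
  cut <- stop_pos > 0
  aa[cut] <- substr(aa[cut], 1L, stop_pos[cut] - 1L)
  setNames(aa, names(nts))
}

#' Summarise a genome in standard overview shape
#'
#' One row per genome with size, contig count, GC content and feature
#' counts, the shape used to compare reduced symbiont genomes with
#' free-living relatives.
#'
#' @param genome A `lux_genome`.
#' @return A one-row tibble.
#' @export
genome_summary <- function(genome) {
  ft <- genome$features
  bases <- str_split(paste(genome$contigs, collapse = ""), "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  tibble(
    genome_id = genome$genome_id,
    size_bp = genome_length(genome),
    n_contigs = length(genome$contigs),
    gc_pct = round(100 * gc, 1),
    total_cds = sum(ft$kind == "CDS"),
    complete_cds = sum(ft$kind == "CDS" & ft$status == "functional"),
    pseudogenes = sum(ft$kind == "CDS" & ft$status == "pseudogene"),
    rrna = sum(ft$kind == "rRNA"),
    trna = sum(ft$kind == "tRNA")
  )
}
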