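#' Read an annotated genome from FASTA + GFF3
#'
#' Contig sequences come from the FASTA, features from the GFF3. Only CDS,
#' rRNA and tRNA features are kept; other feature kinds are skipped with a
#' message reporting their count. A `pseudo` attribute (any value other than
#' "false") or `status=pseudogene` marks a feature as pseudogene.
#'
#' @param fasta_path Path to the contig FASTA.
#' @param gff3_path Path to the GFF3 annotation. Contig ids must match the
#'   FASTA.
#' @param genome_id Genome label (default: FASTA file stem).
#' @return A [lux_genome()].
#' @export
read_genome <- function(fasta_path, gff3_path,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  gr <- rtracklayer::import.gff3(gff3_path)
  type <- as.character(gr$type)
  keep <- type %in% c("CDS", "rRNA", "tRNA")
  if (any(!keep)) {
    inform(paste0("skipped ", sum(!keep), " feature(s) of unknown kind"))
    gr <- gr[keep]
    type <- type[keep]
  }
  mc <- as.data.frame(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  if (all(is.na(ids))) ids <- paste0("feature_", seq_len(nrow(mc)))
  status <- if ("status" %in% names(mc)) as.character(mc$status) else
    rep(NA_character_, nrow(mc))
  if ("pseudo" %in% names(mc)) {
    pse <- !is.na(mc$pseudo) & tolower(as.character(mc$pseudo)) != "false"
    status[pse] <- "pseudogene"
  }
  status[is.na(status)] <- "unknown"
  product <- if ("product" %in% names(mc)) as.character(mc$product) else ""
  product[is.na(product)] <- ""
  tags <- if ("category_tags" %in% names(mc)) {
    lapply(mc$category_tags, function(x) as.character(x))
  } else {
    rep(list(character()), nrow(mc))
  }
  features <- tibble(
    feature_id = ids,
    contig_id = as.character(mc$seqnames),
    start = as.integer(mc$start),
    end = as.integer(mc$end),
    strand = ifelse(as.character(mc$strand) == "-", "-", "+"),
    kind = type,
    status = status,
    product = product,
    category_tags = tags
  )
  missing_contig <- setdiff(unique(features$contig_id), names(contigs))
  if (length(missing_contig) > 0) {
    abort(paste0("GFF3 refers to contig(s) absent from FASTA: ",
                 paste(missing_contig, collapse = ", ")))
  }
  lux_genome(genome_id, contigs, features)
}

#' Write an annotated genome as FASTA + GFF3
#'
#' Round-trips losslessly with [read_genome()] at the field level.
#'
#' @param genome A `lux_genome`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta_path)
  ft <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = ft$contig_id,
    ranges = IRanges::IRanges(ft$start, ft$end),
    strand = ft$strand
  )
  gr$type <- ft$kind
  gr$ID <- ft$feature_id
  gr$status <- ft$status
  gr$product <- ft$product
  gr$category_tags <- IRanges::CharacterList(ft$category_tags)
  suppressWarnings(rtracklayer::export.gff3(gr, gff3_path))
  invisible(genome)
}

#' Multiple sequence alignment container
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @param alphabet "nucleotide" or "amino-acid"; guessed from the residues
#'   when `NULL`.
#' @return An object of class `lux_alignment`.
#' @export
lux_alignment <- function(seqs, alphabet = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) > 0) {
    abort("aligned sequences must be uniquely named")
  }
  seqs <- setNames(str_to_upper(as.character(seqs)), names(seqs))
  lens <- str_length(seqs)
  if (length(unique(lens)) > 1) {
    ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- names(seqs)[lens != ref]
    abort(paste0("alignment rows differ in length: ",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(alphabet)) {
    res <- unique(str_split(paste(seqs, collapse = ""), "")[[1]])
    res <- setdiff(res, "-")
    alphabet <- if (all(res %in% c("A", "C", "G", "T", "U", "N")))
      "nucleotide" else "amino-acid"
  }
  structure(list(seqs = seqs, alphabet = alphabet), class = "lux_alignment")
}

#' @export
print.lux_alignment <- function(x, ...) {
  cat("<lux_alignment> ", length(x$seqs), " x ",
      if (length(x$seqs)) str_length(x$seqs[[1]]) else 0,
      " (", x$alphabet, ")\n", sep = "")
  invisible(x)
}

#' Read a multiple alignment (FASTA or relaxed PHYLIP)
#'
#' Relaxed PHYLIP: a header line `ntaxa nsites`, then one `name sequence`
#' row per taxon (whitespace-separated, sequence may contain spaces).
#' Ragged rows are rejected with an error naming the offending ids.
#'
#' @param path Input file.
#' @param dialect "auto" (default; sniffs a leading `>`), "fasta" or
#'   "phylip".
#' @return A [lux_alignment()].
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "phylip")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (length(first) > 0 && startsWith(first, ">"))
      "fasta" else "phylip"
  }
  if (dialect == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    return(lux_alignment(seqs))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    abort("not a PHYLIP file: header must be '<ntaxa> <nsites>'")
  }
  ntax <- as.integer(hdr[1]); nsite <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) != ntax) {
    abort(paste0("PHYLIP header declares ", ntax, " sequences but file has ",
                 length(body)))
  }
  parts <- str_split(trimws(body), "\\s+")
  nm <- map_chr(parts, 1)
  seqs <- map_chr(parts, ~ paste(.x[-1], collapse = ""))
  lens <- str_length(seqs)
  if (any(lens != nsite)) {
    abort(paste0("row length differs from header (", nsite, "): ",
                 paste(nm[lens != nsite], collapse = ", ")))
  }
  lux_alignment(setNames(seqs, nm))
}

#' Write a multiple alignment
#'
#' @param aln A [lux_alignment()].
#' @param path Output file.
#' @param dialect "fasta" or "phylip" (relaxed).
#' @return Invisibly, `aln`.
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "phylip")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  } else {
    lines <- c(paste(length(aln$seqs), str_length(aln$seqs[[1]])),
               paste(names(aln$seqs), aln$seqs))
    writeLines(lines, path)
  }
  invisible(aln)
}

pileup_cols <- c("contig", "pos", "ref", "depth", "A", "C", "G", "T")

#' Read a per-site pileup table
#'
#' An 8-column TSV with header `contig pos ref depth A C G T`; `depth` must
#' equal the sum of the four base counts on every row (rows violating this
#' are reported with their line numbers). An empty file yields an empty
#' table.
#'
#' @param tsv_path Input TSV.
#' @return Tibble with the eight pileup columns.
#' @export
read_pileup <- function(tsv_path) {
  empty <- tibble(contig = character(), pos = integer(), ref = character(),
                  depth = integer(), A = integer(), C = integer(),
                  G = integer(), T = integer())
  if (file.size(tsv_path) == 0) return(empty)
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           contig = readr::col_character(),
                           pos = readr::col_integer(),
                           ref = readr::col_character(),
                           depth = readr::col_integer(),
                           A = readr::col_integer(),
                           C = readr::col_integer(),
                           G = readr::col_integer(),
                           T = readr::col_integer()))
  if (!identical(names(tab), pileup_cols)) {
    abort(paste0("pileup header must be: ", paste(pileup_cols, collapse = " ")))
  }
  if (nrow(tab) == 0) return(empty)
  validate_pileup(tab)
}

validate_pileup <- function(tab) {
  tot <- tab$A + tab$C + tab$G + tab$T
  bad <- which(tot != tab$depth)
  if (length(bad) > 0) {
    abort(paste0("depth != A+C+G+T on data line(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  as_tibble(tab)
}

#' Write a per-site pileup table
#' @param pileup Tibble in pileup shape (see [read_pileup()]).
#' @param tsv_path Output path.
#' @return Invisibly, `pileup`.
#' @export
write_pileup <- function(pileup, tsv_path) {
  validate_pileup(pileup)
  readr::write_tsv(pileup, tsv_path, progress = FALSE)
  invisible(pileup)
}

#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] that turns silent parse failures
#' into errors.
#'
#' @param newick_path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(newick_path) {
  tr <- tryCatch(ape::read.tree(newick_path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) {
    txt <- paste(readLines(newick_path), collapse = "")
    depth <- cumsum((strsplit(txt, "")[[1]] == "(") -
                      (strsplit(txt, "")[[1]] == ")"))
    off <- if (any(depth < 0)) which(depth < 0)[1] else nchar(txt)
    abort(paste0("newick parse error near character ", off))
  }
  tr
}

#' Write a newick tree
#'
#' Branch lengths are preserved to 10 significant digits.
#'
#' @param tree An `ape::phylo` tree.
#' @param newick_path Output path.
#' @return Invisibly, `tree`.
#' @export
write_tree <- function(tree, newick_path) {
  ape::write.tree(tree, file = newick_path, digits = 10)
  invisible(tree)
}
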