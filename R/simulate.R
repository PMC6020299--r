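# Synthetic ancestor/derived genome pairs, alignments and pileups with full
# ground truth, emulating the degradation syndrome of host-restricted
# luminous symbionts: gene deletion, truncation pseudogenization (often at
# transposon insertion points), proliferation of a few transposase families
# followed by decay, clade-specific rate acceleration, and pileups with a
# sequencing-error floor plus a minority of true polymorphic sites.

# run `code` under a dedicated RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sample_bases <- function(n, gc_frac) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc_frac) / 2, gc_frac / 2, gc_frac / 2,
                  (1 - gc_frac) / 2))
}

# an ORF: ATG + sense codons + stop, no internal stop
random_orf <- function(n_codons, gc_frac) {
  n_sense <- max(n_codons - 2L, 1L)
  bases <- sample_bases(3L * n_sense, gc_frac)
  codons <- apply(matrix(bases, nrow = 3L), 2, paste, collapse = "")
  while (any(codons %in% STOP_CODONS)) {
    bad <- codons %in% STOP_CODONS
    codons[bad] <- apply(matrix(sample_bases(3L * sum(bad), gc_frac),
                                nrow = 3L), 2, paste, collapse = "")
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1))
}

DEFAULT_CATEGORIES <- c("metabolism", "transport", "energy_metabolism",
                        "cell_wall", "motility_chemotaxis", "regulation",
                        "dna_repair", "translation")

#' Simulate an ancestral (non-reduced) genome
#'
#' One contig of ORF genes (start codon, stop codon, no internal stops)
#' separated by intergenic spacers, each gene tagged with one or two
#' functional categories. Optionally a contiguous run of genes forms a
#' single-category cluster (emulating an operon/necessary-gene block that
#' degradation can be told to protect). Deterministic given `seed`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param mean_gene_len Mean gene length in nt (Poisson-distributed codon
#'   counts; default 900).
#' @param intergenic_len Mean intergenic spacer length in nt (default 150).
#' @param gc_frac Target GC fraction (default 0.4, the low-GC regime of
#'   reduced symbiont genomes).
#' @param categories Category labels to tag genes with.
#' @param cluster Optional `list(category =, start =, n =)` marking genes
#'   `start..start+n-1` as a contiguous cluster with that single category.
#' @param genome_id Genome label.
#' @param seed RNG seed.
#' @return A [lux_genome()] whose CDS are all functional.
#' @export
simulate_ancestor <- function(n_genes, mean_gene_len = 900,
                              intergenic_len = 150, gc_frac = 0.4,
                              categories = DEFAULT_CATEGORIES,
                              cluster = NULL, genome_id = "ancestor",
                              seed = 1) {
  stopifnot(n_genes >= 1, mean_gene_len >= 30, gc_frac > 0, gc_frac < 1)
  with_seed(seed, {
    n_codons <- pmax(10L, rpois(n_genes, mean_gene_len / 3))
    genes <- vapply(n_codons, random_orf, character(1), gc_frac = gc_frac)
    spacers <- vapply(pmax(10L, rpois(n_genes + 1L, intergenic_len)),
                      function(n) paste(sample_bases(n, gc_frac),
                                        collapse = ""), character(1))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    tags <- lapply(seq_len(n_genes), function(i) {
      sort(sample(categories, sample(1:2, 1)))
    })
    if (!is.null(cluster)) {
      idx <- cluster$start:(cluster$start + cluster$n - 1L)
      if (any(idx < 1 | idx > n_genes)) abort("cluster outside gene range")
      for (i in idx) tags[[i]] <- cluster$category
    }
    fwd <- ifelse(strands == "+", genes, revcomp(genes))
    pieces <- character(2 * n_genes + 1)
    pieces[seq(1, 2 * n_genes + 1, by = 2)] <- spacers
    pieces[seq(2, 2 * n_genes, by = 2)] <- fwd
    lens <- str_length(pieces)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    gi <- seq(2, 2 * n_genes, by = 2)
    features <- tibble(
      feature_id = sprintf("gene_%05d", seq_len(n_genes)),
      contig_id = "contig_1",
      start = as.integer(starts[gi]),
      end = as.integer(ends[gi]),
      strand = strands,
      kind = "CDS",
      status = "functional",
      product = sprintf("protein gene_%05d", seq_len(n_genes)),
      category_tags = tags
    )
    lux_genome(genome_id, c(contig_1 = paste(pieces, collapse = "")),
               features)
  })
}

# ---- synthetic insertion-sequence family references ---------------------

IS_FAMILY_IDS <- c("IS5", "IS982", "IS256", "ISL3", "Tn3", "IS200/IS605",
                   "IS66", "IS6", "ISAs1")

sim_env <- new.env(parent = emptyenv())

#' Synthetic insertion-sequence family reference set
#'
#' A deterministic, fully synthetic stand-in for a curated transposase
#' reference database: one representative element per IS family (terminal
#' inverted repeats flanking a transposase ORF) plus its protein. Useful for
#' testing and simulation; for real annotation supply your own reference
#' proteins in the same shape.
#'
#' @param families Subset of family ids (default: all nine built-ins).
#' @return Tibble: family_id, element_nt (IR + ORF + IR), protein,
#'   full_length_aa, ir_len.
#' @export
is_family_reference <- function(families = IS_FAMILY_IDS) {
  if (is.null(sim_env$is_ref)) {
    rows <- lapply(seq_along(IS_FAMILY_IDS), function(i) {
      with_seed(770 + i, {
        n_codons <- sample(260:420, 1)
        orf <- random_orf(n_codons, gc_frac = 0.45)
        ir <- paste(sample_bases(15, 0.45), collapse = "")
        elem <- paste0(ir, orf, revcomp(ir))
        prot <- unname(translate_cds(setNames(orf, "x"), quiet = TRUE))
        tibble(family_id = IS_FAMILY_IDS[i], element_nt = elem,
               protein = prot, full_length_aa = str_length(prot),
               ir_len = 15L)
      })
    })
    sim_env$is_ref <- bind_rows(rows)
  }
  out <- sim_env$is_ref
  miss <- setdiff(families, out$family_id)
  if (length(miss) > 0) {
    abort(paste0("unknown IS family: ", paste(miss, collapse = ", ")))
  }
  out[match(families, out$family_id), ]
}

#' Degradation parameters for [degrade_genome()]
#'
#' @param deletion_frac Per-gene deletion probability.
#' @param pseudo_frac Per-gene truncation-pseudogenization probability.
#' @param truncation_range Uniform bounds on the surviving fraction of a
#'   pseudogenized CDS (default c(0.2, 0.45): clear-cut truncations).
#' @param te_bursts List of bursts, each `list(family_id, n_copies,
#'   sub_rate, trunc_prob, trunc_range, founder_sub_rate)`: per-copy decay
#'   substitution rate and truncation probability/surviving-fraction
#'   bounds, plus an optional founder divergence (substitutions applied
#'   once to the family element before copying, kept stop-free inside the
#'   ORF, emulating an element lineage long separated from the database
#'   representative; default 0).
#' @param te_pseudo_frac Fraction of pseudogenizations caused by a TE
#'   inserting into the gene (recorded in the truth).
#' @param protected_categories Category labels whose gene clusters receive
#'   no TE insertions (and are kept intact, mirroring purifying selection
#'   on necessary genes).
#' @param tsd_len Target-site duplication length at each insertion
#'   (default 4 nt).
#' @param rng_seed RNG seed recorded in the truth record.
#' @return A validated list of class `lux_degradation_params`.
#' @export
degradation_params <- function(deletion_frac = 0.2, pseudo_frac = 0.3,
                               truncation_range = c(0.2, 0.45),
                               te_bursts = list(), te_pseudo_frac = 0.5,
                               protected_categories = character(),
                               tsd_len = 4L, rng_seed = 1) {
  stopifnot(deletion_frac >= 0, deletion_frac <= 1,
            pseudo_frac >= 0, pseudo_frac <= 1,
            deletion_frac + pseudo_frac <= 1,
            length(truncation_range) == 2,
            truncation_range[1] > 0, truncation_range[2] < 1,
            truncation_range[1] <= truncation_range[2],
            te_pseudo_frac >= 0, te_pseudo_frac <= 1, tsd_len >= 0)
  for (b in te_bursts) {
    stopifnot(is.character(b$family_id), b$n_copies >= 0,
              b$sub_rate >= 0, b$sub_rate < 1,
              b$trunc_prob >= 0, b$trunc_prob <= 1,
              (b$founder_sub_rate %||% 0) >= 0,
              (b$founder_sub_rate %||% 0) < 1)
    if (is.null(b$trunc_range)) b$trunc_range <- c(0.4, 0.9)
  }
  structure(list(
    deletion_frac = deletion_frac, pseudo_frac = pseudo_frac,
    truncation_range = truncation_range, te_bursts = te_bursts,
    te_pseudo_frac = te_pseudo_frac,
    protected_categories = protected_categories,
    tsd_len = as.integer(tsd_len), rng_seed = rng_seed
  ), class = "lux_degradation_params")
}

# mutate an IS element while keeping its transposase ORF free of new
# in-frame stops (the IRs mutate freely); the ORF occupies
# [ir_len + 1, length - ir_len] in frame 0
mutate_element_stopfree <- function(element_nt, ir_len, sub_rate) {
  if (sub_rate <= 0) return(element_nt)
  mut <- mutate_seq(element_nt, sub_rate)
  n <- str_length(mut)
  orf_starts <- seq(ir_len + 1L, n - ir_len - 2L, by = 3L)
  codons <- substring(mut, orf_starts, orf_starts + 2L)
  # revert any new in-frame internal stop to its original codon (the
  # original ORF had none, so one pass suffices)
  bad <- which(codons[-length(codons)] %in% STOP_CODONS)
  if (length(bad) > 0) {
    chars <- strsplit(mut, "")[[1]]
    orig <- strsplit(element_nt, "")[[1]]
    for (ci in bad) {
      at <- orf_starts[ci]
      chars[at:(at + 2L)] <- orig[at:(at + 2L)]
    }
    mut <- paste(chars, collapse = "")
  }
  mut
}

mutate_seq <- function(seq, sub_rate) {
  n <- str_length(seq)
  nsub <- rbinom(1, n, sub_rate)
  if (nsub == 0) return(seq)
  pos <- sample.int(n, nsub)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# build one decayed TE copy; returns list(seq (element orientation),
# truncated, kept_frac, lost_end)
decay_te_copy <- function(element_nt, sub_rate, trunc_prob, trunc_range) {
  seq <- mutate_seq(element_nt, sub_rate)
  truncated <- runif(1) < trunc_prob
  kept <- 1
  lost_end <- NA_character_
  if (truncated) {
    kept <- runif(1, trunc_range[1], trunc_range[2])
    keep_nt <- max(30L, floor(kept * str_length(seq)))
    if (runif(1) < 0.5) {
      lost_end <- "3prime"
      seq <- substr(seq, 1L, keep_nt)
    } else {
      lost_end <- "5prime"
      seq <- substr(seq, str_length(seq) - keep_nt + 1L, str_length(seq))
    }
  }
  list(seq = seq, truncated = truncated, kept_frac = kept,
       lost_end = lost_end)
}

#' Degrade an ancestral genome, with ground truth
#'
#' Applies the reduced-genome syndrome to an ancestor: per-gene deletion,
#' truncation-based pseudogenization (a configurable fraction caused by a
#' transposon inserting into the gene), and bursts of IS-like elements
#' inserted at intergenic sites (with a target-site duplication) and then
#' decayed by point substitutions and/or truncation. Genes carrying a
#' protected category are kept intact and their clusters receive no
#' insertions. Gene fates partition the ancestral gene set exactly.
#' Intergenic insertions are placed on the first contig (the generator
#' produces single-contig ancestors).
#'
#' @param ancestor A [lux_genome()] (typically from [simulate_ancestor()]).
#' @param params A [degradation_params()].
#' @return A list with `genome` (the derived [lux_genome()]) and `truth`, a
#'   list of class `lux_truth` holding `fates` (feature_id, fate,
#'   trunc_frac, te_caused), `te_copies` (copy_id, family_id, contig,
#'   start, end, strand, sub_rate, truncated, kept_frac, interrupts),
#'   `protected` spans (derived coordinates), and the seed.
#' @export
degrade_genome <- function(ancestor, params) {
  stopifnot(inherits(params, "lux_degradation_params"))
  with_seed(params$rng_seed, {
    ft <- arrange(ancestor$features, contig_id, start)
    is_cds <- ft$kind == "CDS"
    protected <- map_lgl(ft$category_tags, function(tg) {
      length(intersect(tg, params$protected_categories)) > 0
    })
    n <- nrow(ft)
    u <- runif(n)
    fate <- ifelse(u < params$deletion_frac, "deleted",
                   ifelse(u < params$deletion_frac + params$pseudo_frac,
                          "pseudogenized", "retained"))
    fate[!is_cds | protected] <- "retained"
    trunc_frac <- rep(NA_real_, n)
    te_caused <- rep(FALSE, n)
    ps <- which(fate == "pseudogenized")
    trunc_frac[ps] <- runif(length(ps), params$truncation_range[1],
                            params$truncation_range[2])
    te_caused[ps] <- runif(length(ps)) < params$te_pseudo_frac

    # roster of TE copies across bursts
    ref <- if (length(params$te_bursts) > 0)
      is_family_reference(map_chr(params$te_bursts, "family_id")) else NULL
    roster <- list()
    ci <- 0
    for (bi in seq_along(params$te_bursts)) {
      b <- params$te_bursts[[bi]]
      trg <- b$trunc_range %||% c(0.4, 0.9)
      founder <- mutate_element_stopfree(ref$element_nt[bi],
                                         ref$ir_len[bi],
                                         b$founder_sub_rate %||% 0)
      for (j in seq_len(b$n_copies)) {
        ci <- ci + 1
        roster[[ci]] <- list(copy_id = sprintf("te_%03d", ci),
                             family_id = b$family_id,
                             element_nt = founder,
                             sub_rate = b$sub_rate,
                             trunc_prob = b$trunc_prob, trunc_range = trg)
      }
    }
    n_copies <- length(roster)
    if (n_copies > 0) roster <- roster[sample.int(n_copies)]
    interrupters <- which(te_caused)
    if (length(interrupters) > n_copies) {
      te_caused[interrupters[(n_copies + 1):length(interrupters)]] <- FALSE
      interrupters <- interrupters[seq_len(max(n_copies, 0))]
    }
    # first copies of the shuffled roster interrupt genes
    copy_of_gene <- setNames(seq_along(interrupters), interrupters)

    tsd <- params$tsd_len
    te_rows <- list()
    out_contigs <- character()
    out_features <- list()
    prot_spans <- list()

    emit_te <- function(copy) {
      dec <- decay_te_copy(copy$element_nt, copy$sub_rate, copy$trunc_prob,
                           copy$trunc_range)
      strand <- sample(c("+", "-"), 1)
      seq_fwd <- if (strand == "+") dec$seq else revcomp(dec$seq)
      list(seq = seq_fwd, strand = strand, dec = dec)
    }

    for (cid in names(ancestor$contigs)) {
      cseq <- ancestor$contigs[[cid]]
      cf_idx <- which(ft$contig_id == cid)
      cf <- ft[cf_idx, ]
      # segments: seq + optional feature payload
      segs <- list()
      add_seg <- function(seq, meta = NULL) {
        segs[[length(segs) + 1]] <<- list(seq = seq, meta = meta)
      }
      cursor <- 1L
      for (k in seq_len(nrow(cf))) {
        row <- cf[k, ]
        i <- cf_idx[k]
        if (row$start > cursor) {
          add_seg(substr(cseq, cursor, row$start - 1L))
        }
        block <- substr(cseq, row$start, row$end)
        if (fate[i] == "deleted") {
          # gene (and its sequence) removed
        } else if (fate[i] == "retained") {
          add_seg(block, meta = row)
        } else {
          orf <- if (row$strand == "+") block else revcomp(block)
          n_codons <- str_length(orf) %/% 3L
          keep_nt <- 3L * max(3L, floor(trunc_frac[i] * n_codons))
          trunc_orf <- substr(orf, 1L, keep_nt)
          rest_orf <- substr(orf, keep_nt + 1L, str_length(orf))
          gene_meta <- row
          gene_meta$status <- "pseudogene"
          sub <- list(list(seq = trunc_orf, meta = gene_meta))
          if (te_caused[i]) {
            copy <- roster[[copy_of_gene[[as.character(i)]]]]
            te <- emit_te(copy)
            te_meta <- tibble(
              feature_id = copy$copy_id, contig_id = cid,
              start = NA_integer_, end = NA_integer_, strand = te$strand,
              kind = "CDS", status = "pseudogene",
              product = paste(copy$family_id, "family transposase"),
              category_tags = list("mobile_element")
            )
            tsd_seq <- if (tsd > 0)
              substr(trunc_orf, keep_nt - tsd + 1L, keep_nt) else ""
            sub <- c(sub, list(list(seq = te$seq, meta = te_meta,
                                    te = list(copy = copy, dec = te$dec,
                                              interrupts = row$feature_id)),
                               list(seq = tsd_seq, meta = NULL)))
          }
          sub <- c(sub, list(list(seq = rest_orf, meta = NULL)))
          if (row$strand == "-") {
            sub <- rev(sub)
            for (m in seq_along(sub)) {
              if (nzchar(sub[[m]]$seq)) sub[[m]]$seq <- revcomp(sub[[m]]$seq)
              meta <- sub[[m]]$meta
              # the interrupted gene keeps its own (minus) strand; an
              # inserted TE's orientation flips with the host context
              if (!is.null(meta) && meta$feature_id != row$feature_id) {
                sub[[m]]$meta$strand <- if (meta$strand == "+") "-" else "+"
              }
            }
          }
          for (m in sub) if (nzchar(m$seq) || !is.null(m$meta)) {
            segs[[length(segs) + 1]] <- m
          }
        }
        cursor <- row$end + 1L
      }
      if (cursor <= str_length(cseq)) {
        add_seg(substr(cseq, cursor, str_length(cseq)))
      }

      # intergenic TE insertions: segments with no feature payload and not
      # inside the protected cluster span
      n_used <- length(interrupters)
      free_copies <- if (n_copies > n_used)
        roster[(n_used + 1):n_copies] else list()
      if (cid == names(ancestor$contigs)[1] && length(free_copies) > 0) {
        seg_is_free <- map_lgl(segs, ~ is.null(.x$meta))
        # protected span: between the first and last protected feature
        prot_here <- which(protected[cf_idx])
        seg_gene_ids <- map_chr(segs, ~ if (!is.null(.x$meta))
          .x$meta$feature_id else NA_character_)
        if (length(prot_here) > 0) {
          prot_ids <- cf$feature_id[prot_here]
          gidx <- which(seg_gene_ids %in% prot_ids)
          if (length(gidx) >= 2) {
            inside <- seq(min(gidx), max(gidx))
            seg_is_free[inside] <- FALSE
          }
        }
        free_idx <- which(seg_is_free & map_int(segs, ~ str_length(.x$seq)) >
                            2L * tsd + 2L)
        if (length(free_idx) == 0) {
          abort("insertion space exhausted: no unprotected intergenic room")
        }
        lens <- map_int(segs[free_idx], ~ str_length(.x$seq))
        host <- sample(length(free_idx), length(free_copies), replace = TRUE,
                       prob = lens)
        ins <- tibble(seg = free_idx[host],
                      off = map_int(host, ~ as.integer(
                        sample.int(lens[.x] - 2L * tsd, 1) + tsd)),
                      copy = seq_along(free_copies))
        new_segs <- list()
        for (sidx in seq_along(segs)) {
          here <- filter(ins, seg == sidx) %>% arrange(off)
          if (nrow(here) == 0) {
            new_segs[[length(new_segs) + 1]] <- segs[[sidx]]
            next
          }
          seqs0 <- segs[[sidx]]$seq
          cur <- 1L
          for (q in seq_len(nrow(here))) {
            copy <- free_copies[[here$copy[q]]]
            te <- emit_te(copy)
            left <- substr(seqs0, cur, here$off[q])
            tsd_seq <- if (tsd > 0)
              substr(seqs0, here$off[q] - tsd + 1L, here$off[q]) else ""
            new_segs[[length(new_segs) + 1]] <- list(seq = left, meta = NULL)
            te_meta <- tibble(
              feature_id = copy$copy_id, contig_id = cid,
              start = NA_integer_, end = NA_integer_, strand = te$strand,
              kind = "CDS", status = "pseudogene",
              product = paste(copy$family_id, "family transposase"),
              category_tags = list("mobile_element")
            )
            new_segs[[length(new_segs) + 1]] <-
              list(seq = te$seq, meta = te_meta,
                   te = list(copy = copy, dec = te$dec,
                             interrupts = NA_character_))
            new_segs[[length(new_segs) + 1]] <- list(seq = tsd_seq,
                                                     meta = NULL)
            cur <- here$off[q] + 1L
          }
          new_segs[[length(new_segs) + 1]] <-
            list(seq = substr(seqs0, cur, str_length(seqs0)), meta = NULL)
        }
        segs <- new_segs
      }

      # assemble coordinates
      seq_vec <- map_chr(segs, "seq")
      lens <- str_length(seq_vec)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      out_contigs[[cid]] <- paste(seq_vec, collapse = "")
      for (sidx in seq_along(segs)) {
        m <- segs[[sidx]]$meta
        if (is.null(m)) next
        m$start <- as.integer(starts[sidx])
        m$end <- as.integer(ends[sidx])
        m$contig_id <- cid
        out_features[[length(out_features) + 1]] <- m
        if (!is.null(segs[[sidx]]$te)) {
          tinfo <- segs[[sidx]]$te
          te_rows[[length(te_rows) + 1]] <- tibble(
            copy_id = m$feature_id, family_id = tinfo$copy$family_id,
            contig = cid, start = m$start, end = m$end,
            strand = m$strand, sub_rate = tinfo$copy$sub_rate,
            truncated = tinfo$dec$truncated,
            kept_frac = tinfo$dec$kept_frac,
            interrupts = tinfo$interrupts
          )
        }
      }
      # protected span in derived coordinates
      feats_now <- bind_rows(out_features)
      prot_ids <- ft$feature_id[protected & ft$contig_id == cid]
      pf <- filter(feats_now, feature_id %in% prot_ids, contig_id == cid)
      if (nrow(pf) > 0) {
        prot_spans[[length(prot_spans) + 1]] <- tibble(
          contig = cid, start = min(pf$start), end = max(pf$end))
      }
    }

    features <- bind_rows(out_features)
    genome <- lux_genome(paste0(ancestor$genome_id, "_derived"),
                         out_contigs, features, source = "degrade_genome")
    truth <- structure(list(
      fates = tibble(feature_id = ft$feature_id, fate = fate,
                     trunc_frac = trunc_frac, te_caused = te_caused),
      te_copies = if (length(te_rows)) bind_rows(te_rows) else
        tibble(copy_id = character(), family_id = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), sub_rate = double(),
               truncated = logical(), kept_frac = double(),
               interrupts = character()),
      protected = if (length(prot_spans)) bind_rows(prot_spans) else
        tibble(contig = character(), start = integer(), end = integer()),
      rate_multiplier = NA_real_,
      polymorphic_sites = NULL,
      seed = params$rng_seed
    ), class = "lux_truth")
    list(genome = genome, truth = truth)
  })
}

#' Simulate an alignment on a tree with a foreground rate multiplier
#'
#' Sites evolve i.i.d. under a reversible substitution model along a tree
#' whose branch lengths are expected substitutions per site at the
#' background rate; branches inside (and, by default, the stem of) the
#' foreground clade evolve `rate_multiplier` times faster. Deterministic
#' given `seed`.
#'
#' @param tree Rooted `ape::phylo` with non-negative branch lengths.
#' @param model A [substitution_model()] (reversible by construction).
#' @param n_sites Number of sites.
#' @param foreground Optional character vector of tip labels (monophyletic
#'   clade) to accelerate.
#' @param rate_multiplier Foreground rate multiplier r > 0.
#' @param include_stem Scale the clade's stem branch too (default TRUE).
#' @param seed RNG seed.
#' @return A [lux_alignment()] over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, n_sites, foreground = NULL,
                               rate_multiplier = 1, include_stem = TRUE,
                               seed = 1) {
  stopifnot(rate_multiplier > 0, n_sites >= 1)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("tree must have non-negative branch durations")
  }
  fg_idx <- if (is.null(foreground)) integer() else
    foreground_edges(tree, foreground, include_stem)
  with_seed(seed, {
    k <- length(model$states)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    pre <- ape::reorder.phylo(tree, "cladewise")
    len <- pre$edge.length
    orig_fg <- paste(tree$edge[, 1], tree$edge[, 2])[fg_idx]
    fg_pre <- paste(pre$edge[, 1], pre$edge[, 2]) %in% orig_fg
    len[fg_pre] <- len[fg_pre] * rate_multiplier
    ncat <- length(model$cat_rates)
    site_cat <- if (ncat > 1)
      sample.int(ncat, n_sites, replace = TRUE) else rep(1L, n_sites)
    nn <- ntip + tree$Nnode
    states <- matrix(0L, nn, n_sites)
    states[root, ] <- sample.int(k, n_sites, replace = TRUE, prob = model$pi)
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]
      ch <- pre$edge[e, 2]
      for (cc in unique(site_cat)) {
        P <- model_pmat(model, len[e] * model$cat_rates[cc])
        sel <- which(site_cat == cc)
        ps <- states[par, sel]
        for (a in unique(ps)) {
          w <- sel[ps == a]
          states[ch, w] <- sample.int(k, length(w), replace = TRUE,
                                      prob = P[a, ])
        }
      }
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(s) {
      paste(model$states[s], collapse = "")
    })
    lux_alignment(setNames(seqs, tree$tip.label),
                  alphabet = model$alphabet)
  })
}

#' Simulate a per-site pileup with an error floor and true polymorphisms
#'
#' Per-site depth is Poisson(`mean_depth`); each non-reference base draws
#' Binomial(depth, `error_rate`/3) error reads; sites listed in
#' `polymorphic_sites` additionally draw Binomial(depth, freq) reads of the
#' stated alternate base. Deterministic given `seed`.
#'
#' @param genome A [lux_genome()] or named character vector of contigs.
#' @param mean_depth Mean read depth.
#' @param error_rate Per-base sequencing error rate.
#' @param polymorphic_sites Optional tibble (contig, pos, alt, freq) with
#'   freq in (0,1); positions must lie inside the genome.
#' @param seed RNG seed.
#' @return A pileup tibble (see [read_pileup()]).
#' @export
simulate_pileup <- function(genome, mean_depth = 100, error_rate = 1e-3,
                            polymorphic_sites = NULL, seed = 1) {
  contigs <- if (inherits(genome, "lux_genome")) genome$contigs else genome
  stopifnot(error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    rows <- lapply(names(contigs), function(cid) {
      cseq <- strsplit(contigs[[cid]], "")[[1]]
      L <- length(cseq)
      depth <- rpois(L, mean_depth)
      bases <- c("A", "C", "G", "T")
      cnt <- matrix(0L, L, 4, dimnames = list(NULL, bases))
      err <- matrix(rbinom(3L * L, rep(depth, 3), error_rate / 3), L, 3)
      ref_idx <- match(cseq, bases)
      ok <- !is.na(ref_idx)
      # distribute the 3 error columns over the non-ref bases
      for (b in 1:4) {
        nonref <- which(ok)
        pos_in_row <- (b - ref_idx[nonref]) %% 4
        sel <- nonref[pos_in_row > 0]
        cnt[sel, b] <- err[cbind(sel, pos_in_row[pos_in_row > 0])]
      }
      if (!is.null(polymorphic_sites)) {
        here <- filter(as_tibble(polymorphic_sites), contig == cid)
        if (nrow(here) > 0) {
          if (any(here$pos < 1 | here$pos > L)) {
            abort("polymorphic site outside genome")
          }
          stopifnot(all(here$freq > 0 & here$freq < 1))
          add <- rbinom(nrow(here), depth[here$pos], here$freq)
          bi <- match(str_to_upper(here$alt), bases)
          cnt[cbind(here$pos, bi)] <- cnt[cbind(here$pos, bi)] + add
        }
      }
      alt_tot <- rowSums(cnt)
      over <- alt_tot > depth
      if (any(over)) {
        # clamp pathological draws so counts never exceed depth
        for (i in which(over)) {
          cnt[i, ] <- floor(cnt[i, ] * depth[i] / alt_tot[i])
        }
        alt_tot <- rowSums(cnt)
      }
      refc <- depth - alt_tot
      cnt[cbind(which(ok), ref_idx[ok])] <-
        cnt[cbind(which(ok), ref_idx[ok])] + refc[ok]
      # non-ACGT reference: park remaining depth on A so sums stay valid
      if (any(!ok)) cnt[!ok, "A"] <- cnt[!ok, "A"] + refc[!ok]
      tibble(contig = cid, pos = seq_len(L), ref = cseq,
             depth = depth, A = cnt[, 1], C = cnt[, 2], G = cnt[, 3],
             T = cnt[, 4])
    })
    bind_rows(rows)
  })
}
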