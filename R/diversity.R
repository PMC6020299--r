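# Intra-sample diversity from pileup base counts: the alternate-base
# frequency spectrum, error-like vs polymorphic site classification, and
# the per-kilobase polymorphism rate.

#' Per-site alternate-base frequencies
#'
#' For each pileup row with positive depth, computes the alternate-base
#' frequency `alt_freq = (depth - ref_count) / depth` (all non-reference
#' reads) and identifies the majority alternate base (ties broken in fixed
#' base order A < C < G < T). Zero-depth rows are skipped with a message.
#'
#' @param pileup Pileup tibble (see [read_pileup()]).
#' @return Tibble: contig, pos, ref, depth, alt_base, alt_count, alt_freq.
#' @export
site_frequencies <- function(pileup) {
  validate_pileup(pileup)
  zero <- pileup$depth == 0
  if (any(zero)) {
    inform(paste0("skipped ", sum(zero), " zero-depth site(s)"))
    pileup <- pileup[!zero, ]
  }
  if (nrow(pileup) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  depth = integer(), alt_base = character(),
                  alt_count = integer(), alt_freq = double()))
  }
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileup[, bases])
  ref_idx <- match(pileup$ref, bases)
  ref_count <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  ref_count[is.na(ref_idx)] <- 0L # non-ACGT reference: all reads alternate
  alt <- cnt
  alt[cbind(which(!is.na(ref_idx)), ref_idx[!is.na(ref_idx)])] <- -1L
  alt_idx <- max.col(alt, ties.method = "first")
  tibble(
    contig = pileup$contig,
    pos = pileup$pos,
    ref = pileup$ref,
    depth = pileup$depth,
    alt_base = bases[alt_idx],
    alt_count = alt[cbind(seq_len(nrow(alt)), alt_idx)],
    alt_freq = (pileup$depth - ref_count) / pileup$depth
  )
}

#' Classify sites as error-like, intermediate or polymorphic
#'
#' Sites with a nonzero alternate frequency are partitioned by two
#' thresholds: `alt_freq < f_err` is error-like (consistent with a
#' sequencing-error floor), `alt_freq > f_poly` is polymorphic (candidate
#' intra-sample variation), anything between is intermediate.
#'
#' @param sites Tibble from [site_frequencies()].
#' @param f_err Error-like threshold (default 0.0005, i.e. 0.05% of the
#'   per-site read depth).
#' @param f_poly Polymorphic threshold (default 0.01, i.e. 1%).
#' @return A list of class `lux_site_classes`: `sites` (with a `class`
#'   column; zero-alternate sites get `NA`), and `summary` with
#'   n_error_like, n_intermediate, n_polymorphic and `frac_error_like`
#'   (`NA` when no site has a nonzero alternate count).
#' @export
classify_sites <- function(sites, f_err = 0.0005, f_poly = 0.01) {
  stopifnot(f_err > 0, f_err < f_poly, f_poly < 1)
  cls <- rep(NA_character_, nrow(sites))
  nz <- sites$alt_freq > 0
  cls[nz & sites$alt_freq < f_err] <- "error_like"
  cls[nz & sites$alt_freq >= f_err & sites$alt_freq <= f_poly] <- "intermediate"
  cls[nz & sites$alt_freq > f_poly] <- "polymorphic"
  sites$class <- cls
  n_err <- sum(cls == "error_like", na.rm = TRUE)
  n_int <- sum(cls == "intermediate", na.rm = TRUE)
  n_poly <- sum(cls == "polymorphic", na.rm = TRUE)
  tot <- n_err + n_int + n_poly
  structure(list(
    sites = sites,
    f_err = f_err, f_poly = f_poly,
    summary = list(
      n_error_like = n_err,
      n_intermediate = n_int,
      n_polymorphic = n_poly,
      frac_error_like = if (tot > 0) n_err / tot else NA_real_
    )
  ), class = "lux_site_classes")
}

#' @export
print.lux_site_classes <- function(x, ...) {
  s <- x$summary
  cat("<lux_site_classes> error-like ", s$n_error_like,
      ", intermediate ", s$n_intermediate,
      ", polymorphic ", s$n_polymorphic,
      " (frac error-like ",
      ifelse(is.na(s$frac_error_like), "NA",
             format(round(s$frac_error_like, 4))), ")\n", sep = "")
  invisible(x)
}

#' Polymorphism rate per kilobase
#'
#' `1000 * n_polymorphic / genome_length_bp`, where polymorphic sites are
#' those with `alt_freq > f_poly`. The denominator is total genome length
#' (set `genome_length_bp` to a callable length for the callable-sites
#' variant).
#'
#' @param sites Tibble from [site_frequencies()].
#' @param genome_length_bp Genome length in bp (> 0).
#' @param f_poly Polymorphic threshold (default 0.01).
#' @return Polymorphisms per kilobase (double).
#' @export
polymorphism_rate <- function(sites, genome_length_bp, f_poly = 0.01) {
  stopifnot(genome_length_bp > 0)
  1000 * sum(sites$alt_freq > f_poly) / genome_length_bp
}

#' Alternate-base frequency spectrum
#'
#' Bins the alternate frequencies of sites with a nonzero alternate count.
#' Frequencies outside the bin range are clamped into the first/last bin
#' with a message.
#'
#' @param sites Tibble from [site_frequencies()].
#' @param bin_edges Strictly increasing bin edges; default 25 log-spaced
#'   bins over `[1e-4, 1]`.
#' @return A list of class `lux_spectrum`: `edges`, `counts` (length
#'   `length(edges) - 1`), `total` observations.
#' @export
alt_frequency_spectrum <- function(sites,
                                   bin_edges = 10^seq(-4, 0, length.out = 26)) {
  if (any(diff(bin_edges) <= 0)) abort("bin_edges must be strictly increasing")
  f <- sites$alt_freq[sites$alt_freq > 0]
  out_of_range <- sum(f < bin_edges[1] | f > bin_edges[length(bin_edges)])
  if (out_of_range > 0) {
    inform(paste0(out_of_range,
                  " frequencies outside bin range clamped to end bins"))
    f <- pmin(pmax(f, bin_edges[1]), bin_edges[length(bin_edges)])
  }
  idx <- findInterval(f, bin_edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(bin_edges) - 1L)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  structure(list(edges = bin_edges, counts = counts, total = length(f)),
            class = "lux_spectrum")
}

#' @export
print.lux_spectrum <- function(x, ...) {
  cat("<lux_spectrum> ", x$total, " alternate-base observations in ",
      length(x$counts), " bins over [",
      format(x$edges[1]), ", ", format(x$edges[length(x$edges)]), "]\n",
      sep = "")
  invisible(x)
}

#' Run the full intra-sample diversity analysis
#'
#' Convenience wrapper: site frequencies, classification, spectrum, and the
#' per-kilobase polymorphism rate in one report.
#'
#' @param pileup Pileup tibble.
#' @param genome_length_bp Total genome length in bp.
#' @param f_err,f_poly Classification thresholds.
#' @param bin_edges Spectrum bin edges.
#' @return A list of class `lux_diversity` with `sites`, `classes`,
#'   `spectrum`, and `rate_per_kb`.
#' @export
diversity_report <- function(pileup, genome_length_bp, f_err = 0.0005,
                             f_poly = 0.01,
                             bin_edges = 10^seq(-4, 0, length.out = 26)) {
  sites <- site_frequencies(pileup)
  classes <- classify_sites(sites, f_err = f_err, f_poly = f_poly)
  spec <- alt_frequency_spectrum(sites, bin_edges = bin_edges)
  structure(list(
    sites = sites,
    classes = classes,
    spectrum = spec,
    rate_per_kb = polymorphism_rate(sites, genome_length_bp, f_poly)
  ), class = "lux_diversity")
}
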