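# broom-style accessors for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_global_clock `tidy()` returns one row per branch with
#'   its duration, rate class and fitted length.
#' @param x A `lux_clock_fit`.
#' @param ... Unused.
#' @export
tidy.lux_clock_fit <- function(x, ...) {
  tr <- x$tree
  fg <- if (is.null(x$foreground)) integer() else
    foreground_edges(tr, x$foreground, isTRUE(x$include_stem))
  tibble(
    parent = tr$edge[, 1],
    child = tr$edge[, 2],
    label = ifelse(tr$edge[, 2] <= length(tr$tip.label),
                   tr$tip.label[tr$edge[, 2]], NA_character_),
    duration = x$times[tr$edge[, 1]] - x$times[tr$edge[, 2]],
    foreground = seq_len(nrow(tr$edge)) %in% fg,
    branch_length = tr$edge.length
  )
}

#' @describeIn fit_global_clock `glance()` returns a one-row model
#'   summary.
#' @export
glance.lux_clock_fit <- function(x, ...) {
  tibble(logL = x$logL, b = x$b, r = x$r,
         n_free_params = x$n_free_params, converged = x$converged)
}

#' @describeIn lrt `tidy()` returns the test as a one-row tibble.
#' @param x A `lux_lrt`.
#' @param ... Unused.
#' @export
tidy.lux_lrt <- function(x, ...) {
  as_tibble(unclass(x)[c("LR", "df", "p", "r", "lnL0", "lnLA")])
}

#' @describeIn call_pseudogenes `tidy()` returns the per-locus call table.
#' @param x A `lux_pseudogene_calls`.
#' @param ... Unused.
#' @export
tidy.lux_pseudogene_calls <- function(x, ...) {
  x$calls
}

#' @describeIn call_pseudogenes `glance()` returns the count summary.
#' @export
glance.lux_pseudogene_calls <- function(x, ...) {
  as_tibble(x$summary)
}

#' @describeIn te_census `tidy()` returns the per-copy record table.
#' @param x A `lux_te_census`.
#' @param ... Unused.
#' @export
tidy.lux_te_census <- function(x, ...) {
  x$records
}

#' @describeIn te_census `glance()` returns the census totals.
#' @export
glance.lux_te_census <- function(x, ...) {
  tibble(n_te = x$n_te, n_cds = x$n_cds, n_complete = x$n_complete,
         te_pct_of_cds = x$te_pct_of_cds)
}

#' @describeIn burst_test `tidy()` returns the report as a one-row tibble.
#' @param x A `lux_burst`.
#' @param ... Unused.
#' @export
tidy.lux_burst <- function(x, ...) {
  tibble(family_id = x$family_id, n_copies = x$n_copies,
         monophyletic = x$monophyletic, stem_length = x$stem_length,
         mean_crown_depth = x$mean_crown_depth,
         burst_ratio = x$burst_ratio, verdict = x$verdict)
}

#' @describeIn classify_sites `tidy()` returns the per-site table with
#'   classes.
#' @param x A `lux_site_classes`.
#' @param ... Unused.
#' @export
tidy.lux_site_classes <- function(x, ...) {
  x$sites
}

#' @describeIn classify_sites `glance()` returns the class counts.
#' @export
glance.lux_site_classes <- function(x, ...) {
  as_tibble(x$summary)
}

#' @describeIn alt_frequency_spectrum `tidy()` returns one row per bin.
#' @param x A `lux_spectrum`.
#' @param ... Unused.
#' @export
tidy.lux_spectrum <- function(x, ...) {
  k <- length(x$counts)
  tibble(bin_low = x$edges[seq_len(k)],
         bin_high = x$edges[seq_len(k) + 1L],
         mid = sqrt(x$edges[seq_len(k)] * x$edges[seq_len(k) + 1L]),
         count = x$counts)
}
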