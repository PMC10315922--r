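#' Between-sample normalization
#'
#' Removes systematic between-sample intensity biases (sample loading,
#' instrument drift) with one multiplicative factor per sample. Sample
#' traces (one log2 trace per sample over all ions) are aligned by
#' [capped_shift()]; the recovered additive log2 factors are re-centered
#' so their median is 0 (shifts are only defined up to a common constant;
#' this gauge keeps the overall intensity scale of the dataset), then
#' applied to the table: normalized intensity = intensity * 2^factor.
#' Relative ion intensities within each sample are untouched.
#'
#' The median pairwise shift assumes that the majority of ions are not
#' regulated between samples. When that fails for a known reason, pass
#' `subset`: traces are then built only from ions of those (for instance
#' housekeeping) proteins, while the factors are applied to the whole
#' table.
#'
#' @param t an [ion_table()].
#' @param nmax cap on traces entering full hierarchical merging
#'   (default 50).
#' @param subset optional character vector of protein ids to build the
#'   normalization traces from.
#' @param stat pairwise shift statistic; `"mode"` (kernel-density peak)
#'   is available for datasets where the unregulated majority assumption
#'   is doubtful, `"median"` is the default.
#' @return An object of class `"lfq_normalization"`: list with `table`
#'   (the normalized [ion_table()]), `log2_factors` (named per-sample
#'   additive log2 shifts) and `flags` (named logical; `TRUE` where a
#'   sample shared no ions with the anchors and kept factor 0).
#' @examples
#' t <- ion_table(data.frame(protein = "P1", ion = rep(c("a", "b"), 2),
#'                           sample = rep(c("s1", "s2"), each = 2),
#'                           intensity = c(8, 16, 32, 64)))
#' normalize_samples(t)$log2_factors
#' @export
normalize_samples <- function(t, nmax = 50, subset = NULL,
                              stat = c("median", "mode")) {
  stat <- match.arg(stat)
  stopifnot(inherits(t, "ion_table"))
  if (nrow(t) == 0L) stop("ion table is empty", call. = FALSE)

  basis <- t
  if (!is.null(subset)) {
    keep <- t$protein %in% subset
    if (!any(keep))
      stop("normalization subset matches no ions: ",
           paste(utils::head(subset, 5L), collapse = ", "),
           if (length(subset) > 5L) ", ..." else "", call. = FALSE)
    basis <- t[keep, , drop = FALSE]
    attr(basis, "samples") <- attr(t, "samples")
    attr(basis, "proteins") <- unique(basis$protein)
    attr(basis, "ions") <- unique(basis$ion)
    class(basis) <- class(t)
  }

  ts <- to_trace_set_by_sample(basis)
  sol <- capped_shift(ts, nmax, stat)

  factors <- sol$shifts - stats::median(sol$shifts)
  # samples present in t but absent from the subset basis: factor 0, flagged
  all_s <- attr(t, "samples")
  log2_factors <- stats::setNames(numeric(length(all_s)), all_s)
  flags <- stats::setNames(logical(length(all_s)), all_s)
  log2_factors[names(factors)] <- factors
  flags[names(sol$flagged)] <- sol$flagged
  flags[setdiff(all_s, names(factors))] <- TRUE
  if (any(flags))
    warning(sum(flags), " sample(s) could not be normalized (no ion overlap); ",
            "factor kept at 0", call. = FALSE)

  out <- t
  out$intensity <- t$intensity * 2^log2_factors[t$sample]
  structure(list(table = out, log2_factors = log2_factors, flags = flags),
            class = "lfq_normalization")
}

#' @export
print.lfq_normalization <- function(x, ...) {
  cat("Sample normalization over", length(x$log2_factors), "samples\n")
  cat("  log2 factor range: ",
      sprintf("[%.3g, %.3g]", min(x$log2_factors), max(x$log2_factors)), "\n")
  if (any(x$flags)) cat("  flagged samples:", sum(x$flags), "\n")
  invisible(x)
}

#' Plain per-sample median normalization
#'
#' Baseline comparator: each sample's log2 intensities are centered so
#' all per-sample medians of the *observed* records coincide (at the mean
#' of the raw sample medians). Unlike trace alignment, this statistic is
#' taken over whatever subset of ions happens to be observed in each
#' sample, so differing sample depth or asymmetric regulation bias it.
#'
#' @param t an [ion_table()].
#' @return An `"lfq_normalization"` object (same shape as
#'   [normalize_samples()]).
#' @export
median_normalize_samples <- function(t) {
  stopifnot(inherits(t, "ion_table"))
  med <- tapply(log2(t$intensity), factor(t$sample, levels = attr(t, "samples")),
                stats::median)
  factors <- mean(med) - med
  out <- t
  out$intensity <- t$intensity * 2^factors[t$sample]
  structure(list(table = out,
                 log2_factors = stats::setNames(as.numeric(factors), names(med)),
                 flags = stats::setNames(logical(length(med)), names(med))),
            class = "lfq_normalization")
}
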