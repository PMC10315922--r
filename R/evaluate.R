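# Benchmark statistics for spike-in designs and replicate consistency.

# pull the protein-by-sample linear intensity matrix out of whatever the
# caller passes (fit object, quantification result, or plain matrix)
.intensity_matrix <- function(result) {
  if (inherits(result, c("tracelfq_fit", "protein_quant")))
    return(result$intensities)
  if (is.matrix(result)) return(result)
  stop("expected a tracelfq fit, a protein_quant result, or a matrix",
       call. = FALSE)
}

#' Per-protein log2 fold change between two sample groups
#'
#' For every protein, the median log2 intensity over group A minus the
#' median log2 intensity over group B. Proteins missing in all samples
#' of a group get a missing fold change.
#'
#' @param result a [tracelfq()] fit, [quantify_all_proteins()] result, or
#'   a protein-by-sample linear intensity matrix.
#' @param group_a,group_b disjoint, non-empty character vectors of sample
#'   ids (columns).
#' @return Named numeric vector of log2 fold changes (A minus B).
#' @export
log2fc_per_protein <- function(result, group_a, group_b) {
  m <- log2(.intensity_matrix(result))
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  miss <- setdiff(c(group_a, group_b), colnames(m))
  if (length(miss))
    stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
  med <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  apply(m[, group_a, drop = FALSE], 1L, med) -
    apply(m[, group_b, drop = FALSE], 1L, med)
}

#' Per-protein coefficient of variation
#'
#' Replicate-consistency metric: standard deviation divided by mean of
#' the linear intensities over the given samples. Proteins with fewer
#' than two non-missing values get a missing CV.
#'
#' @inheritParams log2fc_per_protein
#' @param samples sample ids to compute the CV over (default: all).
#' @return Named numeric vector of CVs.
#' @export
cv_per_protein <- function(result, samples = NULL) {
  m <- .intensity_matrix(result)
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(m))
    if (length(miss))
      stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
    m <- m[, samples, drop = FALSE]
  }
  apply(m, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x) / mean(x)
  })
}

#' Summarize fold changes by species
#'
#' Groups per-protein log2 fold changes by a protein-to-species map and
#' reports the median and standard deviation per species, the summary
#' used to judge spike-in ratio recovery.
#'
#' @param fc named per-protein log2 fold changes
#'   (from [log2fc_per_protein()]).
#' @param species named character vector mapping protein ids to species.
#' @return Data frame with columns `species`, `median_log2fc`, `sd`, `n`.
#' @export
benchmark_summary <- function(fc, species) {
  sp <- species[names(fc)]
  out <- do.call(rbind, lapply(split(fc, sp), function(x) {
    data.frame(median_log2fc = stats::median(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE),
               n = sum(!is.na(x)))
  }))
  data.frame(species = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-sample median log2 ratio to a reference sample
#'
#' For each sample, the median over shared ions of the log2 intensity
#' ratio to a reference sample. After successful normalization these
#' medians should sit near 0 when the majority of ions are unregulated;
#' systematic deviations reveal residual between-sample bias.
#'
#' @param t an [ion_table()] (typically a normalized one).
#' @param reference reference sample id.
#' @param complete_only evaluate only ions observed in every sample
#'   (default `FALSE`). Complete ions are unaffected by intensity-dependent
#'   censoring, so their ratios reflect true abundance changes more
#'   directly; the usual convention when judging normalization quality.
#' @return Named numeric vector, one median log2 ratio per sample
#'   (0 for the reference itself; `NA` if a sample shares no ions with
#'   the reference).
#' @export
sample_median_ratios <- function(t, reference, complete_only = FALSE) {
  stopifnot(inherits(t, "ion_table"))
  smp <- attr(t, "samples")
  if (!reference %in% smp)
    stop("unknown reference sample: ", reference, call. = FALSE)
  if (complete_only) {
    n_obs <- table(t$ion)
    keep <- t$ion %in% names(n_obs)[n_obs == length(smp)]
    if (!any(keep))
      stop("no ions observed in every sample", call. = FALSE)
    t <- ion_table(t[keep, , drop = FALSE])
    attr(t, "samples") <- smp
  }
  ref <- t[t$sample == reference, c("ion", "intensity")]
  ref_l <- stats::setNames(log2(ref$intensity), ref$ion)
  vapply(smp, function(s) {
    sub <- t[t$sample == s, c("ion", "intensity")]
    d <- log2(sub$intensity) - ref_l[sub$ion]
    d <- d[!is.na(d)]
    if (length(d)) stats::median(d) else NA_real_
  }, numeric(1))
}
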