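#' Fit label-free protein quantities by intensity-trace alignment
#'
#' The main entry point: takes an ion intensity table, performs
#' between-sample normalization ([normalize_samples()]) followed by
#' per-protein intensity estimation ([quantify_all_proteins()]), and
#' returns a fitted object carrying protein intensities, the aligned ion
#' traces and the normalization factors.
#'
#' Both stages shift log2 intensity traces on top of each other by one
#' additive factor per trace; trace shapes (the relative changes that
#' carry the biology) are never altered. The whole procedure is
#' deterministic and scales linearly in the number of samples.
#'
#' @param x an [ion_table()] or a data frame with columns `protein`,
#'   `ion`, `sample`, `intensity`.
#' @param nmax_samples cap for the sample-normalization pairwise stage
#'   (default 50).
#' @param nmax_ions cap for the per-protein ion-alignment stage
#'   (default 10).
#' @param min_ions minimum number of ions for a protein to be quantified
#'   (default 1).
#' @param normalize if `FALSE`, skip between-sample normalization.
#' @param subset_proteins optional housekeeping protein ids to restrict
#'   normalization to (see [normalize_samples()]).
#' @param stat pairwise shift statistic (`"median"` or `"mode"`).
#' @return An object of class `"tracelfq_fit"` with components
#'   `intensities` (protein-by-sample linear intensity matrix),
#'   `aligned_ions`, `n_ions`, `dropped`, `normalization`
#'   (`NULL` when skipped), `params` and `call`. Methods: `print`,
#'   `summary`, `coef` (the intensity matrix), `fitted` (log2
#'   intensities), `residuals` (aligned ion log2 minus the protein log2
#'   profile) and `plot` (aligned ion traces of one protein).
#' @examples
#' sim <- simulate_lfq(sim_config(n_proteins = c(A = 5), seed = 1))
#' fit <- tracelfq(sim$table)
#' coef(fit)[1:3, ]
#' @export
tracelfq <- function(x, nmax_samples = 50, nmax_ions = 10, min_ions = 1,
                     normalize = TRUE, subset_proteins = NULL,
                     stat = c("median", "mode")) {
  stat <- match.arg(stat)
  cl <- match.call()
  t <- if (inherits(x, "ion_table")) x else ion_table(x)

  norm <- NULL
  if (normalize) {
    norm <- normalize_samples(t, nmax = nmax_samples,
                              subset = subset_proteins, stat = stat)
    t <- norm$table
  }
  pq <- quantify_all_proteins(t, nmax = nmax_ions, min_ions = min_ions)

  structure(list(intensities = pq$intensities,
                 aligned_ions = pq$aligned_ions,
                 n_ions = pq$n_ions,
                 dropped = pq$dropped,
                 normalization = norm,
                 params = list(nmax_samples = nmax_samples,
                               nmax_ions = nmax_ions,
                               min_ions = min_ions,
                               normalize = normalize,
                               stat = stat),
                 call = cl),
            class = "tracelfq_fit")
}

#' @export
print.tracelfq_fit <- function(x, ...) {
  cat("Label-free quantification by intensity-trace alignment\n")
  cat("  proteins:", nrow(x$intensities),
      " samples:", ncol(x$intensities), "\n")
  cat("  normalization:",
      if (is.null(x$normalization)) "skipped"
      else sprintf("median-centered, factor range [%.3g, %.3g]",
                   min(x$normalization$log2_factors),
                   max(x$normalization$log2_factors)), "\n")
  cat("  nmax (samples/ions):", x$params$nmax_samples, "/",
      x$params$nmax_ions, "\n")
  invisible(x)
}

#' @export
summary.tracelfq_fit <- function(object, ...) {
  li <- log2(object$intensities)
  out <- list(n_proteins = nrow(object$intensities),
              n_samples = ncol(object$intensities),
              n_dropped = length(object$dropped),
              ion_counts = summary(as.numeric(object$n_ions)),
              log2_intensity = summary(as.numeric(li[is.finite(li)])),
              completeness = mean(!is.na(object$intensities)),
              log2_factors = if (is.null(object$normalization)) NULL
                             else object$normalization$log2_factors)
  class(out) <- "summary.tracelfq_fit"
  out
}

#' @export
print.summary.tracelfq_fit <- function(x, ...) {
  cat("Protein quantification summary\n")
  cat(sprintf("  %d proteins x %d samples (%.1f%% complete), %d dropped\n",
              x$n_proteins, x$n_samples, 100 * x$completeness, x$n_dropped))
  cat("  ions per protein:\n"); print(x$ion_counts)
  cat("  log2 protein intensity:\n"); print(x$log2_intensity)
  if (!is.null(x$log2_factors)) {
    cat("  per-sample log2 normalization factors:\n")
    print(round(x$log2_factors, 4))
  }
  invisible(x)
}

#' @export
coef.tracelfq_fit <- function(object, ...) object$intensities

#' @export
fitted.tracelfq_fit <- function(object, ...) log2(object$intensities)

#' Residual ion deviations from the protein profile
#'
#' For every aligned ion observation, the difference between its shifted
#' log2 intensity and the protein's log2 intensity profile at that sample
#' (up to the constant conservation rescaling, which cancels in shape).
#'
#' @param object a [tracelfq()] fit.
#' @param ... unused.
#' @return The `aligned_ions` data frame with an extra `residual` column.
#' @export
residuals.tracelfq_fit <- function(object, ...) {
  ai <- object$aligned_ions
  li <- log2(object$intensities)
  # compare shapes: center both ion trace and protein profile per protein
  prof <- li[cbind(match(ai$protein, rownames(li)),
                   match(ai$sample, colnames(li)))]
  centers <- tapply(ai$aligned_log2_intensity - prof, ai$protein,
                    stats::median, na.rm = TRUE)
  ai$residual <- ai$aligned_log2_intensity - prof - centers[ai$protein]
  ai
}

#' Plot aligned ion traces for one protein
#'
#' Shows the shifted log2 ion traces over samples together with the
#' median protein profile, the direct visual account of how the protein
#' intensity estimate arises from its ion evidence.
#'
#' @param x a [tracelfq()] fit.
#' @param protein protein id to plot (default: the first).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tracelfq_fit <- function(x, protein = rownames(x$intensities)[1L], ...) {
  ai <- x$aligned_ions[x$aligned_ions$protein == protein, , drop = FALSE]
  if (!nrow(ai)) stop("no aligned ions for protein ", protein, call. = FALSE)
  smp <- colnames(x$intensities)
  ions <- unique(ai$ion)
  m <- matrix(NA_real_, length(smp), length(ions),
              dimnames = list(smp, ions))
  m[cbind(match(ai$sample, smp), match(ai$ion, ions))] <-
    ai$aligned_log2_intensity
  graphics::matplot(m, type = "b", lty = 1, pch = 16,
                    col = grDevices::adjustcolor(seq_len(ncol(m)), 0.6),
                    xlab = "sample", ylab = "aligned log2 intensity",
                    main = protein, xaxt = "n", ...)
  graphics::axis(1, at = seq_along(smp), labels = smp, las = 2, cex.axis = 0.7)
  prof <- apply(m, 1L, stats::median, na.rm = TRUE)
  graphics::lines(seq_along(smp), prof, lwd = 3)
  invisible(x)
}
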