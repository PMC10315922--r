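#' Estimate a protein's relative log2 profile
#'
#' Aligns the protein's ion traces on top of each other with
#' [capped_shift()] (removing constant ionization-efficiency offsets
#' between ions of the same protein) and takes the per-sample median of
#' the aligned log2 values as the relative protein profile. Samples with
#' no ion evidence are missing.
#'
#' @param ts a [trace_set()] of ion traces over the sample axis.
#' @param nmax cap on ion traces entering full hierarchical merging
#'   (default 10).
#' @return Numeric log2 profile over samples (named), with attributes
#'   `aligned` (the shifted ion trace matrix) and `shifts` (per-ion log2
#'   factors).
#' @export
estimate_relative_profile <- function(ts, nmax = 10) {
  stopifnot(inherits(ts, "trace_set"))
  if (nrow(ts$values) == 0L) stop("no ion traces", call. = FALSE)
  sol <- capped_shift(ts, nmax)
  aligned <- ts$values + sol$shifts
  profile <- apply(aligned, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col)) stats::median(col) else NA_real_
  })
  names(profile) <- ts$features
  attr(profile, "aligned") <- aligned
  attr(profile, "shifts") <- sol$shifts
  profile
}

#' Rescale a relative profile to linear protein intensities
#'
#' Back-transforms the log2 profile and multiplies it by a single factor
#' representing overall protein abundance: the sum of all linear ion
#' intensities over all samples for the protein, divided by the sum of
#' the back-transformed profile over all samples. The protein thereby
#' conserves its total ion signal exactly.
#'
#' @param profile numeric log2 profile over samples (missing allowed).
#' @param total_ion_intensity total linear ion intensity of the protein
#'   (sum over all its ions and samples), or an [ion_table()] restricted
#'   to the protein, from which the total is taken.
#' @return Numeric vector of linear protein intensities per sample
#'   (missing where the profile is missing).
#' @export
rescale_to_linear <- function(profile, total_ion_intensity) {
  if (inherits(total_ion_intensity, "ion_table"))
    total_ion_intensity <- sum(total_ion_intensity$intensity)
  p_lin <- 2^profile
  attributes(p_lin) <- list(names = names(profile))
  if (all(is.na(p_lin))) return(p_lin)
  factor <- total_ion_intensity / sum(p_lin, na.rm = TRUE)
  factor * p_lin
}

#' Quantify all proteins in an ion table
#'
#' Applies [estimate_relative_profile()] and [rescale_to_linear()] to
#' every protein group independently. The aligned (shifted) log2 ion
#' traces are retained so that each protein intensity estimate can be
#' retraced to the ion evidence behind it.
#'
#' @param t an [ion_table()], normally already normalized with
#'   [normalize_samples()].
#' @param nmax cap on ion traces per protein entering hierarchical
#'   merging (default 10).
#' @param min_ions proteins with fewer ions are dropped (default 1,
#'   i.e. keep everything).
#' @return An object of class `"protein_quant"`: list with
#'   \describe{
#'     \item{intensities}{protein-by-sample matrix of linear intensities,
#'       `NA` where a protein has no ion evidence in a sample;}
#'     \item{aligned_ions}{data frame `protein, ion, sample,
#'       aligned_log2_intensity` of the shifted ion traces;}
#'     \item{n_ions}{named ion count per quantified protein;}
#'     \item{dropped}{protein ids removed by the `min_ions` filter.}
#'   }
#' @export
quantify_all_proteins <- function(t, nmax = 10, min_ions = 1) {
  stopifnot(inherits(t, "ion_table"))
  sets <- to_trace_sets_by_protein(t)
  n_ions_all <- vapply(sets, function(s) nrow(s$values), integer(1))
  dropped <- names(sets)[n_ions_all < min_ions]
  if (length(dropped))
    message(length(dropped), " protein(s) dropped by min_ions = ", min_ions)
  sets <- sets[n_ions_all >= min_ions]
  if (!length(sets)) stop("no proteins left to quantify", call. = FALSE)

  smp <- attr(t, "samples")
  kept <- t$protein %in% names(sets)
  totals <- rowsum(t$intensity[kept],
                   factor(t$protein[kept], levels = names(sets)))

  intens <- matrix(NA_real_, length(sets), length(smp),
                   dimnames = list(names(sets), smp))
  aligned_list <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    prof <- estimate_relative_profile(sets[[i]], nmax = nmax)
    intens[i, ] <- rescale_to_linear(prof, totals[names(sets)[i], 1L])
    al <- attr(prof, "aligned")
    keep <- !is.na(al)
    aligned_list[[i]] <- data.frame(
      protein = names(sets)[i],
      ion = rep(rownames(al), times = ncol(al))[keep],
      sample = rep(colnames(al), each = nrow(al))[keep],
      aligned_log2_intensity = al[keep],
      stringsAsFactors = FALSE)
  }

  structure(list(intensities = intens,
                 aligned_ions = do.call(rbind, aligned_list),
                 n_ions = stats::setNames(vapply(sets, function(s)
                   nrow(s$values), integer(1)), names(sets)),
                 dropped = dropped),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("Protein quantification:", nrow(x$intensities), "protein groups x",
      ncol(x$intensities), "samples\n")
  if (length(x$dropped))
    cat("  dropped by min_ions filter:", length(x$dropped), "\n")
  invisible(x)
}
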