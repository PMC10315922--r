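#' Canonical ion intensity table
#'
#' Long-format store of quantified ions: one record per (protein group,
#' ion, sample) with a positive linear intensity. Absence of a record
#' means the ion was not quantified in that sample. All readers parse
#' into this container and all pipeline stages consume it.
#'
#' At construction, records with missing, zero or negative intensity are
#' dropped (log2 is undefined for them; they are treated as missing),
#' ions assigned to more than one protein group are removed with a
#' warning (protein grouping is deferred entirely to the upstream search
#' engine), and duplicate (ion, sample) records are summed in linear
#' space, matching total-signal semantics.
#'
#' @param x data frame with columns `protein`, `ion`, `sample`,
#'   `intensity` (or vectors via the individual arguments).
#' @param protein,ion,sample,intensity vectors used when `x` is missing.
#' @return An object of class `"ion_table"`: a data frame with the four
#'   canonical columns and attributes `samples`, `proteins`, `ions`
#'   holding first-appearance orderings.
#' @examples
#' t <- ion_table(data.frame(protein = "P1", ion = c("a", "a", "b"),
#'                           sample = c("s1", "s2", "s1"),
#'                           intensity = c(8, 16, 32)))
#' @export
ion_table <- function(x = NULL, protein = NULL, ion = NULL, sample = NULL,
                      intensity = NULL) {
  if (is.null(x)) {
    x <- data.frame(protein = protein, ion = ion, sample = sample,
                    intensity = intensity, stringsAsFactors = FALSE)
  }
  req <- c("protein", "ion", "sample", "intensity")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("ion table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(protein = as.character(x$protein),
                   ion = as.character(x$ion),
                   sample = as.character(x$sample),
                   intensity = as.numeric(x$intensity),
                   stringsAsFactors = FALSE)

  bad <- !is.finite(df$intensity) | df$intensity <= 0
  if (any(bad)) df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("ion table has no positive-intensity records", call. = FALSE)

  # an ion must map to exactly one protein group
  map <- unique(df[c("ion", "protein")])
  multi <- unique(map$ion[duplicated(map$ion)])
  if (length(multi)) {
    warning(length(multi), " ion(s) mapped to multiple protein groups; dropped",
            call. = FALSE)
    df <- df[!(df$ion %in% multi), , drop = FALSE]
    if (nrow(df) == 0L)
      stop("no ions left after removing multi-group ions", call. = FALSE)
  }

  # duplicate (ion, sample) records: sum linear intensities
  key <- paste(df$ion, df$sample, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    summed <- rowsum(df$intensity, key, reorder = FALSE)
    df_first <- df[first, , drop = FALSE]
    df_first$intensity <- as.numeric(summed[match(key[first], rownames(summed)), 1L])
    df <- df_first
  }

  rownames(df) <- NULL
  structure(df,
            samples = unique(df$sample),
            proteins = unique(df$protein),
            ions = unique(df$ion),
            class = c("ion_table", "data.frame"))
}

#' @export
print.ion_table <- function(x, ...) {
  cat("Ion table:", nrow(x), "records |",
      length(attr(x, "proteins")), "protein groups |",
      length(attr(x, "ions")), "ions |",
      length(attr(x, "samples")), "samples\n")
  invisible(x)
}

#' @rdname ion_table
#' @param t an `ion_table`.
#' @export
samples <- function(t) attr(t, "samples")

#' @rdname ion_table
#' @export
proteins <- function(t) attr(t, "proteins")

#' Pivot an ion table into sample traces
#'
#' One trace per sample over the union of all ions: the orientation used
#' for between-sample normalization. Values are log2 intensities; a
#' missing record becomes a missing entry.
#'
#' @param t an [ion_table()].
#' @return A [trace_set()] with samples as traces and ions as features.
#' @export
to_trace_set_by_sample <- function(t) {
  stopifnot(inherits(t, "ion_table"))
  if (nrow(t) == 0L) stop("ion table is empty", call. = FALSE)
  smp <- attr(t, "samples"); ions <- attr(t, "ions")
  m <- matrix(NA_real_, length(smp), length(ions),
              dimnames = list(smp, ions))
  m[cbind(match(t$sample, smp), match(t$ion, ions))] <- log2(t$intensity)
  trace_set(m, features = ions, trace_ids = smp)
}

#' Pivot an ion table into per-protein ion traces
#'
#' For each protein group, one trace per ion over the shared ordered
#' sample axis of the whole table (all samples, not only those where the
#' protein was observed): the orientation used for protein intensity
#' estimation.
#'
#' @param t an [ion_table()].
#' @return Named list of [trace_set()] objects, one per protein group, in
#'   first-appearance protein order; ions are traces, samples features.
#' @export
to_trace_sets_by_protein <- function(t) {
  stopifnot(inherits(t, "ion_table"))
  smp <- attr(t, "samples")
  out <- lapply(split(seq_len(nrow(t)), factor(t$protein, levels = attr(t, "proteins"))),
                function(idx) {
    sub <- t[idx, , drop = FALSE]
    ions <- unique(sub$ion)
    m <- matrix(NA_real_, length(ions), length(smp),
                dimnames = list(ions, smp))
    m[cbind(match(sub$ion, ions), match(sub$sample, smp))] <- log2(sub$intensity)
    trace_set(m, features = smp, trace_ids = ions)
  })
  out
}

#' Hierarchical ion identifiers
#'
#' Ion identifiers are ordered components (modified sequence, charge,
#' optional fragment or isotope tag) rendered as one `|`-delimited string,
#' so that the rendering round-trips losslessly.
#'
#' @param ... character components, in hierarchical order.
#' @return `ion_id()` a single delimited string; `parse_ion_id()` the
#'   character vector of components.
#' @examples
#' parse_ion_id(ion_id("PEPTIDE", "z2", "frag1"))
#' @export
ion_id <- function(...) paste(c(...), collapse = "|")

#' @rdname ion_id
#' @param id a rendered ion identifier.
#' @export
parse_ion_id <- function(id) strsplit(id, "|", fixed = TRUE)[[1L]]
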