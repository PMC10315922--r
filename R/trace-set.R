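#' Intensity traces and trace sets
#'
#' An intensity trace is a vector of log2 intensities over a shared feature
#' axis (ions when traces are samples, samples when traces are ions), with
#' `NA` marking missing values. A trace set bundles traces that share one
#' feature axis; it is the unit the shifting engine operates on.
#'
#' @param values numeric vector of log2 intensities; `NA` = missing. Every
#'   non-missing entry must be finite.
#' @param trace_id identifier, coerced to character.
#' @param n_members number of original traces averaged into this trace
#'   (1 for a raw measured trace).
#' @return `intensity_trace()` returns an object of class `"intensity_trace"`.
#' @examples
#' tr <- intensity_trace(c(23, 25, NA), "sample1")
#' @export
intensity_trace <- function(values, trace_id = "trace", n_members = 1L) {
  values <- as.numeric(values)
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-missing trace values must be finite", call. = FALSE)
  n_members <- as.integer(n_members)
  if (length(n_members) != 1L || is.na(n_members) || n_members < 1L)
    stop("n_members must be a single integer >= 1", call. = FALSE)
  structure(list(trace_id = as.character(trace_id),
                 values = values,
                 n_members = n_members),
            class = "intensity_trace")
}

#' @param x numeric matrix, one row per trace, one column per feature;
#'   `NA` = missing. Row names become trace ids, column names feature ids.
#' @param features optional character vector of feature identifiers.
#' @param trace_ids optional character vector of unique trace identifiers.
#' @param n_members integer vector of member counts, recycled to the number
#'   of traces.
#' @return `trace_set()` returns an object of class `"trace_set"`: a list
#'   with elements `values` (trace-by-feature matrix), `features`,
#'   `trace_ids` and `n_members`.
#' @rdname intensity_trace
#' @export
trace_set <- function(x, features = NULL, trace_ids = NULL, n_members = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.na(x) & !is.finite(x)))
    stop("non-missing trace values must be finite", call. = FALSE)
  if (is.null(trace_ids)) trace_ids <- rownames(x)
  if (is.null(trace_ids))
    trace_ids <- paste0("trace", seq_len(nrow(x)), recycle0 = TRUE)
  trace_ids <- as.character(trace_ids)
  if (anyDuplicated(trace_ids))
    stop("trace ids must be unique", call. = FALSE)
  if (length(trace_ids) != nrow(x))
    stop("trace_ids length must match the number of traces", call. = FALSE)
  if (is.null(features)) features <- colnames(x)
  if (is.null(features))
    features <- paste0("f", seq_len(ncol(x)), recycle0 = TRUE)
  if (length(features) != ncol(x))
    stop("features length must match the number of columns", call. = FALSE)
  n_members <- rep_len(as.integer(n_members), nrow(x))
  if (any(is.na(n_members) | n_members < 1L))
    stop("n_members must all be >= 1", call. = FALSE)
  dimnames(x) <- list(trace_ids, features)
  structure(list(values = x,
                 features = as.character(features),
                 trace_ids = trace_ids,
                 n_members = n_members),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("Trace set:", nrow(x$values), "traces over", ncol(x$values),
      "features;", sum(is.na(x$values)), "missing entries\n")
  invisible(x)
}

#' @export
length.trace_set <- function(x) nrow(x$values)

# subset a trace set by trace index, keeping the feature axis
subset_traces <- function(ts, idx) {
  trace_set(ts$values[idx, , drop = FALSE],
            features = ts$features,
            trace_ids = ts$trace_ids[idx],
            n_members = ts$n_members[idx])
}

as_trace <- function(x) {
  if (inherits(x, "intensity_trace")) return(x)
  intensity_trace(x)
}
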