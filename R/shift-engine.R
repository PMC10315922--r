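# Hierarchical pairwise shifting of intensity traces.
#
# The engine compares traces by subtracting their log2 vectors on the
# features where both are observed. The median of that difference
# distribution estimates the systematic shift between the traces; its
# variance measures how divergent their shapes are. The most similar pair
# (minimum variance) is aligned and replaced by a membership-weighted
# average trace, the affected half-matrix entries are recomputed, and the
# procedure repeats until one trace remains.

# difference-distribution statistics on two numeric log2 vectors.
# stat = "median" (default) or "mode" (kernel-density peak; falls back to
# the median when fewer than 3 overlapping features are available).
.pair_stats <- function(av, bv, stat = "median") {
  d <- av - bv
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0L)
    return(list(median_shift = NA_real_, variance = NA_real_, n_overlap = 0L))
  shift <- if (stat == "mode" && n >= 3L && diff(range(d)) > 1e-8) {
    dens <- stats::density(d)
    dens$x[which.max(dens$y)]
  } else {
    stats::median(d)
  }
  v <- if (n >= 2L) stats::var(d) else Inf
  list(median_shift = shift, variance = v, n_overlap = n)
}

#' Compare two intensity traces
#'
#' Computes the median and the sample variance (denominator n - 1) of the
#' element-wise difference `a - b` over the features where both traces are
#' observed. The median estimates the systematic log2 shift between the
#' traces; the variance their overall divergence. A pair with no common
#' feature is incomparable: `median_shift` and `variance` are `NA` and
#' `n_overlap` is 0. A single-feature overlap defines the median but gets
#' variance `Inf`, so such pairs are merged last.
#'
#' @param a,b numeric log2 vectors of equal length (or
#'   [intensity_trace()] objects); `NA` marks missing values.
#' @param stat shift statistic: `"median"` (default) or `"mode"`
#'   (kernel-density peak of the difference distribution).
#' @return A list of class `"pair_stats"` with elements `median_shift`,
#'   `variance` and `n_overlap`.
#' @examples
#' pairwise_stats(c(23, 25, NA), c(22, 24, 26)) # shift 1, variance 0
#' @export
pairwise_stats <- function(a, b, stat = c("median", "mode")) {
  stat <- match.arg(stat)
  a <- as_trace(a); b <- as_trace(b)
  if (length(a$values) != length(b$values))
    stop("traces must share the feature axis", call. = FALSE)
  structure(.pair_stats(a$values, b$values, stat), class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  if (x$n_overlap == 0L) {
    cat("Pair stats: incomparable (no overlapping features)\n")
  } else {
    cat(sprintf("Pair stats: median shift %.4g, variance %.4g, overlap %d\n",
                x$median_shift, x$variance, x$n_overlap))
  }
  invisible(x)
}

# membership-weighted element-wise mean of two aligned value vectors;
# a slot missing in one contributor is filled from the other.
.merge_values <- function(va, vb, wa, wb) {
  out <- (wa * va + wb * vb) / (wa + wb)
  only_a <- is.na(vb) & !is.na(va)
  only_b <- is.na(va) & !is.na(vb)
  out[only_a] <- va[only_a]
  out[only_b] <- vb[only_b]
  out
}

#' Merge two traces into an averaged trace
#'
#' Shifts `b` onto `a` by adding `stats$median_shift` and combines the pair
#' into a more stable averaged trace: where both are observed, the
#' membership-weighted mean; where exactly one is observed, that value;
#' where neither, missing. The member count of the result is the sum of
#' the contributors' counts.
#'
#' @inheritParams pairwise_stats
#' @param stats a [pairwise_stats()] result for `(a, b)`; must be
#'   comparable (`n_overlap >= 1`).
#' @return An [intensity_trace()].
#' @examples
#' a <- intensity_trace(c(23, 25, NA)); b <- intensity_trace(c(22, 24, 26))
#' merge_pair(a, b, pairwise_stats(a, b)) # values 23 25 27
#' @export
merge_pair <- function(a, b, stats) {
  a <- as_trace(a); b <- as_trace(b)
  if (is.null(stats$n_overlap) || stats$n_overlap < 1L)
    stop("cannot merge an incomparable pair (no overlapping features)",
         call. = FALSE)
  vb <- b$values + stats$median_shift
  intensity_trace(.merge_values(a$values, vb, a$n_members, b$n_members),
                  trace_id = paste0("avg(", a$trace_id, ",", b$trace_id, ")"),
                  n_members = a$n_members + b$n_members)
}

# scan the alive upper triangle for the comparable pair with minimum
# variance; ties broken by lowest (row, column). Returns NULL if none.
.min_var_pair <- function(var_mat, alive) {
  idx <- which(alive)
  best <- NULL; best_v <- Inf; found <- FALSE
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    if (ii == length(idx)) break
    for (j in idx[(ii + 1L):length(idx)]) {
      v <- var_mat[i, j]
      if (is.na(v)) next
      if (!found || v < best_v) { best <- c(i, j); best_v <- v; found <- TRUE }
    }
  }
  best
}

#' Hierarchically align a set of intensity traces
#'
#' Collects the variance and median half-matrices over all trace pairs,
#' repeatedly merges the most similar comparable pair (minimum variance of
#' the difference distribution, ties broken by lowest index pair), shifting
#' the second member onto the first by the pairwise median and replacing
#' the pair with a membership-weighted average trace. Only the matrix
#' entries involving the merged trace are recomputed. Applied shifts are
#' propagated to every original trace underlying an averaged trace.
#'
#' Traces in connected components never merged into the main (largest)
#' component keep shift 0 and are flagged; when no merge is possible at
#' all, every trace is flagged.
#'
#' @param ts a [trace_set()] with at least one trace.
#' @param stat shift statistic passed to the pairwise comparison.
#' @return An object of class `"shift_solution"`: list with
#'   \describe{
#'     \item{shifts}{named numeric, one additive log2 factor per input trace;}
#'     \item{flagged}{named logical, `TRUE` for traces that could not be
#'       merged into the main component;}
#'     \item{merge_log}{data frame of (trace_id_a, trace_id_b,
#'       applied_shift) in merge order;}
#'     \item{average}{the final averaged trace of the main component
#'       (an [intensity_trace()]);}
#'     \item{n_comparisons}{number of pairwise comparisons between input
#'       traces (the unit of the linear-scaling contract);}
#'     \item{n_update_comparisons}{recomputations against derived averaged
#'       traces during half-matrix updates.}
#'   }
#' @examples
#' ts <- trace_set(rbind(a = c(10, 12, 14), b = c(13, 15, 17)))
#' hierarchical_shift(ts)$shifts
#' @export
hierarchical_shift <- function(ts, stat = c("median", "mode")) {
  stat <- match.arg(stat)
  stopifnot(inherits(ts, "trace_set"))
  n <- nrow(ts$values)
  if (n == 0L) stop("trace set is empty", call. = FALSE)

  shifts <- stats::setNames(numeric(n), ts$trace_ids)
  flagged <- stats::setNames(logical(n), ts$trace_ids)
  if (n == 1L) {
    return(structure(list(shifts = shifts, flagged = flagged,
                          merge_log = .empty_merge_log(),
                          average = intensity_trace(ts$values[1L, ],
                                                    ts$trace_ids[1L],
                                                    ts$n_members[1L]),
                          n_comparisons = 0L, n_update_comparisons = 0L),
                     class = "shift_solution"))
  }

  vals <- ts$values
  n_mem <- as.numeric(ts$n_members)
  members <- lapply(seq_len(n), identity)
  labels <- ts$trace_ids
  alive <- rep(TRUE, n)

  var_mat <- matrix(NA_real_, n, n)
  med_mat <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- .pair_stats(vals[i, ], vals[j, ], stat)
      var_mat[i, j] <- s$variance
      med_mat[i, j] <- s$median_shift
    }
  }
  n_comp <- n * (n - 1L) / 2L
  n_upd <- 0L

  log_a <- character(0); log_b <- character(0); log_s <- numeric(0)

  while (sum(alive) > 1L) {
    pair <- .min_var_pair(var_mat, alive)
    if (is.null(pair)) break
    i <- pair[1L]; j <- pair[2L]
    shift <- med_mat[i, j]

    log_a <- c(log_a, labels[i]); log_b <- c(log_b, labels[j])
    log_s <- c(log_s, shift)

    shifts[members[[j]]] <- shifts[members[[j]]] + shift
    vals[i, ] <- .merge_values(vals[i, ], vals[j, ] + shift,
                               n_mem[i], n_mem[j])
    n_mem[i] <- n_mem[i] + n_mem[j]
    members[[i]] <- c(members[[i]], members[[j]])
    labels[i] <- paste0("avg(", labels[i], ",", labels[j], ")")
    alive[j] <- FALSE

    for (k in which(alive)) {
      if (k == i) next
      s <- .pair_stats(vals[i, ], vals[k, ], stat)
      n_upd <- n_upd + 1L
      lo <- min(i, k); hi <- max(i, k)
      sgn <- if (i < k) 1 else -1
      var_mat[lo, hi] <- s$variance
      med_mat[lo, hi] <- sgn * s$median_shift
    }
  }

  remaining <- which(alive)
  if (length(remaining) > 1L) {
    if (all(n_mem[remaining] == 1)) {
      flagged[] <- TRUE
      shifts[] <- 0
      main <- remaining[1L]
    } else {
      main <- remaining[which.max(n_mem[remaining])]
      for (r in setdiff(remaining, main)) {
        shifts[members[[r]]] <- 0
        flagged[members[[r]]] <- TRUE
      }
    }
  } else {
    main <- remaining
  }

  structure(list(shifts = shifts, flagged = flagged,
                 merge_log = data.frame(trace_id_a = log_a,
                                        trace_id_b = log_b,
                                        applied_shift = log_s,
                                        stringsAsFactors = FALSE),
                 average = intensity_trace(vals[main, ], labels[main],
                                           n_mem[main]),
                 n_comparisons = as.integer(n_comp),
                 n_update_comparisons = as.integer(n_upd)),
            class = "shift_solution")
}

.empty_merge_log <- function() {
  data.frame(trace_id_a = character(0), trace_id_b = character(0),
             applied_shift = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.shift_solution <- function(x, ...) {
  cat("Shift solution for", length(x$shifts), "traces\n")
  cat("  log2 shifts: ",
      paste(sprintf("%.3g", utils::head(x$shifts, 8L)), collapse = ", "),
      if (length(x$shifts) > 8L) ", ..." else "", "\n", sep = "")
  if (any(x$flagged))
    cat("  flagged (unmerged):", sum(x$flagged), "trace(s)\n")
  cat("  pairwise comparisons:", x$n_comparisons,
      "(+", x$n_update_comparisons, "matrix updates)\n")
  invisible(x)
}

#' Select the most complete traces as anchors
#'
#' Ranks traces by ascending number of missing values (ties broken by
#' input order) and returns the indices of the first `min(nmax, n)`.
#'
#' @inheritParams hierarchical_shift
#' @param nmax maximum number of anchor traces.
#' @return Integer vector of trace indices.
#' @export
select_anchor_traces <- function(ts, nmax) {
  stopifnot(inherits(ts, "trace_set"), nmax >= 1)
  miss <- rowSums(is.na(ts$values))
  utils::head(order(miss), min(as.integer(nmax), length(miss)))
}

#' Align traces with a cap on the pairwise stage
#'
#' For `n <= nmax` traces this is [hierarchical_shift()]. Otherwise the
#' `nmax` most complete traces (fewest missing values) are merged
#' hierarchically into an anchor average, and each remaining trace is
#' shifted independently toward that frozen average by its pairwise
#' median. Pairwise comparisons between measured traces are thus bounded
#' by `nmax (nmax - 1) / 2 + (n - nmax)`, which makes the procedure scale
#' linearly in the number of traces.
#'
#' @inheritParams hierarchical_shift
#' @param nmax cap on the number of traces entering full hierarchical
#'   merging; 50 is the sample-normalization default, 10 the
#'   protein-estimation default.
#' @return A `"shift_solution"` (see [hierarchical_shift()]); shifts are in
#'   input-trace order.
#' @export
capped_shift <- function(ts, nmax, stat = c("median", "mode")) {
  stat <- match.arg(stat)
  stopifnot(inherits(ts, "trace_set"), nmax >= 1)
  n <- nrow(ts$values)
  if (n == 0L) stop("trace set is empty", call. = FALSE)
  nmax <- as.integer(nmax)
  if (n <= nmax) return(hierarchical_shift(ts, stat))

  anchor_idx <- select_anchor_traces(ts, nmax)
  hs <- hierarchical_shift(subset_traces(ts, anchor_idx), stat)

  shifts <- stats::setNames(numeric(n), ts$trace_ids)
  flagged <- stats::setNames(logical(n), ts$trace_ids)
  shifts[anchor_idx] <- hs$shifts
  flagged[anchor_idx] <- hs$flagged

  rest <- setdiff(seq_len(n), anchor_idx)
  avg <- hs$average$values
  extra <- 0L
  for (r in rest) {
    s <- .pair_stats(avg, ts$values[r, ], stat)
    extra <- extra + 1L
    if (s$n_overlap >= 1L) {
      shifts[r] <- s$median_shift
    } else {
      shifts[r] <- 0
      flagged[r] <- TRUE
    }
  }

  structure(list(shifts = shifts, flagged = flagged,
                 merge_log = hs$merge_log,
                 average = hs$average,
                 n_comparisons = hs$n_comparisons + extra,
                 n_update_comparisons = hs$n_update_comparisons),
            class = "shift_solution")
}

#' Apply a shift solution to a trace set
#'
#' Adds each trace's log2 scaling factor to its values; shapes are
#' untouched, only the vertical offsets change.
#'
#' @inheritParams hierarchical_shift
#' @param solution a `"shift_solution"` whose shifts align with `ts`.
#' @return A [trace_set()] with shifted values.
#' @export
apply_shifts <- function(ts, solution) {
  stopifnot(inherits(ts, "trace_set"), inherits(solution, "shift_solution"))
  if (length(solution$shifts) != nrow(ts$values))
    stop("solution does not match the trace set", call. = FALSE)
  trace_set(ts$values + solution$shifts,
            features = ts$features, trace_ids = ts$trace_ids,
            n_members = ts$n_members)
}
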