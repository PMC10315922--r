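# Naive reference implementation of hierarchical trace alignment.
# Rebuilds both full half-matrices from scratch at every iteration instead
# of updating only the affected row/column. Written independently of the
# package engine; selection rule, shift convention, weighting and
# tie-breaking follow the same contract (minimum variance, lowest (row,
# column) on ties, second member shifted onto the first by the median,
# membership-weighted averaging).
naive_hierarchical_shift <- function(ts) {
  vals <- ts$values
  n <- nrow(vals)
  n_mem <- as.numeric(ts$n_members)
  members <- lapply(seq_len(n), identity)
  shifts <- stats::setNames(numeric(n), ts$trace_ids)
  flagged <- stats::setNames(logical(n), ts$trace_ids)
  alive <- rep(TRUE, n)
  if (n == 1L) return(list(shifts = shifts, flagged = flagged))

  pair_med_var <- function(a, b) {
    d <- a - b
    d <- d[!is.na(d)]
    if (!length(d)) return(c(NA_real_, NA_real_, 0))
    c(stats::median(d), if (length(d) >= 2L) stats::var(d) else Inf, length(d))
  }

  repeat {
    act <- which(alive)
    if (length(act) <= 1L) break
    # full rebuild of the half matrices over alive traces
    best <- NULL; best_v <- Inf; found <- FALSE
    med_best <- NA_real_
    for (a in seq_along(act)) {
      if (a == length(act)) break
      for (b in (a + 1L):length(act)) {
        i <- act[a]; j <- act[b]
        mv <- pair_med_var(vals[i, ], vals[j, ])
        if (mv[3] == 0) next
        if (!found || mv[2] < best_v) {
          best <- c(i, j); best_v <- mv[2]; med_best <- mv[1]; found <- TRUE
        }
      }
    }
    if (!found) break
    i <- best[1L]; j <- best[2L]
    shifts[members[[j]]] <- shifts[members[[j]]] + med_best
    bj <- vals[j, ] + med_best
    merged <- (n_mem[i] * vals[i, ] + n_mem[j] * bj) / (n_mem[i] + n_mem[j])
    merged[is.na(vals[i, ])] <- bj[is.na(vals[i, ])]
    merged[is.na(bj)] <- vals[i, is.na(bj)]
    vals[i, ] <- merged
    n_mem[i] <- n_mem[i] + n_mem[j]
    members[[i]] <- c(members[[i]], members[[j]])
    alive[j] <- FALSE
  }

  remaining <- which(alive)
  if (length(remaining) > 1L) {
    if (all(n_mem[remaining] == 1)) {
      flagged[] <- TRUE
      shifts[] <- 0
    } else {
      main <- remaining[which.max(n_mem[remaining])]
      for (r in setdiff(remaining, main)) {
        shifts[members[[r]]] <- 0
        flagged[members[[r]]] <- TRUE
      }
    }
  }
  list(shifts = shifts, flagged = flagged)
}

# random trace sets with scattered missing values for fuzz tests
random_trace_set <- function(n_traces, n_features, miss_prob = 0.2) {
  m <- matrix(round(stats::rnorm(n_traces * n_features, 20, 3), 3),
              n_traces, n_features)
  m[stats::runif(length(m)) < miss_prob] <- NA
  trace_set(m, trace_ids = paste0("T", seq_len(n_traces)))
}
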