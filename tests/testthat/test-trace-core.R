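test_that("pairwise stats extract median and sample variance of the overlap", {
  s <- pairwise_stats(c(23, 25, NA), c(22, 24, 26))
  expect_equal(s$median_shift, 1.0)
  expect_equal(s$variance, 0.0)
  expect_equal(s$n_overlap, 2L)

  s <- pairwise_stats(c(10, 11, 12), c(10, 11, 12))
  expect_equal(s$median_shift, 0.0)
  expect_equal(s$variance, 0.0)
  expect_equal(s$n_overlap, 3L)

  # two-point arithmetic pinned by the n-1 variance denominator
  s <- pairwise_stats(c(10, 12), c(11, 15))
  expect_equal(s$median_shift, -2.0)
  expect_equal(s$variance, 2.0)

  # disjoint support: incomparable sentinel, not an error
  s <- pairwise_stats(c(10, NA), c(NA, 12))
  expect_equal(s$n_overlap, 0L)
  expect_true(is.na(s$median_shift) && is.na(s$variance))

  # single-feature overlap: median defined, variance sentinel Inf
  s <- pairwise_stats(c(10, NA), c(7, 12))
  expect_equal(s$median_shift, 3.0)
  expect_identical(s$variance, Inf)

  expect_error(pairwise_stats(c(1, 2), c(1, 2, 3)), "feature axis")
})

test_that("merging shifts the second trace onto the first and fills gaps", {
  a <- intensity_trace(c(23, 25, NA))
  b <- intensity_trace(c(22, 24, 26))
  m <- merge_pair(a, b, pairwise_stats(a, b))
  expect_equal(m$values, c(23, 25, 27))
  expect_equal(m$n_members, 2L)

  a <- intensity_trace(c(10, 11, 12))
  m <- merge_pair(a, a, pairwise_stats(a, a))
  expect_equal(m$values, a$values)
  expect_equal(m$n_members, 2L)

  a <- intensity_trace(c(10, 10), n_members = 3L)
  b <- intensity_trace(c(13, 13), n_members = 1L)
  m <- merge_pair(a, b, pairwise_stats(a, b))
  expect_equal(m$values, c(10, 10))
  expect_equal(m$n_members, 4L)

  # weighting matters when aligned values differ: 3:1 mean
  a <- intensity_trace(c(10, 14), n_members = 3L)
  b <- intensity_trace(c(10, 10), n_members = 1L)
  st <- pairwise_stats(a, b)   # median shift 2
  m <- merge_pair(a, b, st)
  expect_equal(m$values, c((3 * 10 + 12) / 4, (3 * 14 + 12) / 4))

  bad <- pairwise_stats(c(10, NA), c(NA, 12))
  expect_error(merge_pair(intensity_trace(c(10, NA)),
                          intensity_trace(c(NA, 12)), bad), "incomparable")
})

test_that("hierarchical alignment recovers pure offsets exactly", {
  base <- c(10, 12, 14)
  ts <- trace_set(rbind(T1 = base, T2 = base + 3, T3 = base - 1))
  sol <- hierarchical_shift(ts)
  aligned <- apply_shifts(ts, sol)$values
  for (i in 2:3)
    expect_equal(unname(aligned[i, ]), unname(aligned[1, ]))
  expect_false(any(sol$flagged))
  expect_equal(nrow(sol$merge_log), 2L)
})

test_that("degenerate trace sets are handled per contract", {
  one <- trace_set(matrix(c(1, 2, 3), 1))
  sol <- hierarchical_shift(one)
  expect_equal(unname(sol$shifts), 0)
  expect_error(hierarchical_shift(trace_set(matrix(numeric(0), 0, 3))),
               "empty")

  disjoint <- trace_set(rbind(A = c(10, NA), B = c(NA, 12)))
  sol <- hierarchical_shift(disjoint)
  expect_equal(unname(sol$shifts), c(0, 0))
  expect_true(all(sol$flagged))

  # side component disconnected from a merged main component
  m <- rbind(A = c(10, 11, NA, NA), B = c(12, 13, NA, NA),
             C = c(NA, NA, 5, NA), D = c(NA, NA, NA, 7))
  sol <- hierarchical_shift(trace_set(m))
  expect_false(any(sol$flagged[c("A", "B")]))
  expect_true(all(sol$flagged[c("C", "D")]))
  expect_equal(unname(sol$shifts[c("C", "D")]), c(0, 0))
})

test_that("incremental matrix update matches the naive full-recomputation oracle", {
  set.seed(42)
  for (rep in 1:60) {
    ts <- random_trace_set(sample(2:8, 1), sample(3:10, 1),
                           miss_prob = stats::runif(1, 0, 0.5))
    got <- hierarchical_shift(ts)
    ref <- naive_hierarchical_shift(ts)
    expect_identical(got$shifts, ref$shifts)
    expect_identical(got$flagged, ref$flagged)
  }
})

test_that("alignment is idempotent on its own output", {
  set.seed(7)
  for (rep in 1:10) {
    ts <- random_trace_set(6, 12, miss_prob = 0.25)
    sol <- hierarchical_shift(ts)
    again <- hierarchical_shift(apply_shifts(ts, sol))
    expect_lt(max(abs(again$shifts)), 1e-9)
  }
  # also for the capped path
  ts <- random_trace_set(20, 15, miss_prob = 0.1)
  sol <- capped_shift(ts, nmax = 5)
  again <- capped_shift(apply_shifts(ts, sol), nmax = 5)
  expect_lt(max(abs(again$shifts)), 1e-9)
})

test_that("a global offset changes no relative alignment", {
  set.seed(11)
  ts <- random_trace_set(5, 10, miss_prob = 0.2)
  ts2 <- trace_set(ts$values + 4.2, trace_ids = ts$trace_ids)
  a1 <- apply_shifts(ts, hierarchical_shift(ts))$values
  a2 <- apply_shifts(ts2, hierarchical_shift(ts2))$values
  # pairwise post-shift differences are invariant
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(a1[i, ] - a1[j, ], a2[i, ] - a2[j, ])
})

test_that("shifting preserves trace shapes exactly", {
  set.seed(13)
  ts <- random_trace_set(6, 9, miss_prob = 0.3)
  aligned <- apply_shifts(ts, hierarchical_shift(ts))$values
  for (i in 1:6) {
    d <- aligned[i, ] - ts$values[i, ]
    d <- d[!is.na(d)]
    if (length(d)) expect_lt(diff(range(d)), 1e-12)
  }
})

test_that("the engine is deterministic", {
  set.seed(3)
  ts <- random_trace_set(7, 11, miss_prob = 0.25)
  expect_identical(hierarchical_shift(ts), hierarchical_shift(ts))
  expect_identical(capped_shift(ts, 3), capped_shift(ts, 3))
})

test_that("anchor selection ranks by completeness with stable ties", {
  m <- rbind(A = c(1, 2, 3), B = c(1, NA, NA), C = c(1, 2, NA))
  expect_equal(select_anchor_traces(trace_set(m), 2), c(1L, 3L))
  full <- trace_set(matrix(1, 4, 3))
  expect_equal(select_anchor_traces(full, 2), c(1L, 2L))
  expect_equal(select_anchor_traces(full, 10), 1:4)
})

test_that("capped alignment matches full alignment in the noise-free case", {
  base <- c(20, 22, 21, 25)
  ts <- trace_set(rbind(T1 = base, T2 = base + 2, T3 = base - 3))
  a_full <- apply_shifts(ts, capped_shift(ts, 3))$values
  a_capped <- apply_shifts(ts, capped_shift(ts, 2))$values
  # aligned outputs agree up to one common constant
  d <- a_full - a_capped
  expect_lt(diff(range(d)), 1e-12)
})

test_that("with a single anchor every trace is shifted by its pairwise median", {
  set.seed(21)
  m <- matrix(rnorm(5 * 8, 20), 5, 8)
  m[1, 8] <- NA  # trace 2..5 complete; trace 1 least complete? no:
  # make trace 3 the most complete one
  m[c(1, 2, 4, 5), 1] <- NA
  ts <- trace_set(m)
  sol <- capped_shift(ts, nmax = 1)
  anchor <- 3L
  expect_equal(unname(sol$shifts[anchor]), 0)
  for (r in setdiff(1:5, anchor)) {
    expect_equal(unname(sol$shifts[r]),
                 pairwise_stats(m[anchor, ], m[r, ])$median_shift)
  }
})

test_that("pairwise comparisons between input traces respect the linear bound", {
  set.seed(5)
  ts <- random_trace_set(30, 12, miss_prob = 0.15)
  sol <- capped_shift(ts, nmax = 5)
  expect_lte(sol$n_comparisons, 5 * 4 / 2 + (30 - 5))
  full <- capped_shift(ts, nmax = 30)
  expect_equal(full$n_comparisons, 30 * 29 / 2)
})

test_that("unshiftable remaining traces are flagged, not fatal", {
  # 4 anchors on features 1:3, one remaining trace disjoint from them
  m <- rbind(A = c(10, 11, 12, NA), B = c(11, 12, 13, NA),
             C = c(9, 10, 11, NA), D = c(10, 10, 12, NA),
             E = c(NA, NA, NA, 5))
  sol <- capped_shift(trace_set(m), nmax = 4)
  expect_true(sol$flagged["E"])
  expect_equal(unname(sol$shifts["E"]), 0)
  expect_false(any(sol$flagged[c("A", "B", "C", "D")]))
})
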