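test_that("a single ion trace is its own profile and conserves itself", {
  t <- ion_table(data.frame(protein = "P", ion = "a",
                            sample = c("s1", "s2"), intensity = c(8, 16)))
  ts <- to_trace_sets_by_protein(t)$P
  prof <- estimate_relative_profile(ts)
  expect_equal(unname(prof), c(3, 4), ignore_attr = TRUE)
  expect_equal(unname(rescale_to_linear(prof, t)), c(8, 16))
})

test_that("ionization-efficiency offsets are removed before the median", {
  # two ions that are exact shifted copies, 5 log2 units apart
  shape <- c(10, 12, 11, 14)
  m <- rbind(i1 = shape, i2 = shape + 5)
  prof <- estimate_relative_profile(trace_set(m))
  d <- unname(prof) - shape
  expect_lt(diff(range(d)), 1e-12)
})

test_that("two identical ions double the protein while conserving the total", {
  t <- ion_table(data.frame(protein = "P", ion = rep(c("a", "b"), each = 2),
                            sample = rep(c("s1", "s2"), 2),
                            intensity = c(8, 16, 8, 16)))
  pq <- quantify_all_proteins(t)
  expect_equal(unname(pq$intensities["P", ]), c(16, 32))
  expect_equal(sum(pq$intensities["P", ]), sum(t$intensity))
})

test_that("noisy multi-ion profiles equal naive-oracle alignment plus median", {
  set.seed(77)
  shape <- rnorm(10, 20, 2)
  m <- t(replicate(6, shape + rnorm(1, 0, 3) + rnorm(10, 0, 0.2)))
  m[runif(60) < 0.2] <- NA
  rownames(m) <- paste0("i", 1:6)
  ts <- trace_set(m)
  prof <- estimate_relative_profile(ts, nmax = 10)

  ref <- naive_hierarchical_shift(ts)
  aligned <- m + ref$shifts
  expect_equal(unname(prof),
               unname(apply(aligned, 2, stats::median, na.rm = TRUE)),
               ignore_attr = TRUE)
})

test_that("total linear protein intensity conserves total ion intensity", {
  sim <- simulate_lfq(sim_config(n_proteins = c(A = 40),
                                 species_fc = c(A = 3), seed = 9))
  pq <- quantify_all_proteins(sim$table)
  totals_ion <- rowsum(sim$table$intensity, sim$table$protein)
  for (p in rownames(pq$intensities)) {
    expect_lt(abs(sum(pq$intensities[p, ], na.rm = TRUE) -
                  totals_ion[p, 1]) / totals_ion[p, 1], 1e-9)
  }
})

test_that("adding a constant to one ion changes scale but not shape", {
  set.seed(5)
  m <- matrix(rnorm(4 * 6, 20, 1), 4, 6,
              dimnames = list(paste0("i", 1:4), paste0("s", 1:6)))
  p1 <- estimate_relative_profile(trace_set(m))
  m2 <- m; m2[2, ] <- m2[2, ] + 7
  p2 <- estimate_relative_profile(trace_set(m2))
  d <- unname(p2 - p1)
  expect_lt(diff(range(d)), 1e-9)
})

test_that("profiles are robust: median of aligned traces, recomputed directly", {
  set.seed(8)
  m <- matrix(rnorm(5 * 6, 20, 0.1), 5, 6,
              dimnames = list(paste0("i", 1:5), paste0("s", 1:6)))
  m[3, 4] <- m[3, 4] + 50  # gross single-sample outlier in one ion
  prof <- estimate_relative_profile(trace_set(m))
  aligned <- attr(prof, "aligned")
  expect_equal(unname(prof),
               unname(apply(aligned, 2, stats::median, na.rm = TRUE)),
               ignore_attr = TRUE)
  # the outlier moves that sample by no more than the median allows
  clean <- estimate_relative_profile(trace_set(m[-3, ]))
  expect_lt(abs(prof[4] - clean[4]), 1)
})

test_that("the min_ions filter drops under-supported proteins with a log entry", {
  t <- ion_table(data.frame(protein = c("A", "A", "B"),
                            ion = c("a1", "a2", "b1"),
                            sample = "s1", intensity = c(1, 2, 4)))
  expect_message(pq <- quantify_all_proteins(t, min_ions = 2),
                 "dropped by min_ions")
  expect_equal(rownames(pq$intensities), "A")
  expect_equal(pq$dropped, "B")
})

test_that("quantifying proteins jointly equals quantifying them alone", {
  set.seed(31)
  sim <- simulate_lfq(sim_config(n_proteins = c(A = 6), noise_sd = 0.2,
                                 missing_fraction = 0.1, seed = 31))
  t <- sim$table
  pq_all <- quantify_all_proteins(t)
  p1 <- rownames(pq_all$intensities)[1L]
  sub <- ion_table(as.data.frame(t)[t$protein == p1, ])
  # restore the full sample axis for a fair comparison
  missing_smp <- setdiff(attr(t, "samples"), attr(sub, "samples"))
  expect_length(missing_smp, 0)
  pq_one <- quantify_all_proteins(sub)
  expect_equal(pq_all$intensities[p1, ], pq_one$intensities[p1, ])
})

test_that("samples without ion evidence stay missing, not zero", {
  t <- ion_table(data.frame(protein = c("A", "A", "A", "B"),
                            ion = c("a", "a", "a", "b"),
                            sample = c("s1", "s2", "s3", "s2"),
                            intensity = c(2, 4, 8, 5)))
  pq <- quantify_all_proteins(t)
  expect_true(is.na(pq$intensities["B", "s1"]))
  expect_true(is.na(pq$intensities["B", "s3"]))
  expect_equal(pq$intensities["B", "s2"], 5)
})
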