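test_that("invalid configurations are rejected with named fields", {
  expect_error(sim_config(n_proteins = c(A = 0)), "n_proteins")
  expect_error(sim_config(species_fc = c(A = -1)), "species_fc")
  expect_error(sim_config(missing_fraction = 1.2), "missing_fraction")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(sample_loading_offsets = c(0, 0)),
               "sample_loading_offsets")
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- sim_config(n_proteins = c(A = 20, B = 10), species_fc = c(B = 2),
                    seed = 123)
  s1 <- simulate_lfq(cfg)
  s2 <- simulate_lfq(cfg)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$truth$sample_offsets, s2$truth$sample_offsets)
})

test_that("noise-free construction encodes the fold change exactly", {
  cfg <- sim_config(n_proteins = c(A = 5, B = 5), species_fc = c(B = 4),
                    noise_sd = 0, missing_fraction = 0,
                    sample_loading_offsets = rep(0, 6), seed = 2)
  sim <- simulate_lfq(cfg)
  t <- sim$table
  cond <- sim$truth$condition[t$sample]
  for (ion in unique(t$ion[startsWith(t$protein, "B")])) {
    sub <- t[t$ion == ion, ]
    d <- log2(sub$intensity[cond[t$ion == ion] == "cond1"][1]) -
         log2(sub$intensity[cond[t$ion == ion] == "cond2"][1])
    expect_equal(d, 2)
  }
  for (ion in unique(t$ion[startsWith(t$protein, "A")])) {
    sub <- t[t$ion == ion, ]
    expect_lt(diff(range(log2(sub$intensity))), 1e-12)
  }
})

test_that("the realized missing fraction matches the configured one", {
  cfg <- sim_config(n_proteins = c(A = 300), ions_per_protein = c(6, 6),
                    missing_fraction = 0.2, seed = 4)
  sim <- simulate_lfq(cfg)
  n_total <- 300 * 6 * 6
  realized <- 1 - nrow(sim$table) / n_total
  se <- sqrt(0.2 * 0.8 / n_total)
  expect_lt(abs(realized - 0.2), 3 * se)
})

test_that("missingness is intensity dependent (left-censoring)", {
  cfg <- sim_config(n_proteins = c(A = 200), ions_per_protein = c(4, 4),
                    missing_fraction = 0.3, seed = 6)
  sim <- simulate_lfq(cfg)
  # observed records per ion, split by base intensity tercile
  obs <- table(sim$table$ion)
  med_l2 <- tapply(log2(sim$table$intensity), sim$table$ion, stats::median)
  lo <- names(med_l2)[med_l2 < stats::quantile(med_l2, 1 / 3)]
  hi <- names(med_l2)[med_l2 > stats::quantile(med_l2, 2 / 3)]
  expect_gt(mean(obs[hi]), mean(obs[lo]))
})

test_that("generated tables satisfy the ion-table invariants", {
  sim <- simulate_lfq(sim_config(seed = 10))
  t <- sim$table
  expect_s3_class(t, "ion_table")
  expect_true(all(t$intensity > 0))
  expect_false(anyDuplicated(paste(t$ion, t$sample)) > 0)
  map <- unique(t[c("ion", "protein")])
  expect_false(anyDuplicated(map$ion) > 0)
  # truth covers every generated protein (a protein may lose all its
  # records to censoring, but never the reverse)
  expect_true(all(unique(t$protein) %in% names(sim$truth$protein_log2fc)))
})

test_that("DIA-style configs emit MS1 plus fragment traces per precursor", {
  cfg <- sim_config(n_proteins = c(A = 3), ions_per_protein = c(2, 2),
                    fragments_per_precursor = 3, missing_fraction = 0,
                    seed = 8)
  sim <- simulate_lfq(cfg)
  ions <- unique(sim$table$ion)
  expect_length(ions, 3 * 2 * 4)
  expect_equal(sum(grepl("\\|MS1$", ions)), 6)
  expect_equal(sum(grepl("\\|frag", ions)), 18)
})

test_that("the noise-free complete pipeline recovers truth exactly", {
  # unregulated majority: the median pairwise shift is exact at noise 0
  cfg <- sim_config(n_proteins = c(A = 14, B = 6), species_fc = c(B = 6),
                    noise_sd = 0, missing_fraction = 0, seed = 12)
  rep <- end_to_end_truth_recovery(cfg)
  expect_lt(max(abs(rep$per_species$bias)), 1e-9)
  expect_true(all(rep$per_species$sd < 1e-9))
  expect_lt(rep$factor_error, 1e-9)
})
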