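#' Configuration for simulated spike-in datasets
#'
#' Describes a two-condition mixed-species spike-in design with known
#' ground truth: several species blocks of proteins, each at a fixed
#' linear abundance ratio between condition 1 and condition 2, per-ion
#' base intensities spanning orders of magnitude, per-ion ionization
#' offsets, per-sample loading offsets, multiplicative (log-normal)
#' noise and intensity-dependent (left-censored) missingness.
#'
#' @param n_proteins named integer vector: proteins per species block.
#' @param species_fc named numeric vector of linear abundance ratios
#'   condition1 / condition2 per species; species not named get ratio 1.
#' @param n_samples_per_condition replicates per condition (default 3).
#' @param ions_per_protein integer range (min, max) of precursors per
#'   protein (default 2 to 6).
#' @param fragments_per_precursor number of MS2 fragment traces per
#'   precursor in addition to its MS1 trace; 0 (default) emulates DDA
#'   (MS1 precursor traces only), 3 a typical DIA export where each
#'   fragment ion is an independent trace.
#' @param base_log2_range range of per-protein base log2 intensity,
#'   drawn uniformly (default 18 to 30, i.e. linear intensities spanning
#'   about four orders of magnitude).
#' @param ionization_offset_sd standard deviation (log2 units) of the
#'   per-ion constant offset emulating ionization-efficiency differences
#'   (default 2).
#' @param noise_sd standard deviation of additive Gaussian noise in log2
#'   space, i.e. multiplicative log-normal error (default 0.3).
#' @param sample_loading_offsets per-sample additive log2 loading
#'   offsets; `NULL` (default) draws them uniformly from (-1, 1).
#' @param missing_fraction target marginal fraction of records dropped
#'   (default 0.15); dropping probability follows a logistic function of
#'   the record's log2 intensity (low-abundance ions missing more often),
#'   calibrated so the marginal fraction matches.
#' @param missing_steepness scale (log2 units) of the logistic
#'   missingness curve (default 1.5).
#' @param seed RNG seed; fully determines the output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = c(background = 400, spiked = 200),
                       species_fc = c(spiked = 6),
                       n_samples_per_condition = 3,
                       ions_per_protein = c(2, 6),
                       fragments_per_precursor = 0,
                       base_log2_range = c(18, 30),
                       ionization_offset_sd = 2,
                       noise_sd = 0.3,
                       sample_loading_offsets = NULL,
                       missing_fraction = 0.15,
                       missing_steepness = 1.5,
                       seed = 1) {
  cfg <- list(n_proteins = n_proteins, species_fc = species_fc,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              ions_per_protein = as.integer(ions_per_protein),
              fragments_per_precursor = as.integer(fragments_per_precursor),
              base_log2_range = as.numeric(base_log2_range),
              ionization_offset_sd = as.numeric(ionization_offset_sd),
              noise_sd = as.numeric(noise_sd),
              sample_loading_offsets = sample_loading_offsets,
              missing_fraction = as.numeric(missing_fraction),
              missing_steepness = as.numeric(missing_steepness),
              seed = as.integer(seed))
  problems <- character(0)
  if (is.null(names(cfg$n_proteins)) || any(cfg$n_proteins < 1))
    problems <- c(problems, "n_proteins: named counts >= 1 required")
  if (length(cfg$species_fc) && (is.null(names(cfg$species_fc)) ||
      any(cfg$species_fc <= 0)))
    problems <- c(problems, "species_fc: named positive ratios required")
  if (cfg$n_samples_per_condition < 1)
    problems <- c(problems, "n_samples_per_condition: must be >= 1")
  if (length(cfg$ions_per_protein) != 2L || any(cfg$ions_per_protein < 1) ||
      diff(cfg$ions_per_protein) < 0)
    problems <- c(problems, "ions_per_protein: range (min, max), min >= 1")
  if (cfg$fragments_per_precursor < 0)
    problems <- c(problems, "fragments_per_precursor: must be >= 0")
  if (cfg$noise_sd < 0)
    problems <- c(problems, "noise_sd: must be >= 0")
  if (cfg$ionization_offset_sd < 0)
    problems <- c(problems, "ionization_offset_sd: must be >= 0")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    problems <- c(problems, "missing_fraction: must be in [0, 1)")
  if (cfg$missing_steepness <= 0)
    problems <- c(problems, "missing_steepness: must be > 0")
  n_samples <- 2L * cfg$n_samples_per_condition
  if (!is.null(cfg$sample_loading_offsets) &&
      length(cfg$sample_loading_offsets) != n_samples)
    problems <- c(problems,
                  "sample_loading_offsets: length must be 2 * n_samples_per_condition")
  if (length(problems))
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate an ion table with known ground truth
#'
#' Generates a two-condition spike-in dataset under a [sim_config()].
#' Each record's log2 intensity is
#' `base(protein) + ionization_offset(ion) + log2(species ratio) * [condition 1]
#'  + loading_offset(sample) + Gaussian(0, noise_sd)`,
#' and the record is dropped with a probability that decreases
#' logistically with its log2 intensity, calibrated to the configured
#' marginal missing fraction. The output is fully determined by the seed.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `"lfq_sim"`: `table` (an [ion_table()]) and
#'   `truth` with `protein_log2fc` (condition 1 minus condition 2, named
#'   per protein), `species` (named per protein), `sample_offsets`,
#'   `condition` (named per sample, `"cond1"`/`"cond2"`),
#'   `ion_offsets`, and `config`.
#' @export
simulate_lfq <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  species <- rep(names(cfg$n_proteins), cfg$n_proteins)
  n_prot <- length(species)
  prot_ids <- sprintf("%s_P%04d", species, unlist(lapply(cfg$n_proteins, seq_len)))
  fc_lin <- rep(1, n_prot)
  hit <- species %in% names(cfg$species_fc)
  fc_lin[hit] <- cfg$species_fc[species[hit]]
  prot_log2fc <- log2(fc_lin)

  n_rep <- cfg$n_samples_per_condition
  sample_ids <- c(sprintf("cond1_rep%d", seq_len(n_rep)),
                  sprintf("cond2_rep%d", seq_len(n_rep)))
  condition <- stats::setNames(rep(c("cond1", "cond2"), each = n_rep),
                               sample_ids)
  loading <- cfg$sample_loading_offsets
  if (is.null(loading)) loading <- stats::runif(length(sample_ids), -1, 1)
  loading <- stats::setNames(as.numeric(loading), sample_ids)

  base <- stats::runif(n_prot, cfg$base_log2_range[1L], cfg$base_log2_range[2L])
  prec_range <- seq(cfg$ions_per_protein[1L], cfg$ions_per_protein[2L])
  n_prec <- if (length(prec_range) == 1L) rep(prec_range, n_prot)
            else sample(prec_range, n_prot, replace = TRUE)

  # expand to one row per ion: each precursor contributes an MS1 trace and
  # fragments_per_precursor fragment traces, each with its own offset
  n_frag <- cfg$fragments_per_precursor
  ions_per_prec <- 1L + n_frag
  prot_idx <- rep(seq_len(n_prot), n_prec * ions_per_prec)
  prec_idx <- unlist(lapply(n_prec, function(k) rep(seq_len(k), each = ions_per_prec)))
  level <- rep(c("MS1", if (n_frag > 0) paste0("frag", seq_len(n_frag))),
               sum(n_prec))
  ion_ids <- paste(prot_ids[prot_idx],
                   paste0("p", prec_idx), level, sep = "|")
  n_ions <- length(ion_ids)
  ion_offset <- stats::rnorm(n_ions, 0, cfg$ionization_offset_sd)

  n_s <- length(sample_ids)
  # record grid: ions x samples, column-major over samples
  ri <- rep(seq_len(n_ions), times = n_s)
  rs <- rep(seq_len(n_s), each = n_ions)
  log2_int <- base[prot_idx][ri] + ion_offset[ri] +
    prot_log2fc[prot_idx][ri] * (condition[rs] == "cond1") +
    loading[rs] +
    if (cfg$noise_sd > 0) stats::rnorm(n_ions * n_s, 0, cfg$noise_sd) else 0

  keep <- rep(TRUE, length(log2_int))
  if (cfg$missing_fraction > 0) {
    s <- cfg$missing_steepness
    f <- function(x0) mean(stats::plogis((x0 - log2_int) / s)) -
      cfg$missing_fraction
    x0 <- stats::uniroot(f, range(log2_int) + c(-60, 60), tol = 1e-8)$root
    p_miss <- stats::plogis((x0 - log2_int) / s)
    keep <- stats::runif(length(log2_int)) >= p_miss
  }

  df <- data.frame(protein = prot_ids[prot_idx][ri][keep],
                   ion = ion_ids[ri][keep],
                   sample = sample_ids[rs][keep],
                   intensity = 2^log2_int[keep],
                   stringsAsFactors = FALSE)

  structure(list(table = ion_table(df),
                 truth = list(protein_log2fc = stats::setNames(prot_log2fc, prot_ids),
                              species = stats::setNames(species, prot_ids),
                              sample_offsets = loading,
                              condition = condition,
                              ion_offsets = stats::setNames(ion_offset, ion_ids),
                              config = cfg)),
            class = "lfq_sim")
}

#' @export
print.lfq_sim <- function(x, ...) {
  cat("Simulated LFQ dataset\n  ")
  print(x$table)
  tab <- table(x$truth$species)
  cat("  species blocks:",
      paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end ground-truth recovery report
#'
#' Simulates a dataset, runs the full pipeline (normalization + protein
#' quantification) and compares the results to the known ground truth:
#' per-species bias and spread of recovered protein log2 fold changes
#' (condition 1 minus condition 2), and the worst-case error of the
#' recovered sample normalization factors against the true loading
#' offsets (both gauged to median 0).
#'
#' @param cfg a [sim_config()].
#' @param ... passed to [tracelfq()].
#' @return A list of class `"recovery_report"`: `per_species` data frame
#'   (species, true and median recovered log2 FC, bias, sd, n), and
#'   `factor_error` (max abs log2 deviation of recovered factors).
#' @export
end_to_end_truth_recovery <- function(cfg, ...) {
  sim <- simulate_lfq(cfg)
  fit <- tracelfq(sim$table, ...)
  cond <- sim$truth$condition
  fc <- log2fc_per_protein(fit, names(cond)[cond == "cond1"],
                           names(cond)[cond == "cond2"])
  sp <- sim$truth$species[names(fc)]
  truth <- sim$truth$protein_log2fc[names(fc)]
  per_species <- do.call(rbind, lapply(split(seq_along(fc), sp), function(i) {
    data.frame(species = sp[i][1L],
               true_log2fc = truth[i][1L],
               median_log2fc = stats::median(fc[i], na.rm = TRUE),
               bias = stats::median(fc[i] - truth[i], na.rm = TRUE),
               sd = stats::sd(fc[i], na.rm = TRUE),
               n = sum(!is.na(fc[i])),
               stringsAsFactors = FALSE)
  }))
  rownames(per_species) <- NULL

  true_o <- sim$truth$sample_offsets
  rec <- fit$normalization$log2_factors[names(true_o)]
  # factors should undo the offsets; compare in the common median-0 gauge
  err <- (rec + true_o) - stats::median(rec + true_o)
  structure(list(per_species = per_species,
                 factor_error = max(abs(err)),
                 fold_changes = fc),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Ground-truth recovery\n")
  print(x$per_species, digits = 4)
  cat(sprintf("  max |factor error|: %.4g log2 units\n", x$factor_error))
  invisible(x)
}
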