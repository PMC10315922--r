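# Readers for search-engine ion tables and writers for results.
# All formats are plain TSV, UTF-8, "." decimal point.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L) stop("empty input: ", path, call. = FALSE)
  df
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " input is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

# numeric coercion with a counted warning for unparseable entries
.as_intensity <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(v)
  if (any(bad))
    warning(sum(bad), " row(s) with unparseable intensity skipped",
            call. = FALSE)
  v
}

#' Read a generic ion table
#'
#' Accepts the canonical TSV dialects: long format with columns
#' `protein`, `ion`, `sample`, `intensity`, or wide format with columns
#' `protein`, `ion` and one intensity column per sample. Empty or
#' non-positive cells are missing.
#'
#' @param path TSV file path.
#' @param type `"auto"` (default), `"long"` or `"wide"`. Auto-detection
#'   errors when the dialect is ambiguous.
#' @return An [ion_table()].
#' @export
read_generic <- function(path, type = c("auto", "long", "wide")) {
  type <- match.arg(type)
  df <- .read_tsv(path)
  long_cols <- c("protein", "ion", "sample", "intensity")
  if (type == "auto") {
    is_long <- all(long_cols %in% names(df))
    is_wide <- all(c("protein", "ion") %in% names(df)) &&
      length(setdiff(names(df), long_cols)) > 0L && !is_long
    if (is_long && "sample" %in% names(df) &&
        length(setdiff(names(df), long_cols)) > 0L)
      stop("ambiguous dialect (long columns plus extra sample-like columns); ",
           "pass an explicit input type", call. = FALSE)
    if (is_long) type <- "long"
    else if (is_wide) type <- "wide"
    else stop("cannot detect dialect; pass an explicit input type",
              call. = FALSE)
  }
  if (type == "long") {
    .require_columns(df, long_cols, "generic long")
    df$intensity <- .as_intensity(df$intensity)
    return(ion_table(df[long_cols]))
  }
  .require_columns(df, c("protein", "ion"), "generic wide")
  smp <- setdiff(names(df), c("protein", "ion"))
  if (!length(smp)) stop("wide input has no sample columns", call. = FALSE)
  recs <- lapply(smp, function(s) {
    v <- .as_intensity(df[[s]])
    keep <- !is.na(v) & v > 0
    data.frame(protein = df$protein[keep], ion = df$ion[keep],
               sample = s, intensity = v[keep], stringsAsFactors = FALSE)
  })
  ion_table(do.call(rbind, recs))
}

#' Read a MaxQuant evidence table
#'
#' Parses `evidence.txt`: one ion per (modified sequence, charge), one
#' sample per raw file; rows with empty or zero intensity are skipped
#' and duplicate precursor-run rows are summed in linear space. Rows
#' marked as decoys (`Reverse == "+"`) or potential contaminants are
#' dropped by default. When `protein_groups_path` is given, ions are
#' remapped to the protein-group identifiers of `proteinGroups.txt` via
#' the evidence `Protein group IDs` column; evidence rows assigned to
#' more than one protein group are dropped with a warning.
#'
#' @param evidence_path path to `evidence.txt`.
#' @param protein_groups_path optional path to `proteinGroups.txt`.
#' @param keep_flagged keep decoy/contaminant-marked rows (default
#'   `FALSE`).
#' @return An [ion_table()].
#' @export
read_maxquant <- function(evidence_path, protein_groups_path = NULL,
                          keep_flagged = FALSE) {
  df <- .read_tsv(evidence_path)
  .require_columns(df, c("Modified sequence", "Charge", "Raw file",
                         "Intensity"), "MaxQuant evidence")
  if (!keep_flagged) {
    for (col in c("Reverse", "Potential contaminant")) {
      if (col %in% names(df)) {
        flagged <- !is.na(df[[col]]) & df[[col]] == "+"
        df <- df[!flagged, , drop = FALSE]
      }
    }
    if (nrow(df) == 0L)
      stop("no rows left after removing decoy/contaminant entries",
           call. = FALSE)
  }

  if (!is.null(protein_groups_path)) {
    .require_columns(df, "Protein group IDs", "MaxQuant evidence")
    pg <- .read_tsv(protein_groups_path)
    .require_columns(pg, c("id", "Protein IDs"), "MaxQuant proteinGroups")
    gid <- as.character(df[["Protein group IDs"]])
    multi <- grepl(";", gid, fixed = TRUE)
    if (any(multi))
      warning(sum(multi),
              " evidence row(s) assigned to multiple protein groups; dropped",
              call. = FALSE)
    df <- df[!multi, , drop = FALSE]
    protein <- pg[["Protein IDs"]][match(df[["Protein group IDs"]],
                                         as.character(pg$id))]
    unmatched <- is.na(protein)
    if (any(unmatched))
      warning(sum(unmatched),
              " evidence row(s) with unknown protein group id; dropped",
              call. = FALSE)
    df <- df[!unmatched, , drop = FALSE]
    protein <- protein[!unmatched]
  } else {
    pcol <- intersect(c("Leading razor protein", "Proteins"), names(df))
    if (!length(pcol))
      stop("MaxQuant evidence input is missing a protein identifier column ",
           "(Leading razor protein or Proteins)", call. = FALSE)
    protein <- as.character(df[[pcol[1L]]])
  }

  intensity <- .as_intensity(df$Intensity)
  keep <- !is.na(intensity) & intensity > 0
  ion_table(data.frame(
    protein = protein[keep],
    ion = paste(df[["Modified sequence"]][keep],
                paste0("z", df$Charge[keep]), sep = "|"),
    sample = as.character(df[["Raw file"]][keep]),
    intensity = intensity[keep],
    stringsAsFactors = FALSE))
}

#' Read a DIA-NN main report
#'
#' Builds one intensity trace per precursor MS1 area and one per fragment
#' position of `Fragment.Quant.Raw` (delimiter-separated values, trailing
#' empties ignored). Zero or missing quantities are dropped.
#'
#' @param report_path path to the long-format DIA-NN report TSV.
#' @param fragment_delim delimiter inside `Fragment.Quant.Raw`
#'   (default `";"`).
#' @return An [ion_table()].
#' @export
read_diann <- function(report_path, fragment_delim = ";") {
  df <- .read_tsv(report_path)
  .require_columns(df, c("Run", "Protein.Group", "Precursor.Id", "MS1.Area",
                         "Fragment.Quant.Raw"), "DIA-NN report")
  ms1 <- .as_intensity(df$MS1.Area)
  frag_str <- as.character(df$Fragment.Quant.Raw)
  frag_str[is.na(frag_str)] <- ""
  frags <- strsplit(frag_str, fragment_delim, fixed = TRUE)

  recs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ions <- character(0); vals <- numeric(0)
    if (!is.na(ms1[i]) && ms1[i] > 0) {
      ions <- paste(df$Precursor.Id[i], "MS1", sep = "|")
      vals <- ms1[i]
    }
    fv <- suppressWarnings(as.numeric(frags[[i]]))
    ok <- !is.na(fv) & fv > 0
    if (any(ok)) {
      ions <- c(ions, paste(df$Precursor.Id[i],
                            paste0("frag", which(ok)), sep = "|"))
      vals <- c(vals, fv[ok])
    }
    if (length(ions))
      recs[[i]] <- data.frame(protein = df$Protein.Group[i], ion = ions,
                              sample = df$Run[i], intensity = vals,
                              stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) stop("no positive intensities in DIA-NN report",
                          call. = FALSE)
  ion_table(do.call(rbind, recs))
}

#' Read a Spectronaut fragment-ion long export
#'
#' Expects a long-format export with one row per fragment-ion quantity:
#' columns `R.FileName` (run), `PG.ProteinGroups`, `EG.PrecursorId`,
#' `F.FrgIon` (fragment or isotope identifier) and `F.PeakArea`
#' (quantity). Each fragment ion of each precursor becomes an
#' independent intensity trace.
#'
#' @param report_path path to the export TSV.
#' @return An [ion_table()].
#' @export
read_spectronaut <- function(report_path) {
  df <- .read_tsv(report_path)
  .require_columns(df, c("R.FileName", "PG.ProteinGroups", "EG.PrecursorId",
                         "F.FrgIon", "F.PeakArea"), "Spectronaut export")
  intensity <- .as_intensity(df$F.PeakArea)
  keep <- !is.na(intensity) & intensity > 0
  if (!any(keep)) stop("no positive intensities in Spectronaut export",
                       call. = FALSE)
  ion_table(data.frame(
    protein = as.character(df$PG.ProteinGroups)[keep],
    ion = paste(df$EG.PrecursorId, df$F.FrgIon, sep = "|")[keep],
    sample = as.character(df$R.FileName)[keep],
    intensity = intensity[keep],
    stringsAsFactors = FALSE))
}

#' Write an ion table as generic TSV
#'
#' @param t an [ion_table()].
#' @param path output TSV path.
#' @param format `"long"` (protein, ion, sample, intensity) or `"wide"`
#'   (protein, ion, one column per sample; empty cell = missing).
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(t, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(t, "ion_table"))
  if (format == "long") {
    utils::write.table(as.data.frame(t)[c("protein", "ion", "sample",
                                          "intensity")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    smp <- attr(t, "samples"); ions <- attr(t, "ions")
    m <- matrix(NA_real_, length(ions), length(smp),
                dimnames = list(ions, smp))
    m[cbind(match(t$ion, ions), match(t$sample, smp))] <- t$intensity
    wide <- data.frame(protein = t$protein[match(ions, t$ion)], ion = ions,
                       m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write the quantification results of a fit
#'
#' Emits three TSV files into `dir`: `protein_intensities.tsv` (wide,
#' rows = protein groups, columns = samples, linear intensities, empty
#' cell = missing), `aligned_ions.tsv` (long: protein, ion, sample,
#' aligned_log2_intensity), and `normalization_factors.tsv` (sample,
#' log2_factor, flag) when the fit was normalized.
#'
#' @param fit a [tracelfq()] fit.
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "tracelfq_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p <- file.path(dir, "protein_intensities.tsv")
  wide <- data.frame(protein = rownames(fit$intensities), fit$intensities,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(wide, p, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  paths <- c(paths, p)

  p <- file.path(dir, "aligned_ions.tsv")
  utils::write.table(fit$aligned_ions, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(fit$normalization)) {
    p <- file.path(dir, "normalization_factors.tsv")
    utils::write.table(
      data.frame(sample = names(fit$normalization$log2_factors),
                 log2_factor = fit$normalization$log2_factors,
                 flag = fit$normalization$flags,
                 stringsAsFactors = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a wide protein intensity table back into a matrix
#'
#' @param path TSV written by [write_outputs()] (`protein` column plus
#'   one column per sample).
#' @return Protein-by-sample numeric matrix with `NA` for empty cells.
#' @export
read_protein_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, "protein", "protein table")
  m <- as.matrix(df[setdiff(names(df), "protein")])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein
  m
}
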