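## Readers and writers for the pipeline's CSV tables.
##
## All tables are RFC-4180 CSV, UTF-8, '.' decimal separator. Units are
## fixed throughout the package: voltages in mV, times in s,
## concentrations in uM. Missing optional values are empty fields and
## surface as NA, never as zero.

.PHASES <- c("control", "drug", "washout")

.required_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    .stopf("%s: missing required column(s): %s", what, paste(missing, collapse = ", "))
}

#' Read a drug metadata table
#'
#' One row per drug: three-letter code, name, therapeutic class, the
#' concentration tested in the train protocol and (optionally) the human
#' plasma concentration. Codes are upper-cased on read and must be unique.
#'
#' @param path path to a CSV file with columns `drug_code`, `name`,
#'   `therapeutic_class`, `concentration_tested_uM` and optionally
#'   `mechanism`, `plasma_concentration_uM`.
#' @return A data.frame, one row per drug.
#' @export
#' @examples
#' drugs <- read_drug_table(sciblock_example("table1_drugs.csv"))
#' nrow(drugs) # 44
read_drug_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .required_cols(df, c("drug_code", "name", "therapeutic_class", "concentration_tested_uM"),
                 "drug table")
  if (nrow(df) == 0L) return(df)
  df$drug_code <- toupper(trimws(df$drug_code))
  dup <- df$drug_code[duplicated(df$drug_code)]
  if (length(dup) > 0L)
    .stopf("drug table: duplicate drug_code: %s", paste(unique(dup), collapse = ", "))
  bad <- which(is.na(df$concentration_tested_uM))
  if (length(bad) > 0L)
    .stopf("drug table row %s: missing concentration_tested_uM", paste(bad, collapse = ", "))
  bad <- which(df$concentration_tested_uM <= 0)
  if (length(bad) > 0L)
    .stopf("drug table row %s: concentration_tested_uM must be > 0", paste(bad, collapse = ", "))
  if ("plasma_concentration_uM" %in% names(df)) {
    bad <- which(!is.na(df$plasma_concentration_uM) & df$plasma_concentration_uM <= 0)
    if (length(bad) > 0L)
      .stopf("drug table row %s: plasma_concentration_uM must be > 0", paste(bad, collapse = ", "))
  }
  df
}

#' Read train-protocol recordings
#'
#' Long-format table, one row per evoked pulse of the 5 Hz train
#' protocol. Validates, per cell: strictly increasing sweep times, known
#' phase labels appearing in the order control, drug, washout, five
#' pulses per train and non-negative peak amplitudes.
#'
#' @param path CSV with columns `drug_code`, `cell_id`, `sweep_time_s`,
#'   `train_index`, `pulse_index`, `phase`, `peak_amplitude`.
#' @return A data.frame ordered by drug, cell and sweep time.
#' @export
read_recordings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .required_cols(df, c("drug_code", "cell_id", "sweep_time_s", "train_index",
                       "pulse_index", "phase", "peak_amplitude"), "recordings")
  if (nrow(df) == 0L) return(df)
  df$drug_code <- toupper(df$drug_code)
  bad <- which(!(df$phase %in% .PHASES))
  if (length(bad) > 0L)
    .stopf("recordings row %d: unknown phase label '%s'", bad[1], df$phase[bad[1]])
  bad <- which(df$peak_amplitude < 0)
  if (length(bad) > 0L)
    .stopf("recordings row %d: negative peak_amplitude", bad[1])
  bad <- which(!(df$pulse_index %in% 1:5))
  if (length(bad) > 0L)
    .stopf("recordings row %d: pulse_index must be in 1..5", bad[1])
  for (key in split(seq_len(nrow(df)), list(df$drug_code, df$cell_id), drop = TRUE)) {
    sub <- df[key, ]
    if (is.unsorted(sub$sweep_time_s, strictly = TRUE))
      .stopf("recordings: non-monotone sweep times for cell '%s' (first offending row %d)",
             sub$cell_id[1], key[which(diff(sub$sweep_time_s) <= 0)[1] + 1L])
    ph <- match(sub$phase, .PHASES)
    if (is.unsorted(ph))
      .stopf("recordings: phases out of control->drug->washout order for cell '%s'",
             sub$cell_id[1])
    per_train <- table(paste(sub$phase, sub$train_index))
    if (any(per_train != 5L))
      .stopf("recordings: cell '%s' has a train without exactly 5 pulses", sub$cell_id[1])
  }
  df[order(df$drug_code, df$cell_id, df$sweep_time_s), , drop = FALSE]
}

#' Read availability (steady-state inactivation) curves
#'
#' One row per pre-pulse voltage, per cell and condition. The drug-free
#' curve is normalized to its own maximum, the drug curve to the
#' drug-free maximum.
#'
#' @param path CSV with columns `drug_code`, `cell_id`,
#'   `prepulse_voltage_mV`, `normalized_current`, `condition`
#'   (`control` or `drug`).
#' @return A data.frame ordered by drug, cell, condition and voltage.
#' @export
read_availability <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .required_cols(df, c("drug_code", "cell_id", "prepulse_voltage_mV",
                       "normalized_current", "condition"), "availability")
  if (nrow(df) == 0L) return(df)
  df$drug_code <- toupper(df$drug_code)
  bad <- which(!(df$condition %in% c("control", "drug")))
  if (length(bad) > 0L)
    .stopf("availability row %d: unknown condition '%s'", bad[1], df$condition[bad[1]])
  for (key in split(seq_len(nrow(df)),
                    list(df$drug_code, df$cell_id, df$condition), drop = TRUE)) {
    sub <- df[key, ]
    if (nrow(sub) < 6L)
      .stopf("availability: cell '%s' (%s) has fewer than 6 voltage points",
             sub$cell_id[1], sub$condition[1])
    if (is.unsorted(sub$prepulse_voltage_mV, strictly = TRUE))
      .stopf("availability: voltages not strictly increasing for cell '%s' (%s)",
             sub$cell_id[1], sub$condition[1])
    if (sub$condition[1] == "control" &&
        any(sub$normalized_current < 0 | sub$normalized_current > 1 + 1e-9))
      .stopf("availability: drug-free normalized_current outside [0, 1] for cell '%s'",
             sub$cell_id[1])
    if (any(sub$normalized_current < 0))
      .stopf("availability: negative normalized_current for cell '%s'", sub$cell_id[1])
  }
  df[order(df$drug_code, df$cell_id, df$condition, df$prepulse_voltage_mV), , drop = FALSE]
}

#' Read a chemical descriptor table
#'
#' @param path CSV with columns `drug_code`, `logP`, `logD7_3`, `pKa`,
#'   `MW`, `PSA`, `aromatic_atom_count`, `min_projection_area`, and
#'   optionally `n_pka` and a logical `acid` flag.
#' @return A data.frame, one row per drug; codes upper-cased.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .required_cols(df, c("drug_code", "logP", "pKa", "MW", "PSA",
                       "aromatic_atom_count", "min_projection_area"), "descriptors")
  df$drug_code <- toupper(df$drug_code)
  dup <- df$drug_code[duplicated(df$drug_code)]
  if (length(dup) > 0L)
    .stopf("descriptors: duplicate drug_code: %s", paste(unique(dup), collapse = ", "))
  df
}

.PROFILE_COLS <- c("drug_code", "cc_uM", "n_cells",
                   "Inh", "Inh_sem", "IC50_uM", "Rev", "Rev_sem", "UD", "UD_sem",
                   "tau_on_s", "tau_on_sem", "tau_off_s", "tau_off_sem",
                   "Inh_150", "dV_half_mV", "Kr_uM", "Ki_dV_uM", "Ki_kapp_uM", "SD")

#' Write biophysical profiles to CSV
#'
#' Writes a profile table with a deterministic column order and floats
#' rounded to a fixed number of significant digits (4 by default, the
#' precision of the printed reference tables).
#'
#' @param profiles data.frame containing at least `drug_code`; the
#'   canonical profile columns are written first, any extras after.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, digits = 4) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) > 0L && !"drug_code" %in% names(profiles))
    .stopf("profiles: drug_code column is required")
  cols <- c(intersect(.PROFILE_COLS, names(profiles)),
            setdiff(names(profiles), .PROFILE_COLS))
  out <- profiles[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, digits))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a biophysical profile table written by [write_profiles()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) df$drug_code <- toupper(df$drug_code)
  df
}

#' Write train recordings or availability curves to CSV
#'
#' Thin writers matching [read_recordings()] / [read_availability()],
#' used by the simulator so that synthetic data round-trips through the
#' same files an instrument export would use.
#'
#' @param x data.frame in the respective long format.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_recordings
#' @export
write_availability <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
sciblock_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "sciblock")))
  path <- system.file("extdata", file, package = "sciblock")
  if (path == "") .stopf("no packaged file named '%s'", file)
  path
}
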