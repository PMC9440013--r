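# Chemical records, HLC <-> Kaw unit conversion, CSV ingest/emit.

#' Canonical column names for chemical record tables
#'
#' Chemical records are plain data frames with these columns. Numeric
#' columns use `NA` for absent values; on disk an absent value is an
#' empty cell ("NA"/"NaN" are accepted on read, never written).
#'
#' @format Character vector of 16 column names.
#' @export
chem_record_columns <- c(
  "record_id", "name", "cas",
  "log_kow", "log_kaw", "hlc_atm_m3_mol",
  "E", "S", "A", "B", "V", "L",
  "log_klw_exp", "log_kpw_exp",
  "source_kow", "source_kaw"
)

.numeric_cols <- c("log_kow", "log_kaw", "hlc_atm_m3_mol",
                   "E", "S", "A", "B", "V", "L",
                   "log_klw_exp", "log_kpw_exp")
.asd_cols <- c("E", "S", "A", "B", "V", "L")
.source_levels <- c("experimental", "asm", "episuite", "unknown")

#' Physical constants for the air-water partition conversion
#'
#' The dimensionless air-water partition coefficient is
#' `Kaw = HLC / (R * T)` with `R = 8.205e-5` m3 atm K-1 mol-1 and
#' `T = 298.15` K by default. No temperature correction is applied to
#' partition data measured at other temperatures; the conversion is
#' performed at the reference temperature throughout.
#'
#' @param gas_constant_R Molar gas constant, m3 atm K-1 mol-1.
#' @param temperature_T Absolute temperature, K.
#' @return A list with components `gas_constant_R`, `temperature_T`.
#' @export
#' @examples
#' physical_constants()$gas_constant_R * physical_constants()$temperature_T
physical_constants <- function(gas_constant_R = 8.205e-5,
                               temperature_T = 298.15) {
  stopifnot(is.numeric(gas_constant_R), length(gas_constant_R) == 1L,
            is.numeric(temperature_T), length(temperature_T) == 1L)
  if (gas_constant_R <= 0) stop("gas_constant_R must be > 0")
  if (temperature_T <= 0) stop("temperature_T must be > 0 (Kelvin)")
  list(gas_constant_R = gas_constant_R, temperature_T = temperature_T)
}

#' Convert a Henry's law constant to log10 Kaw
#'
#' `Kaw = HLC / (R T)`; this returns `log10(Kaw)`. Vectorised.
#'
#' @param hlc Henry's law constant(s), atm m3 mol-1; must be > 0.
#' @param constants See [physical_constants()].
#' @param record_id Optional identifier(s) used in error messages.
#' @return log10 of the dimensionless air-water partition coefficient.
#' @seealso [log_kaw_to_hlc()] for the inverse.
#' @export
#' @examples
#' hlc_to_log_kaw(2.44632e-4)  # ~ -2
hlc_to_log_kaw <- function(hlc, constants = physical_constants(),
                           record_id = NULL) {
  bad <- !is.na(hlc) & hlc <= 0
  if (any(bad)) {
    who <- if (is.null(record_id)) which(bad) else record_id[bad]
    stop("non-positive HLC for record(s): ", paste(who, collapse = ", "))
  }
  log10(hlc / (constants$gas_constant_R * constants$temperature_T))
}

#' Convert log10 Kaw back to a Henry's law constant
#'
#' Inverse of [hlc_to_log_kaw()]: `HLC = 10^log_kaw * R * T`
#' (atm m3 mol-1).
#'
#' @inheritParams hlc_to_log_kaw
#' @param log_kaw log10 air-water partition coefficient(s).
#' @export
log_kaw_to_hlc <- function(log_kaw, constants = physical_constants()) {
  10^log_kaw * constants$gas_constant_R * constants$temperature_T
}

# Empty record table with the canonical columns and types.
empty_chem_records <- function() {
  df <- data.frame(matrix(nrow = 0, ncol = length(chem_record_columns)))
  names(df) <- chem_record_columns
  for (cl in .numeric_cols) df[[cl]] <- numeric(0)
  for (cl in setdiff(chem_record_columns, .numeric_cols)) df[[cl]] <- character(0)
  df
}

#' Coerce and validate a chemical record table
#'
#' Ensures the canonical columns exist (absent optional columns are added
#' as all-`NA`), checks per-row invariants and splits the input into
#' accepted records and a rejection report. Invariants checked per row:
#' mutual consistency of `log_kaw` and `hlc_atm_m3_mol` under
#' `Kaw = HLC/(RT)` (within `kaw_tol` log units); Abraham solute
#' descriptors present either all six or none; HLC strictly positive.
#' A blank `log_kaw` with HLC present is auto-filled from the HLC.
#'
#' @param df Data frame carrying (a subset of) [chem_record_columns].
#' @param constants See [physical_constants()].
#' @param kaw_tol Consistency tolerance, log10 units.
#' @return List with `records` (accepted rows, canonical columns) and
#'   `rejected` (data frame: `row`, `record_id`, `reason`).
#' @export
validate_chem_records <- function(df, constants = physical_constants(),
                                  kaw_tol = 1e-6) {
  stopifnot(is.data.frame(df))
  for (cl in setdiff(chem_record_columns, names(df))) {
    df[[cl]] <- if (cl %in% .numeric_cols) NA_real_ else NA_character_
  }
  extra <- setdiff(names(df), chem_record_columns)
  df <- df[chem_record_columns]
  if (length(extra)) {
    # silently drop unknown columns; schema errors are for missing required ones
  }
  rej_row <- integer(0); rej_id <- character(0); rej_reason <- character(0)
  reject <- function(i, reason) {
    rej_row <<- c(rej_row, i)
    rej_id <<- c(rej_id, ifelse(is.na(df$record_id[i]), "", df$record_id[i]))
    rej_reason <<- c(rej_reason, reason)
  }
  n <- nrow(df)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    hlc <- df$hlc_atm_m3_mol[i]
    kaw <- df$log_kaw[i]
    if (!is.na(hlc) && hlc <= 0) {
      reject(i, "non-positive HLC"); keep[i] <- FALSE; next
    }
    if (!is.na(hlc) && !is.na(kaw)) {
      if (abs(kaw - hlc_to_log_kaw(hlc, constants)) > kaw_tol) {
        reject(i, "inconsistent HLC/K_aw"); keep[i] <- FALSE; next
      }
    }
    if (!is.na(hlc) && is.na(kaw)) {
      df$log_kaw[i] <- hlc_to_log_kaw(hlc, constants)
    }
    n_asd <- sum(!is.na(unlist(df[i, .asd_cols])))
    if (n_asd > 0 && n_asd < 6) {
      reject(i, "partial Abraham descriptor set (need all six or none)")
      keep[i] <- FALSE; next
    }
    for (src in c("source_kow", "source_kaw")) {
      v <- df[[src]][i]
      if (is.na(v) || !nzchar(v)) df[[src]][i] <- "unknown"
      else if (!v %in% .source_levels) {
        reject(i, paste0("invalid ", src, ": '", v, "'")); keep[i] <- FALSE
      }
    }
  }
  list(
    records = df[keep, , drop = FALSE],
    rejected = data.frame(row = rej_row, record_id = rej_id,
                          reason = rej_reason, stringsAsFactors = FALSE)
  )
}

#' Read chemical records from CSV
#'
#' Comma-separated, UTF-8, header row with canonical column names (see
#' [chem_record_columns]). `record_id` is required; every other column is
#' optional. Empty cells, `NA` and `NaN` are read as missing. Rows that
#' violate record invariants, or with unparseable numeric cells, are
#' collected into a rejection report rather than silently dropped; a
#' `log_kaw` left blank when HLC is present is auto-filled via
#' [hlc_to_log_kaw()].
#'
#' @param path CSV file path.
#' @param constants See [physical_constants()].
#' @param hlc_unit `"atm_m3_mol"` (default) or `"Pa_m3_mol"`; the latter
#'   is divided by 101325 on read.
#' @return List with `records` and `rejected`, as
#'   [validate_chem_records()].
#' @export
read_chem_records <- function(path, constants = physical_constants(),
                              hlc_unit = c("atm_m3_mol", "Pa_m3_mol")) {
  hlc_unit <- match.arg(hlc_unit)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA", "NaN"),
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!"record_id" %in% names(raw)) {
    stop("schema error: required column 'record_id' missing from ", path)
  }
  unknown <- setdiff(names(raw), chem_record_columns)
  if (length(unknown)) {
    stop("schema error: unknown column(s): ", paste(unknown, collapse = ", "))
  }
  rej_row <- integer(0); rej_id <- character(0); rej_reason <- character(0)
  keep <- rep(TRUE, nrow(raw))
  for (cl in intersect(.numeric_cols, names(raw))) {
    txt <- raw[[cl]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & is.na(num)
    if (any(bad)) {
      for (i in which(bad)) {
        rej_row <- c(rej_row, i)
        rej_id <- c(rej_id, ifelse(is.na(raw$record_id[i]), "", raw$record_id[i]))
        rej_reason <- c(rej_reason,
                        paste0("unparseable numeric cell in '", cl, "': '",
                               txt[i], "'"))
      }
      keep[bad] <- FALSE
    }
    raw[[cl]] <- num
  }
  raw <- raw[keep, , drop = FALSE]
  if ("hlc_atm_m3_mol" %in% names(raw) && hlc_unit == "Pa_m3_mol") {
    raw$hlc_atm_m3_mol <- raw$hlc_atm_m3_mol / 101325
  }
  out <- validate_chem_records(raw, constants = constants)
  parse_rej <- data.frame(row = rej_row, record_id = rej_id,
                          reason = rej_reason, stringsAsFactors = FALSE)
  out$rejected <- rbind(parse_rej, out$rejected)
  out
}

#' Write chemical records to CSV
#'
#' Canonical columns, empty cells for missing values, numeric fields at
#' 12 significant digits so that a write/read cycle reproduces the
#' records field-for-field.
#'
#' @param records Data frame of chemical records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chem_records <- function(records, path) {
  for (cl in setdiff(chem_record_columns, names(records))) {
    records[[cl]] <- if (cl %in% .numeric_cols) NA_real_ else NA_character_
  }
  records <- records[chem_record_columns]
  out <- records
  for (cl in .numeric_cols) {
    v <- records[[cl]]
    out[[cl]] <- ifelse(is.na(v), "", sprintf("%.12g", v))
  }
  for (cl in setdiff(chem_record_columns, .numeric_cols)) {
    out[[cl]] <- ifelse(is.na(records[[cl]]), "", records[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Ensure log_kaw is available, deriving it from HLC where needed.
# Internal helper used by prediction and fitting paths.
fill_log_kaw <- function(records, constants = physical_constants()) {
  if (!"log_kaw" %in% names(records)) records$log_kaw <- NA_real_
  if ("hlc_atm_m3_mol" %in% names(records)) {
    idx <- is.na(records$log_kaw) & !is.na(records$hlc_atm_m3_mol)
    if (any(idx)) {
      records$log_kaw[idx] <-
        hlc_to_log_kaw(records$hlc_atm_m3_mol[idx], constants)
    }
  }
  records
}
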