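# Ingestion of device-exported peripapillary RNFL sector thickness tables.
# One CSV row per eye: patient id, laterality, the six sector thicknesses
# and the global value G, all in micrometres. Devices report rounded
# values, so G is validated against the angle-weighted sector mean only up
# to a tolerance (check_g_consistency()).

OCT_COLUMNS <- c("patient_id", "laterality", "TS", "T", "TI",
                 "NS", "N", "NI", "G")

#' Read and validate an OCT sector thickness table
#'
#' Expects a UTF-8 CSV with header columns `patient_id, laterality, TS, T,
#' TI, NS, N, NI, G` (case-insensitive). Laterality tokens right/left/OD/OS
#' are normalized to right/left. Rows violating the physiological range
#' (thicknesses in (0, 300) um) are rejected with per-row diagnostics;
#' duplicate (patient, laterality) keys are an error.
#'
#' @param path CSV file path.
#' @return object of class `oct_table`: list with `table` (validated
#'   data.frame) and `rejected` (data.frame of row number + reason).
#' @export
read_oct_table <- function(path) {
  if (!file.exists(path)) stop("OCT table not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(raw) <- tolower(names(raw))
  need <- tolower(OCT_COLUMNS)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(toupper(missing_cols), collapse = ", "))
  }
  raw <- raw[need]
  names(raw) <- OCT_COLUMNS
  validate_oct_table(raw)
}

#' Validate an in-memory OCT sector table
#'
#' @param df data.frame with the columns of [read_oct_table()].
#' @return `oct_table` object (see [read_oct_table()]).
#' @export
validate_oct_table <- function(df) {
  stopifnot(all(OCT_COLUMNS %in% names(df)))
  df <- df[OCT_COLUMNS]
  df$laterality <- match_laterality(df$laterality)
  num_cols <- SECTORS_G
  bad <- data.frame(row = integer(), patient_id = character(),
                    reason = character())
  vals <- df[num_cols]
  not_num <- !vapply(vals, is.numeric, TRUE)
  if (any(not_num)) {
    suppressWarnings(vals[not_num] <- lapply(vals[not_num], as.numeric))
    df[num_cols] <- vals
  }
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- as.numeric(vals[i, ])
    if (any(is.na(v))) {
      bad <- rbind(bad, data.frame(row = i, patient_id = df$patient_id[i],
                                   reason = "non-numeric thickness"))
      keep[i] <- FALSE
    } else if (any(v <= 0 | v >= 300)) {
      bad <- rbind(bad, data.frame(row = i, patient_id = df$patient_id[i],
                                   reason = "out of physiological range"))
      keep[i] <- FALSE
    }
  }
  ok <- df[keep, , drop = FALSE]
  key <- paste(ok$patient_id, ok$laterality)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, laterality) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(ok) <- NULL
  structure(list(table = ok, rejected = bad), class = "oct_table")
}

#' @export
print.oct_table <- function(x, ...) {
  cat(sprintf("<oct_table %d validated rows, %d rejected>\n",
              nrow(x$table), nrow(x$rejected)))
  invisible(x)
}

#' Write an OCT sector table to CSV
#'
#' @param oct an `oct_table` or a data.frame in the same layout.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_oct_table <- function(oct, path) {
  df <- if (inherits(oct, "oct_table")) oct$table else oct
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check global-sector consistency of an OCT table
#'
#' Flags rows whose reported G differs from the angle-weighted mean of the
#' six sectors, (90 T + 45 TS + 45 NS + 90 N + 45 NI + 45 TI)/360, by more
#' than `tolerance` (relative). Report-only: devices round sector values.
#'
#' @param oct an `oct_table`.
#' @param tolerance relative tolerance (default 0.05).
#' @return data.frame with one row per table row: patient_id, laterality,
#'   reported G, weighted mean, relative deviation, flagged.
#' @export
check_g_consistency <- function(oct, tolerance = 0.05) {
  df <- if (inherits(oct, "oct_table")) oct$table else oct
  wm <- apply(df[SECTORS], 1, function(v) sector_global_mean(v))
  rel <- abs(df$G - wm) / pmax(wm, .Machine$double.eps)
  data.frame(patient_id = df$patient_id, laterality = df$laterality,
             G = df$G, weighted_mean = unname(wm), rel_dev = unname(rel),
             flagged = unname(rel > tolerance))
}

#' Convert one OCT table row to a sector profile
#'
#' @param row single-row data.frame from an `oct_table`.
#' @return a [sector_profile()] with modality `"OCT"`.
#' @export
oct_row_profile <- function(row) {
  sector_profile(unlist(row[SECTORS_G]), modality = "OCT",
                 laterality = row$laterality)
}
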