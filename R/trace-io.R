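# Plain-text I/O. Traces travel as TSV (one row per sample, "." decimal,
# UTF-8, header line) with a JSON sidecar (<path>.json) for protocol and
# plant annotations; coefficient tables travel as CSV.

TRACE_COLUMNS <- c("time_s", "fluorescence", "actinic_ppfd", "pulse_flag")

#' Write a fluorescence trace as TSV plus JSON sidecar
#'
#' Columns `time_s`, `fluorescence`, `actinic_ppfd`, `pulse_flag` (0/1),
#' written with 17 significant digits so that write-read round-trips are
#' exact. The sidecar `<path>.json` records `protocol_id` and any trace
#' metadata (plant_id, cytotype, photoperiod_h, seed).
#'
#' @param trace a [fluor_trace()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "fluor_trace")) {
    pk_stop("`trace` must be a fluor_trace", "pamkit_format_error")
  }
  df <- as.data.frame(trace)
  out <- data.frame(
    time_s = sprintf("%.17g", df$time_s),
    fluorescence = sprintf("%.17g", df$fluorescence),
    actinic_ppfd = sprintf("%.17g", df$actinic_ppfd),
    pulse_flag = as.integer(df$pulse_flag)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  sidecar <- c(list(protocol_id = trace_protocol_id(trace)),
               trace_meta(trace))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a fluorescence trace written by [write_trace()]
#'
#' Malformed input is rejected with a `pamkit_format_error` naming the first
#' offending line (1-based, counting the header); nothing is silently
#' coerced.
#'
#' @param path TSV path; `<path>.json` is read as sidecar when present.
#' @return A [fluor_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    pk_stop(sprintf("%s: file does not exist", path), "pamkit_io_error")
  }
  if (file.size(path) == 0) {
    pk_stop(sprintf("%s: empty file", path), "pamkit_format_error")
  }
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, colClasses = "numeric",
               fileEncoding = "UTF-8"),
    error = function(e) {
      pk_stop(sprintf("%s: cannot parse as trace TSV (%s)",
                      path, conditionMessage(e)), "pamkit_format_error")
    }
  )
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing_cols)) {
    pk_stop(sprintf("%s: missing column(s) %s", path,
                    paste(missing_cols, collapse = ", ")),
            "pamkit_format_error")
  }
  if (nrow(df) == 0L) {
    pk_stop(sprintf("%s: no data rows", path), "pamkit_format_error")
  }
  # +1 for the header so reported lines match the file as seen in an editor
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    pk_stop(sprintf("%s, line %d: time_s not strictly increasing",
                    path, bad[1] + 2L), "pamkit_format_error")
  }
  bad <- which(!is.finite(df$fluorescence) | df$fluorescence <= 0)
  if (length(bad)) {
    pk_stop(sprintf("%s, line %d: fluorescence must be > 0",
                    path, bad[1] + 1L), "pamkit_format_error")
  }
  bad <- which(df$actinic_ppfd < 0)
  if (length(bad)) {
    pk_stop(sprintf("%s, line %d: actinic_ppfd must be >= 0",
                    path, bad[1] + 1L), "pamkit_format_error")
  }
  if (!all(df$pulse_flag %in% c(0, 1))) {
    bad <- which(!df$pulse_flag %in% c(0, 1))
    pk_stop(sprintf("%s, line %d: pulse_flag must be 0 or 1",
                    path, bad[1] + 1L), "pamkit_format_error")
  }
  sidecar_path <- paste0(path, ".json")
  protocol_id <- "YIELD"
  meta <- list()
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    protocol_id <- sc$protocol_id %||% "YIELD"
    meta <- sc[setdiff(names(sc), "protocol_id")]
  }
  fluor_trace(df$time_s, df$fluorescence, df$actinic_ppfd,
              as.logical(df$pulse_flag), protocol_id, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Controlled vocabulary of coefficient names
#'
#' The coefficient names a [coefficient_table()] may contain: the yields
#' `phi_PSII` and `phi_max`, per-intensity `rETR@<ppfd>` entries, the
#' Kautsky quenching set (NPQ, qE, qI, qP, qL, PQ) and the JIP-test fluxes
#' (ABS/RC, TR0/RC, ET0/RC, DI0/RC, PI_ABS).
#'
#' @return Character vector of fixed names (the `rETR@` family is validated
#'   by pattern, not enumerated).
#' @export
coefficient_names <- function() {
  c("phi_PSII", "phi_max", "NPQ", "qE", "qI", "qP", "qL", "PQ",
    "ABS/RC", "TR0/RC", "ET0/RC", "DI0/RC", "PI_ABS")
}

is_valid_coefficient <- function(x) {
  x %in% coefficient_names() | grepl("^rETR@[0-9]+(\\.[0-9]+)?$", x)
}

CYTOTYPE_LEVELS <- c("2x", "4x", "6x_29", "6x_35")
PHOTOPERIOD_LEVELS <- c(10, 16.5)

#' Tidy per-plant coefficient table
#'
#' Long table with one row per (plant, coefficient): columns `plant_id`,
#' `cytotype` (2x, 4x, 6x_29, 6x_35), `photoperiod_h` (10 or 16.5),
#' `coefficient` (controlled vocabulary, see [coefficient_names()]) and
#' `value`.
#'
#' @param df data frame with the five columns above.
#' @return A tibble of class `coefficient_table`.
#' @export
coefficient_table <- function(df) {
  needed <- c("plant_id", "cytotype", "photoperiod_h", "coefficient", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    pk_stop(sprintf("coefficient table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "pamkit_validation_error")
  }
  df <- as_tibble(df[needed])
  df$plant_id <- as.character(df$plant_id)
  df$cytotype <- as.character(df$cytotype)
  df$coefficient <- as.character(df$coefficient)
  df$photoperiod_h <- as.numeric(df$photoperiod_h)
  df$value <- as.numeric(df$value)
  bad <- !df$cytotype %in% CYTOTYPE_LEVELS
  if (any(bad)) {
    pk_stop(sprintf("unknown cytotype '%s' (valid: %s)",
                    df$cytotype[which(bad)[1]],
                    paste(CYTOTYPE_LEVELS, collapse = ", ")),
            "pamkit_validation_error")
  }
  bad <- !df$photoperiod_h %in% PHOTOPERIOD_LEVELS
  if (any(bad)) {
    pk_stop(sprintf("unknown photoperiod_h %g (valid: %s)",
                    df$photoperiod_h[which(bad)[1]],
                    paste(PHOTOPERIOD_LEVELS, collapse = ", ")),
            "pamkit_validation_error")
  }
  bad <- !is_valid_coefficient(df$coefficient)
  if (any(bad)) {
    pk_stop(sprintf(
      "unknown coefficient '%s'; valid names: %s or rETR@<ppfd>",
      df$coefficient[which(bad)[1]],
      paste(coefficient_names(), collapse = ", ")),
      "pamkit_validation_error")
  }
  key <- paste(df$plant_id, df$coefficient, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    pk_stop(sprintf("duplicate (plant, coefficient) pair: (%s, %s)",
                    d$plant_id[1], d$coefficient[1]),
            "pamkit_validation_error")
  }
  class(df) <- c("coefficient_table", class(df))
  df
}

#' Read / write a coefficient table as CSV
#'
#' @param table a [coefficient_table()] (or coercible data frame).
#' @param path CSV path.
#' @return `write_coefficients` returns `path` invisibly;
#'   `read_coefficients` returns a validated [coefficient_table()].
#' @export
write_coefficients <- function(table, path) {
  table <- coefficient_table(table)
  df <- as.data.frame(table)
  df$value <- sprintf("%.17g", df$value)
  write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) {
    pk_stop(sprintf("%s: file does not exist", path), "pamkit_io_error")
  }
  if (file.size(path) == 0) {
    pk_stop(sprintf("%s: empty file", path), "pamkit_format_error")
  }
  df <- tryCatch(
    read.delim(path, sep = ",", header = TRUE, fileEncoding = "UTF-8",
               stringsAsFactors = FALSE),
    error = function(e) {
      pk_stop(sprintf("%s: cannot parse as CSV (%s)", path,
                      conditionMessage(e)), "pamkit_format_error")
    }
  )
  coefficient_table(df)
}
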