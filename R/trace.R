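#' Fluorescence trace container
#'
#' A time-resolved PAM fluorometry record: time since trace start (s),
#' fluorescence (arbitrary units, strictly positive), incident actinic light
#' (umol photons m-2 s-1) and a flag marking saturating/super-pulse windows.
#'
#' @param time_s strictly increasing numeric vector, seconds.
#' @param fluorescence numeric vector, a.u., all > 0.
#' @param actinic_ppfd numeric vector, >= 0.
#' @param pulse_flag logical vector.
#' @param protocol_id one of `"LC"`, `"KC"`, `"OJIP"`, `"YIELD"`.
#' @param meta optional named list carried along (plant_id, cytotype,
#'   photoperiod_h, seed); written to the JSON sidecar by [write_trace()].
#'
#' @return A data frame of class `fluor_trace` with the four columns above
#'   and attributes `protocol_id` and `meta`.
#' @export
fluor_trace <- function(time_s, fluorescence, actinic_ppfd, pulse_flag,
                        protocol_id, meta = list()) {
  n <- length(time_s)
  if (length(fluorescence) != n || length(actinic_ppfd) != n ||
      length(pulse_flag) != n) {
    pk_stop("trace columns must have equal length", "pamkit_format_error")
  }
  if (n == 0L) {
    pk_stop("trace must contain at least one sample", "pamkit_format_error")
  }
  bad_t <- which(diff(time_s) <= 0)
  if (length(bad_t)) {
    pk_stop(sprintf("time_s must be strictly increasing (violated at sample %d)",
                    bad_t[1] + 1L), "pamkit_format_error")
  }
  bad_f <- which(!is.finite(fluorescence) | fluorescence <= 0)
  if (length(bad_f)) {
    pk_stop(sprintf("fluorescence must be finite and > 0 (violated at sample %d)",
                    bad_f[1]), "pamkit_format_error")
  }
  if (any(actinic_ppfd < 0)) {
    pk_stop("actinic_ppfd must be >= 0", "pamkit_format_error")
  }
  if (!protocol_id %in% c("LC", "KC", "OJIP", "YIELD")) {
    pk_stop(sprintf("unknown protocol_id '%s'", protocol_id),
            "pamkit_format_error")
  }
  structure(
    data.frame(time_s = as.numeric(time_s),
               fluorescence = as.numeric(fluorescence),
               actinic_ppfd = as.numeric(actinic_ppfd),
               pulse_flag = as.logical(pulse_flag)),
    protocol_id = protocol_id, meta = meta,
    class = c("fluor_trace", "data.frame")
  )
}

#' @export
print.fluor_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<fluor_trace %s> %d samples, %.4g-%.4g s",
              attr(x, "protocol_id"), nrow(x), min(x$time_s), max(x$time_s)))
  if (!is.null(meta$plant_id)) cat(sprintf(", plant %s", meta$plant_id))
  cat("\n")
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("# ... %d more samples\n", nrow(x) - 4L))
  invisible(x)
}

#' Trace protocol and metadata accessors
#' @param trace a [fluor_trace()].
#' @return `trace_protocol_id()` the protocol identifier string;
#'   `trace_meta()` the metadata list.
#' @export
trace_protocol_id <- function(trace) attr(trace, "protocol_id")

#' @rdname trace_protocol_id
#' @export
trace_meta <- function(trace) attr(trace, "meta")
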