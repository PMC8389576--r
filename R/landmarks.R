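#' Saturating-pulse schedule within a phase
#'
#' Pulse onset times placed at `first_s`, then every `interval_s`, for as
#' long as they fall inside the phase. The default Kautsky protocol uses
#' (60, 7, 12) for the actinic phase — five pulses at 7, 19, 31, 43, 55 s —
#' and (88, 11, 26) for the dark recovery — three pulses at 11, 37, 63 s.
#'
#' @param phase_duration_s phase length in seconds, > 0.
#' @param first_s time of the first pulse after phase start (s), > 0.
#' @param interval_s spacing between subsequent pulses (s), > 0.
#' @return Numeric vector of pulse times (possibly empty), seconds from
#'   phase start.
#' @export
pulse_schedule <- function(phase_duration_s, first_s, interval_s) {
  check_number(phase_duration_s, "phase_duration_s", lower = 1e-12)
  check_number(first_s, "first_s", lower = 1e-12)
  check_number(interval_s, "interval_s", lower = 1e-12)
  if (first_s > phase_duration_s) return(numeric(0))
  seq(first_s, phase_duration_s, by = interval_s)
}

# Samples inside one expected pulse window; errors if the pulse is absent.
pulse_window_values <- function(trace, start_s, end_s) {
  sel <- trace$pulse_flag & trace$time_s >= start_s - 0.051 &
    trace$time_s <= end_s + 0.051
  if (!any(sel)) {
    pk_stop(sprintf("pulse at %g s not found in trace", start_s),
            "pamkit_extraction_error")
  }
  trace$fluorescence[sel]
}

# Median measuring-light fluorescence over [start_s - window, start_s).
pre_pulse_level <- function(trace, start_s, window_s = 0.5) {
  sel <- !trace$pulse_flag & trace$time_s < start_s &
    trace$time_s >= start_s - window_s
  if (!any(sel)) {
    pk_stop(sprintf("no measuring-light samples in the %g s before the pulse at %g s",
                    window_s, start_s), "pamkit_extraction_error")
  }
  median(trace$fluorescence[sel])
}

#' Extract Kautsky-curve landmarks
#'
#' From a KC trace and its protocol, extracts the named fluorescence levels:
#' dark-adapted `F0` (median of measuring-light samples before the initial
#' super pulse) and `FM` (maximum within the initial pulse window); per
#' actinic-phase pulse the quenched maximum `Fm_prime` (window maximum) and
#' the pre-pulse steady-state `Ft` (median over the 0.5 s before the pulse);
#' per dark-recovery pulse the relaxing maximum `Fm_dprime`; and `F0_dprime`,
#' the minimum measuring-light fluorescence in the dark recovery outside
#' pulse windows.
#'
#' @param trace a KC [fluor_trace()].
#' @param protocol the matching [protocol_spec()]; defaults to
#'   `default_protocol("KC")`.
#' @param pre_pulse_window_s window for the pre-pulse `Ft` median (s).
#' @return A list of class `kc_landmarks` with elements `F0`, `FM`,
#'   `Ft`, `Fm_prime` (vectors over actinic pulses), `Fm_dprime` (vector
#'   over dark pulses), `F0_dprime`, and the pulse times.
#' @export
extract_kc_landmarks <- function(trace, protocol = default_protocol("KC"),
                                 pre_pulse_window_s = 0.5) {
  if (!inherits(trace, "fluor_trace")) {
    pk_stop("`trace` must be a fluor_trace", "pamkit_extraction_error")
  }
  ph <- protocol$phases$name
  for (need in c("dark", "actinic", "dark_recovery")) {
    if (!need %in% ph || !length(protocol$pulses[[need]])) {
      pk_stop(sprintf("protocol lacks a '%s' phase with pulses", need),
              "pamkit_protocol_error")
    }
  }
  off <- setNames(phase_offsets(protocol), ph)
  w <- protocol$pulse_width_s

  dark_pulse <- off[["dark"]] + protocol$pulses$dark[1]
  light_pulses <- off[["actinic"]] + protocol$pulses$actinic
  dark_rec_pulses <- off[["dark_recovery"]] + protocol$pulses$dark_recovery

  F0 <- {
    sel <- !trace$pulse_flag & trace$time_s < dark_pulse &
      trace$actinic_ppfd == 0
    if (!any(sel)) {
      pk_stop("no dark measuring-light samples before the initial pulse",
              "pamkit_extraction_error")
    }
    median(trace$fluorescence[sel])
  }
  FM <- max(pulse_window_values(trace, dark_pulse, dark_pulse + w))
  Fm_prime <- vapply(light_pulses, function(p)
    max(pulse_window_values(trace, p, p + w)), numeric(1))
  Ft <- vapply(light_pulses, function(p)
    pre_pulse_level(trace, p, pre_pulse_window_s), numeric(1))
  Fm_dprime <- vapply(dark_rec_pulses, function(p)
    max(pulse_window_values(trace, p, p + w)), numeric(1))

  rec_start <- off[["dark_recovery"]]
  rec_end <- rec_start + protocol$phases$duration_s[match("dark_recovery", ph)]
  sel <- !trace$pulse_flag & trace$time_s >= rec_start &
    trace$time_s <= rec_end
  if (!any(sel)) {
    pk_stop("no measuring-light samples in the dark-recovery phase",
            "pamkit_extraction_error")
  }
  F0_dprime <- min(trace$fluorescence[sel])

  lm <- list(F0 = F0, FM = FM, Ft = Ft, Fm_prime = Fm_prime,
             Fm_dprime = Fm_dprime, F0_dprime = F0_dprime,
             light_pulse_times = light_pulses,
             dark_pulse_times = dark_rec_pulses)
  validate_kc_landmarks(lm)
  structure(lm, class = "kc_landmarks")
}

validate_kc_landmarks <- function(lm) {
  vals <- c(lm$F0, lm$FM, lm$Ft, lm$Fm_prime, lm$Fm_dprime, lm$F0_dprime)
  if (any(!is.finite(vals) | vals <= 0)) {
    pk_stop("all KC landmarks must be finite and > 0",
            "pamkit_extraction_error")
  }
  if (lm$FM < lm$F0) {
    pk_stop("FM < F0: sample shows no variable fluorescence",
            "pamkit_extraction_error")
  }
  invisible(lm)
}

#' Extract light-curve landmarks
#'
#' Dark-adapted `F0`/`FM` from the initial dark super pulse, then one
#' (`ppfd`, `Ft`, `Fm_prime`) triple per actinic step, with the same window
#' rules as [extract_kc_landmarks()].
#'
#' @inheritParams extract_kc_landmarks
#' @return A list of class `lc_landmarks`: `F0`, `FM` and a data frame
#'   `steps` with columns `ppfd`, `Ft`, `Fm_prime`.
#' @export
extract_lc_landmarks <- function(trace, protocol = default_protocol("LC"),
                                 pre_pulse_window_s = 0.5) {
  if (!inherits(trace, "fluor_trace")) {
    pk_stop("`trace` must be a fluor_trace", "pamkit_extraction_error")
  }
  ph <- protocol$phases$name
  if (!"dark" %in% ph || !length(protocol$pulses$dark)) {
    pk_stop("LC protocol lacks the initial dark pulse",
            "pamkit_protocol_error")
  }
  off <- setNames(phase_offsets(protocol), ph)
  w <- protocol$pulse_width_s
  dark_pulse <- off[["dark"]] + protocol$pulses$dark[1]

  sel <- !trace$pulse_flag & trace$time_s < dark_pulse &
    trace$actinic_ppfd == 0
  if (!any(sel)) {
    pk_stop("no dark measuring-light samples before the initial pulse",
            "pamkit_extraction_error")
  }
  F0 <- median(trace$fluorescence[sel])
  FM <- max(pulse_window_values(trace, dark_pulse, dark_pulse + w))

  step_idx <- grep("^step_", ph)
  steps <- do.call(rbind, lapply(step_idx, function(i) {
    p <- off[[ph[i]]] + protocol$pulses[[ph[i]]][1]
    data.frame(ppfd = protocol$phases$actinic_ppfd[i],
               Ft = pre_pulse_level(trace, p, pre_pulse_window_s),
               Fm_prime = max(pulse_window_values(trace, p, p + w)))
  }))
  structure(list(F0 = F0, FM = FM, steps = steps), class = "lc_landmarks")
}

#' Extract OJIP transient landmarks
#'
#' Reads the transient at the O, J, I and P time points by linear
#' interpolation in log-time. `FP` is taken as the maximum of the trace
#' (the transient peak), and `F300` (0.3 ms) is always extracted because
#' the initial-slope statistic M0 needs it.
#'
#' The J, I and P display points follow the usual 2, 30 and 1000 ms. For O
#' the default is 50 us, the common JIP-test origin; a 0.5 ms O point, as
#' some instruments report, can be requested via `timepoints_ms`. The two
#' choices give different FO on a rising transient and are never silently
#' interchanged.
#'
#' @param trace an OJIP [fluor_trace()].
#' @param timepoints_ms named numeric vector with entries `O`, `J`, `I`,
#'   `P`, in milliseconds.
#' @return A list of class `ojip_landmarks`: `FO`, `F300`, `FJ`, `FI`,
#'   `FP` and the `timepoints_ms` used.
#' @export
extract_ojip_landmarks <- function(trace,
                                   timepoints_ms = c(O = 0.05, J = 2,
                                                     I = 30, P = 1000)) {
  if (!inherits(trace, "fluor_trace")) {
    pk_stop("`trace` must be a fluor_trace", "pamkit_extraction_error")
  }
  if (!all(c("O", "J", "I", "P") %in% names(timepoints_ms))) {
    pk_stop("timepoints_ms must name O, J, I and P", "pamkit_extraction_error")
  }
  t_ms <- trace$time_s * 1000
  want <- c(timepoints_ms[c("O", "J", "I")], F300 = 0.3)
  out_of_span <- want < min(t_ms) | want > max(t_ms)
  if (any(out_of_span)) {
    pk_stop(sprintf("requested time point %g ms outside trace span [%g, %g] ms",
                    want[which(out_of_span)[1]], min(t_ms), max(t_ms)),
            "pamkit_extraction_error")
  }
  if (timepoints_ms[["P"]] > max(t_ms)) {
    pk_stop(sprintf("requested P point %g ms outside trace span (trace ends at %g ms)",
                    timepoints_ms[["P"]], max(t_ms)),
            "pamkit_extraction_error")
  }
  at <- function(tp) approx(log(t_ms), trace$fluorescence, xout = log(tp),
                            ties = "ordered")$y
  lm <- list(FO = at(want[["O"]]), F300 = at(want[["F300"]]),
             FJ = at(want[["J"]]), FI = at(want[["I"]]),
             FP = max(trace$fluorescence),
             timepoints_ms = timepoints_ms)
  vals <- unlist(lm[c("FO", "F300", "FJ", "FI", "FP")])
  if (any(!is.finite(vals) | vals <= 0)) {
    pk_stop("OJIP landmarks must be finite and > 0", "pamkit_extraction_error")
  }
  if (lm$FP < lm$FO) {
    pk_stop("FP < FO: transient is not rising", "pamkit_extraction_error")
  }
  structure(lm, class = "ojip_landmarks")
}

#' @export
print.kc_landmarks <- function(x, ...) {
  cat(sprintf("<kc_landmarks> F0=%.4g FM=%.4g F0''=%.4g\n",
              x$F0, x$FM, x$F0_dprime))
  cat("  actinic pulses: FM' =", sprintf("%.4g", x$Fm_prime), "\n")
  cat("  dark pulses:    FM''=", sprintf("%.4g", x$Fm_dprime), "\n")
  invisible(x)
}

#' @export
print.ojip_landmarks <- function(x, ...) {
  cat(sprintf("<ojip_landmarks> FO=%.4g F300=%.4g FJ=%.4g FI=%.4g FP=%.4g\n",
              x$FO, x$F300, x$FJ, x$FI, x$FP))
  invisible(x)
}
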