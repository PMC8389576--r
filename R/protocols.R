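#' Instrument protocol specification
#'
#' Describes one fluorometer measuring protocol as an ordered list of phases
#' (dark, actinic, dark recovery) with their actinic intensities and the
#' saturating-pulse times inside each phase. The defaults mirror a
#' FluorPen-class instrument: measuring light 0.09, saturating/super pulses
#' 2400, OJIP excitation 3000 and Kautsky actinic light
#' 300 umol photons m-2 s-1.
#'
#' @param protocol_id one of `"LC"`, `"KC"`, `"OJIP"`, `"YIELD"`.
#' @param phases data frame with columns `name` (one of dark, actinic,
#'   dark_recovery, pulse), `duration_s` and `actinic_ppfd`.
#' @param pulses list, one numeric vector of pulse onset times per phase,
#'   in seconds from the start of that phase.
#' @param measuring_ppfd,saturating_ppfd,ojip_pulse_ppfd,actinic_ppfd
#'   light intensities in umol photons m-2 s-1.
#' @param pulse_width_s saturating-pulse duration in seconds.
#' @param sample_dt_s sampling interval outside pulse windows (s).
#' @param pulse_dt_s sampling interval inside pulse windows (s).
#'
#' @return An object of class `protocol_spec`.
#' @seealso [default_protocol()] for the shipped LC/KC/OJIP protocols.
#' @export
protocol_spec <- function(protocol_id,
                          phases,
                          pulses = list(),
                          measuring_ppfd = 0.09,
                          saturating_ppfd = 2400,
                          ojip_pulse_ppfd = 3000,
                          actinic_ppfd = 300,
                          pulse_width_s = 0.8,
                          sample_dt_s = 0.1,
                          pulse_dt_s = 0.001) {
  if (!protocol_id %in% c("LC", "KC", "OJIP", "YIELD")) {
    pk_stop(sprintf("unknown protocol_id '%s'", protocol_id),
            "pamkit_protocol_error")
  }
  phases <- as.data.frame(phases)
  needed <- c("name", "duration_s", "actinic_ppfd")
  if (!all(needed %in% names(phases))) {
    pk_stop("`phases` needs columns name, duration_s, actinic_ppfd",
            "pamkit_protocol_error")
  }
  if (any(phases$duration_s <= 0)) {
    pk_stop("phase durations must be > 0", "pamkit_protocol_error")
  }
  if (any(phases$actinic_ppfd < 0) || measuring_ppfd < 0 ||
      saturating_ppfd < 0 || ojip_pulse_ppfd < 0 || actinic_ppfd < 0) {
    pk_stop("light intensities must be >= 0", "pamkit_protocol_error")
  }
  for (ph in names(pulses)) {
    i <- match(ph, phases$name)
    if (is.na(i)) {
      pk_stop(sprintf("pulses given for unknown phase '%s'", ph),
              "pamkit_protocol_error")
    }
    tms <- pulses[[ph]]
    if (length(tms) &&
        (any(tms < 0) || any(tms + pulse_width_s > phases$duration_s[i]))) {
      pk_stop(sprintf("pulse times in phase '%s' fall outside the phase", ph),
              "pamkit_protocol_error")
    }
  }
  structure(
    list(protocol_id = protocol_id, phases = phases, pulses = pulses,
         measuring_ppfd = measuring_ppfd, saturating_ppfd = saturating_ppfd,
         ojip_pulse_ppfd = ojip_pulse_ppfd, actinic_ppfd = actinic_ppfd,
         pulse_width_s = pulse_width_s, sample_dt_s = sample_dt_s,
         pulse_dt_s = pulse_dt_s),
    class = "protocol_spec"
  )
}

#' Shipped default protocols
#'
#' * `"KC"`: 10 s dark (one super pulse at 5 s), 60 s actinic at
#'   300 umol m-2 s-1 with five pulses (first at 7 s, then every 12 s),
#'   88 s dark recovery with three pulses (first at 11 s, then every 26 s).
#' * `"LC"`: 10 s dark with one super pulse, then one 20 s actinic phase per
#'   step of `lc_steps` with the pulse near the end of the step.
#' * `"OJIP"`: a single 2 s saturating red pulse at 3000 umol m-2 s-1,
#'   sampled log-uniformly from 10 us.
#'
#' @param protocol_id `"LC"`, `"KC"` or `"OJIP"`.
#' @param lc_steps actinic intensities for the light curve,
#'   umol photons m-2 s-1, non-decreasing.
#' @param lc_step_duration_s duration of each light-curve step (s).
#' @return A [protocol_spec()].
#' @export
default_protocol <- function(protocol_id = c("KC", "LC", "OJIP"),
                             lc_steps = c(10, 20, 50, 100, 300, 500),
                             lc_step_duration_s = 20) {
  protocol_id <- match.arg(protocol_id)
  switch(protocol_id,
    KC = protocol_spec(
      "KC",
      phases = data.frame(
        name = c("dark", "actinic", "dark_recovery"),
        duration_s = c(10, 60, 88),
        actinic_ppfd = c(0, 300, 0)
      ),
      pulses = list(
        dark = 5,
        actinic = pulse_schedule(60, 7, 12),
        dark_recovery = pulse_schedule(88, 11, 26)
      )
    ),
    LC = {
      if (length(lc_steps) == 0 || any(lc_steps < 0) ||
          is.unsorted(lc_steps)) {
        pk_stop("light-curve steps must be non-empty, non-negative and non-decreasing",
                "pamkit_protocol_error")
      }
      phases <- data.frame(
        name = c("dark", paste0("step_", seq_along(lc_steps))),
        duration_s = c(10, rep(lc_step_duration_s, length(lc_steps))),
        actinic_ppfd = c(0, lc_steps)
      )
      pulses <- c(list(dark = 5),
                  setNames(as.list(rep(lc_step_duration_s - 1.5,
                                       length(lc_steps))),
                           paste0("step_", seq_along(lc_steps))))
      protocol_spec("LC", phases = phases, pulses = pulses)
    },
    OJIP = protocol_spec(
      "OJIP",
      phases = data.frame(name = "pulse", duration_s = 2,
                          actinic_ppfd = 3000),
      pulses = list(pulse = 0),
      pulse_width_s = 2
    )
  )
}

# Absolute start time of each phase within the trace.
phase_offsets <- function(protocol) {
  c(0, cumsum(protocol$phases$duration_s))[seq_len(nrow(protocol$phases))]
}

# All pulse windows as a data.frame(phase, start_s, end_s), absolute times.
pulse_windows <- function(protocol) {
  off <- phase_offsets(protocol)
  out <- list()
  for (i in seq_len(nrow(protocol$phases))) {
    ph <- protocol$phases$name[i]
    tms <- protocol$pulses[[ph]]
    if (length(tms)) {
      out[[length(out) + 1L]] <- data.frame(
        phase = ph, start_s = off[i] + tms,
        end_s = off[i] + tms + protocol$pulse_width_s
      )
    }
  }
  if (!length(out)) {
    return(data.frame(phase = character(), start_s = numeric(),
                      end_s = numeric()))
  }
  do.call(rbind, out)
}

#' Write / read a protocol as JSON
#'
#' @param protocol a [protocol_spec()].
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a [protocol_spec()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_spec"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    pk_stop(sprintf("protocol file '%s' does not exist", path),
            "pamkit_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol_spec(
    protocol_id = x$protocol_id,
    phases = x$phases,
    pulses = as.list(x$pulses),
    measuring_ppfd = x$measuring_ppfd,
    saturating_ppfd = x$saturating_ppfd,
    ojip_pulse_ppfd = x$ojip_pulse_ppfd,
    actinic_ppfd = x$actinic_ppfd,
    pulse_width_s = x$pulse_width_s,
    sample_dt_s = x$sample_dt_s,
    pulse_dt_s = x$pulse_dt_s
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec %s>\n", x$protocol_id))
  for (i in seq_len(nrow(x$phases))) {
    ph <- x$phases$name[i]
    tms <- x$pulses[[ph]]
    cat(sprintf("  %-14s %6.1f s  actinic %g  pulses: %s\n",
                ph, x$phases$duration_s[i], x$phases$actinic_ppfd[i],
                if (length(tms)) paste(tms, collapse = ", ") else "-"))
  }
  invisible(x)
}
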