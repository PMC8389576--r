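#' JIP-test specific energy fluxes and performance index
#'
#' From the OJIP landmarks the standard JIP-test chain is computed:
#' \deqn{F_V = F_P - F_O, \quad \varphi_{P0} = F_V/F_P, \quad
#'       V_J = (F_J - F_O)/F_V, \quad \psi_0 = 1 - V_J,}
#' \deqn{M_0 = 4 (F_{300} - F_O)/F_V \; [\mathrm{ms}^{-1}],}
#' \deqn{TR_0/RC = M_0/V_J, \quad ABS/RC = (TR_0/RC)/\varphi_{P0}, \quad
#'       ET_0/RC = (TR_0/RC)\,\psi_0, \quad DI_0/RC = ABS/RC - TR_0/RC,}
#' \deqn{PI_{ABS} = \frac{\varphi_{P0} V_J}{M_0}\cdot
#'       \frac{\varphi_{P0}}{1-\varphi_{P0}}\cdot\frac{\psi_0}{1-\psi_0}.}
#' All quantities are ratios of fluorescence levels, hence invariant under
#' rescaling of the signal, and the flux balance
#' ABS/RC = TR0/RC + DI0/RC holds to machine precision by construction.
#' M0 always uses the 0.3 ms sample, whatever O/J/I/P display points were
#' requested at extraction. FI is carried through for completeness but
#' enters no flux formula.
#'
#' @param landmarks an `ojip_landmarks` object from
#'   [extract_ojip_landmarks()], or a list with `FO`, `F300`, `FJ`, `FP`
#'   (and optionally `FI`).
#' @return A list of class `jip_coefficients` with `FV`, `phi_P0`, `VJ`,
#'   `psi_0`, `M0`, `ABS_RC`, `TR0_RC`, `ET0_RC`, `DI0_RC`, `PI_ABS`.
#' @export
jip_coefficients <- function(landmarks) {
  need <- c("FO", "F300", "FJ", "FP")
  if (!all(need %in% names(landmarks))) {
    pk_stop(sprintf("landmarks must provide %s", paste(need, collapse = ", ")),
            "pamkit_validation_error")
  }
  FO <- landmarks$FO; F300 <- landmarks$F300
  FJ <- landmarks$FJ; FP <- landmarks$FP
  for (v in need) check_number(landmarks[[v]], v,
                               lower = .Machine$double.xmin)
  if (FP <= FO) {
    pk_stop(sprintf("FP (%g) must exceed FO (%g)", FP, FO),
            "pamkit_validation_error")
  }
  if (F300 < FO || F300 > FP) {
    pk_stop(sprintf("F300 (%g) must lie between FO (%g) and FP (%g)",
                    F300, FO, FP), "pamkit_validation_error")
  }
  FV <- FP - FO
  phi_P0 <- FV / FP
  VJ <- (FJ - FO) / FV
  if (VJ <= 0 || VJ >= 1) {
    pk_stop(sprintf("degenerate transient: VJ = %g must lie strictly in (0, 1)",
                    VJ), "pamkit_degenerate_transient")
  }
  psi_0 <- 1 - VJ
  M0 <- 4 * (F300 - FO) / FV
  if (M0 <= 0) {
    pk_stop("degenerate transient: M0 <= 0 (no initial rise at 0.3 ms)",
            "pamkit_degenerate_transient")
  }
  TR0_RC <- M0 / VJ
  ABS_RC <- TR0_RC / phi_P0
  ET0_RC <- TR0_RC * psi_0
  DI0_RC <- ABS_RC - TR0_RC
  PI_ABS <- (phi_P0 * VJ / M0) * (phi_P0 / (1 - phi_P0)) * (psi_0 / (1 - psi_0))
  structure(
    list(FV = FV, phi_P0 = phi_P0, VJ = VJ, psi_0 = psi_0, M0 = M0,
         ABS_RC = ABS_RC, TR0_RC = TR0_RC, ET0_RC = ET0_RC,
         DI0_RC = DI0_RC, PI_ABS = PI_ABS,
         FI = landmarks$FI %||% NA_real_),
    class = "jip_coefficients"
  )
}

#' @export
print.jip_coefficients <- function(x, ...) {
  cat("<jip_coefficients>\n")
  v <- unlist(x[c("phi_P0", "VJ", "M0", "ABS_RC", "TR0_RC", "ET0_RC",
                  "DI0_RC", "PI_ABS")])
  names(v) <- c("phi_P0", "VJ", "M0", "ABS/RC", "TR0/RC", "ET0/RC",
                "DI0/RC", "PI_ABS")
  print(round(v, 4))
  invisible(x)
}

#' Batch JIP analysis of OJIP traces
#'
#' Extracts landmarks and computes JIP coefficients for every trace,
#' assembling tidy [coefficient_table()] rows. Failing plants are collected
#' and reported, never silently dropped: when any trace fails, the result
#' carries an attribute `failures` (plant_id + message) and a warning is
#' raised; an error is thrown only if every trace fails.
#'
#' @param traces named list of OJIP [fluor_trace()] objects; names (or
#'   trace metadata) supply `plant_id`, and metadata must carry `cytotype`
#'   and `photoperiod_h`.
#' @param timepoints_ms passed to [extract_ojip_landmarks()].
#' @param coefficients which JIP coefficients to report as rows.
#' @return A [coefficient_table()] (rows: plant x coefficient), with
#'   attribute `failures`, a data frame of failed plant ids and messages.
#' @export
jip_batch <- function(traces,
                      timepoints_ms = c(O = 0.05, J = 2, I = 30, P = 1000),
                      coefficients = c("ABS/RC", "TR0/RC", "ET0/RC",
                                       "DI0/RC", "PI_ABS")) {
  if (!length(traces)) {
    pk_stop("no traces supplied", "pamkit_validation_error")
  }
  rows <- list()
  failures <- list()
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    meta <- trace_meta(tr)
    pid <- meta$plant_id %||% names(traces)[k] %||% as.character(k)
    res <- tryCatch({
      jc <- jip_coefficients(extract_ojip_landmarks(tr, timepoints_ms))
      vals <- c("ABS/RC" = jc$ABS_RC, "TR0/RC" = jc$TR0_RC,
                "ET0/RC" = jc$ET0_RC, "DI0/RC" = jc$DI0_RC,
                "PI_ABS" = jc$PI_ABS, "phi_max" = jc$phi_P0)
      tibble(plant_id = pid, cytotype = meta$cytotype,
             photoperiod_h = meta$photoperiod_h,
             coefficient = coefficients,
             value = unname(vals[coefficients]))
    }, pamkit_error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(plant_id = pid, message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  fail_df <- if (length(failures)) do.call(rbind, failures)
             else data.frame(plant_id = character(), message = character())
  if (!length(rows)) {
    pk_stop(sprintf("all %d traces failed JIP analysis (first: %s)",
                    length(traces), fail_df$message[1]),
            "pamkit_extraction_error")
  }
  if (nrow(fail_df)) {
    pk_warn(sprintf("JIP analysis failed for %d plant(s): %s",
                    nrow(fail_df), paste(fail_df$plant_id, collapse = ", ")),
            "pamkit_batch_failures")
  }
  out <- coefficient_table(do.call(rbind, rows))
  attr(out, "failures") <- fail_df
  out
}
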