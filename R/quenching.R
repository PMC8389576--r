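#' Non-photochemical quenching and its components
#'
#' Stern-Volmer non-photochemical quenching NPQ = (FM - FM') / FM'.
#' Its slow, photoinhibitory component `qi()` is the quenching still present
#' at the last dark-recovery pulse, qI = (FM - FM'') / FM''; the fast,
#' energy-dependent component is the remainder, qE = NPQ - qI, so that
#' NPQ = qE + qI holds exactly by construction.
#'
#' @param FM dark-adapted maximal fluorescence, a.u., > 0.
#' @param FMp light-adapted maximal fluorescence FM', a.u., > 0.
#' @return Numeric scalar. A negative NPQ (FM' > FM, possible in noisy
#'   traces) is retained with a warning rather than clipped.
#' @export
npq <- function(FM, FMp) {
  check_number(FM, "FM", lower = .Machine$double.xmin)
  check_number(FMp, "FMp", lower = .Machine$double.xmin)
  out <- (FM - FMp) / FMp
  if (out < 0) {
    pk_warn(sprintf("FM' (%g) exceeds FM (%g): negative NPQ retained",
                    FMp, FM), "pamkit_negative_quenching")
  }
  out
}

#' @rdname npq
#' @param FMpp maximal fluorescence FM'' at the last dark-recovery pulse.
#' @export
qi <- function(FM, FMpp) {
  check_number(FM, "FM", lower = .Machine$double.xmin)
  check_number(FMpp, "FMpp", lower = .Machine$double.xmin)
  out <- (FM - FMpp) / FMpp
  if (out < 0) {
    pk_warn(sprintf("FM'' (%g) exceeds FM (%g): negative qI retained",
                    FMpp, FM), "pamkit_negative_quenching")
  }
  out
}

#' @rdname npq
#' @param NPQ total non-photochemical quenching from [npq()].
#' @param qI photoinhibitory component from [qi()].
#' @export
qe <- function(NPQ, qI) {
  check_number(NPQ, "NPQ")
  check_number(qI, "qI")
  out <- NPQ - qI
  if (out < 0) {
    pk_warn(sprintf("qI (%g) exceeds NPQ (%g): negative qE retained (incomplete relaxation model)",
                    qI, NPQ), "pamkit_negative_quenching")
  }
  out
}

#' Minimal fluorescence in the light, F0'
#'
#' The standard estimator for the light-adapted minimal fluorescence when it
#' is not measured directly:
#' F0' = F0 / (Fv/Fm + F0/FM'). When FM' = FM this reduces to F0, and it
#' decreases monotonically as FM' is quenched below FM.
#'
#' @param F0,FM dark-adapted minimal and maximal fluorescence, `FM > F0 > 0`.
#' @param FMp light-adapted maximal fluorescence FM', > 0.
#' @return F0' in the same arbitrary units.
#' @export
f0_prime <- function(F0, FM, FMp) {
  check_number(F0, "F0", lower = .Machine$double.xmin)
  check_number(FM, "FM", lower = .Machine$double.xmin)
  check_number(FMp, "FMp", lower = .Machine$double.xmin)
  if (FM <= F0) {
    pk_stop(sprintf("FM (%g) must exceed F0 (%g)", FM, F0),
            "pamkit_validation_error")
  }
  denom <- (FM - F0) / FM + F0 / FMp
  if (denom <= 0) {
    pk_stop("F0' estimator denominator <= 0", "pamkit_numerical_error")
  }
  F0 / denom
}

#' Photochemical quenching coefficients
#'
#' `qp()` estimates the fraction of open PSII centers under the "puddle"
#' antenna model, qP = (FM' - F(t)) / (FM' - F0'); `ql()` the "lake" model
#' version, qL = qP x F0'/F(t). Whenever F0' <= F(t), qL <= qP.
#'
#' @param Ft pre-pulse steady-state fluorescence, a.u., > 0.
#' @param FMp light-adapted maximal fluorescence FM', a.u.
#' @param F0p estimated minimal fluorescence in light, see [f0_prime()].
#' @return Numeric scalar.
#' @export
qp <- function(Ft, FMp, F0p) {
  check_number(Ft, "Ft", lower = .Machine$double.xmin)
  check_number(FMp, "FMp", lower = .Machine$double.xmin)
  check_number(F0p, "F0p", lower = .Machine$double.xmin)
  if (FMp <= F0p) {
    pk_stop(sprintf("FM' (%g) must exceed F0' (%g): degenerate landmarks",
                    FMp, F0p), "pamkit_validation_error")
  }
  (FMp - Ft) / (FMp - F0p)
}

#' @rdname qp
#' @param qP value from [qp()].
#' @export
ql <- function(qP, F0p, Ft) {
  check_number(qP, "qP")
  check_number(F0p, "F0p", lower = .Machine$double.xmin)
  check_number(Ft, "Ft", lower = .Machine$double.xmin)
  qP * F0p / Ft
}

#' Photochemical quenching summary coefficient PQ
#'
#' Reported as the closed-center fraction PQ = 1 - qP by default, so that
#' lower values indicate more open centers, i.e. higher photochemical
#' efficiency. The convention is configurable and always recorded in the
#' result metadata; no other biological reading is implied.
#'
#' @param qP photochemical quenching coefficient in [0, 1].
#' @param convention `"one_minus_qP"` (default) or `"qP"` (pass-through).
#' @return Numeric scalar with attribute `convention`.
#' @export
pq_coefficient <- function(qP, convention = c("one_minus_qP", "qP")) {
  convention <- match.arg(convention)
  check_number(qP, "qP", lower = 0, upper = 1)
  val <- switch(convention, one_minus_qP = 1 - qP, qP = qP)
  structure(val, convention = convention)
}

#' Quenching coefficients from Kautsky-curve landmarks
#'
#' Computes the full quenching set from a `kc_landmarks` object. The
#' steady-state light-phase values (NPQ, qE, qP, qL, PQ and F0') are taken
#' at the last actinic-phase pulse — at 55 s of the 60 s induction, the
#' closest the protocol comes to steady state — and qI at the last
#' dark-recovery pulse (63 s into relaxation). Both pulse choices are
#' configurable. NPQ = qE + qI holds exactly by construction.
#'
#' @param landmarks a `kc_landmarks` object from [extract_kc_landmarks()].
#' @param pulse_index index of the actinic-phase pulse used for the
#'   steady-state coefficients; default the last.
#' @param dark_pulse_index index of the dark-recovery pulse used for qI;
#'   default the last.
#' @param pq_convention see [pq_coefficient()].
#' @return A list of class `quenching_coefficients`: `NPQ`, `qE`, `qI`,
#'   `qP`, `qL`, `PQ`, `F0_prime`, `phi_max`, `phi_PSII`, plus a
#'   `conventions` record.
#' @export
kc_coefficients <- function(landmarks, pulse_index = NULL,
                            dark_pulse_index = NULL,
                            pq_convention = "one_minus_qP") {
  if (!inherits(landmarks, "kc_landmarks")) {
    pk_stop("`landmarks` must be a kc_landmarks object",
            "pamkit_validation_error")
  }
  i <- pulse_index %||% length(landmarks$Fm_prime)
  j <- dark_pulse_index %||% length(landmarks$Fm_dprime)
  if (i < 1 || i > length(landmarks$Fm_prime)) {
    pk_stop(sprintf("pulse_index %d out of range", i),
            "pamkit_validation_error")
  }
  if (j < 1 || j > length(landmarks$Fm_dprime)) {
    pk_stop(sprintf("dark_pulse_index %d out of range", j),
            "pamkit_validation_error")
  }
  F0 <- landmarks$F0; FM <- landmarks$FM
  Ft <- landmarks$Ft[i]; FMp <- landmarks$Fm_prime[i]
  FMpp <- landmarks$Fm_dprime[j]

  NPQ <- npq(FM, FMp)
  qI <- qi(FM, FMpp)
  qE <- qe(NPQ, qI)
  F0p <- f0_prime(F0, FM, FMp)
  qP <- qp(Ft, FMp, F0p)
  qL <- ql(qP, F0p, Ft)
  PQ <- pq_coefficient(min(max(qP, 0), 1), pq_convention)

  structure(
    list(NPQ = NPQ, qE = qE, qI = qI, qP = qP, qL = qL,
         PQ = as.numeric(PQ), F0_prime = F0p,
         phi_max = phi_max(F0, FM),
         phi_PSII = phi_psii(Ft, FMp),
         conventions = list(
           pq = attr(PQ, "convention"),
           steady_state_pulse = i, dark_pulse = j,
           f0_prime = "F0 / (Fv/Fm + F0/FM')")),
    class = "quenching_coefficients"
  )
}

#' @export
print.quenching_coefficients <- function(x, ...) {
  cat("<quenching_coefficients>\n")
  v <- unlist(x[c("NPQ", "qE", "qI", "qP", "qL", "PQ", "F0_prime",
                  "phi_max", "phi_PSII")])
  print(round(v, 4))
  invisible(x)
}
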