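#' PSII quantum yields
#'
#' `phi_psii()` is the effective (light-adapted) PSII quantum yield
#' (FM' - F(t)) / FM'; `phi_max()` the dark-adapted maximum quantum yield
#' Fv/Fm = (FM - F0) / FM. Both are dimensionless ratios, invariant under
#' rescaling of the fluorescence signal.
#'
#' @param Ft steady-state fluorescence just before the pulse, a.u., > 0.
#' @param FMp light-adapted maximal fluorescence FM' from the pulse, a.u.
#' @return The yield (numeric scalar). `phi_psii()` warns and keeps the
#'   negative value when `Ft > FMp` (possible in noisy data); clipping
#'   would bias group means.
#' @export
phi_psii <- function(Ft, FMp) {
  check_number(FMp, "FMp", lower = .Machine$double.xmin)
  check_number(Ft, "Ft", lower = .Machine$double.xmin)
  phi <- (FMp - Ft) / FMp
  if (phi < 0) {
    pk_warn(sprintf("Ft (%g) exceeds FM' (%g): negative phi_PSII retained",
                    Ft, FMp), "pamkit_negative_yield")
  }
  phi
}

#' @rdname phi_psii
#' @param F0 dark-adapted minimal fluorescence, a.u., with `FM > F0 > 0`.
#' @param FM dark-adapted maximal fluorescence, a.u.
#' @export
phi_max <- function(F0, FM) {
  check_number(F0, "F0", lower = .Machine$double.xmin)
  check_number(FM, "FM", lower = .Machine$double.xmin)
  if (FM <= F0) {
    pk_stop(sprintf("FM (%g) must exceed F0 (%g): sample is not inductive",
                    FM, F0), "pamkit_validation_error")
  }
  (FM - F0) / FM
}

#' Daily light integral
#'
#' Total photosynthetic photon dose per day:
#' DLI = PPFD x photoperiod x 3600 x 1e-6 (mol photons m-2 d-1). At the
#' growth irradiance of 250 umol m-2 s-1 this gives 9.0 for a 10 h and
#' 14.85 (printed 14.8 at one decimal) for a 16.5 h photoperiod.
#'
#' @param ppfd photosynthetic photon flux density, umol photons m-2 s-1.
#' @param photoperiod_h daily light phase duration, hours, in [0, 24].
#' @return A list of class `daily_light_integral` with `dli`, `ppfd`,
#'   `photoperiod_h`.
#' @export
daily_light_integral <- function(ppfd, photoperiod_h) {
  check_number(ppfd, "ppfd", lower = 0)
  check_number(photoperiod_h, "photoperiod_h", lower = 0, upper = 24)
  structure(list(dli = ppfd * photoperiod_h * 3600 * 1e-6,
                 ppfd = ppfd, photoperiod_h = photoperiod_h),
            class = "daily_light_integral")
}

#' @export
print.daily_light_integral <- function(x, ...) {
  cat(sprintf("DLI = %.2f mol photons m-2 d-1 (%g umol m-2 s-1 x %g h)\n",
              x$dli, x$ppfd, x$photoperiod_h))
  invisible(x)
}

#' Relative electron transport rate
#'
#' rETR = etr_factor x phi_PSII x PPFD. "Relative" because neither leaf
#' absorptance nor its spectral quality enters; the default
#' `etr_factor = 0.5` assumes excitation is split evenly between the two
#' photosystems.
#'
#' @param phi_psii effective PSII yield at this intensity, in [0, 1].
#' @param ppfd actinic intensity, umol photons m-2 s-1, >= 0.
#' @param etr_factor photosystem partition factor, > 0.
#' @return A one-row tibble (`ppfd`, `phi_psii`, `rETR`): one light-curve
#'   point.
#' @export
retr <- function(phi_psii, ppfd, etr_factor = 0.5) {
  check_number(phi_psii, "phi_psii", lower = 0, upper = 1)
  check_number(ppfd, "ppfd", lower = 0)
  check_number(etr_factor, "etr_factor", lower = .Machine$double.xmin)
  tibble(ppfd = ppfd, phi_psii = phi_psii,
         rETR = etr_factor * phi_psii * ppfd)
}

#' Light curve from per-step landmarks
#'
#' Turns the (Ft, FM') pair of every actinic step into a
#' (ppfd, phi_PSII, rETR) point, in step order.
#'
#' @param landmarks an `lc_landmarks` object from [extract_lc_landmarks()],
#'   or a data frame with columns `ppfd`, `Ft`, `Fm_prime`.
#' @param etr_factor see [retr()].
#' @return A tibble with one row per step: `ppfd`, `phi_psii`, `rETR`.
#' @export
light_curve <- function(landmarks, etr_factor = 0.5) {
  steps <- if (inherits(landmarks, "lc_landmarks")) landmarks$steps
           else as.data.frame(landmarks)
  if (!all(c("ppfd", "Ft", "Fm_prime") %in% names(steps))) {
    pk_stop("light_curve needs per-step columns ppfd, Ft, Fm_prime",
            "pamkit_validation_error")
  }
  if (nrow(steps) == 0L) {
    pk_stop("no light-curve steps supplied", "pamkit_validation_error")
  }
  phi <- vapply(seq_len(nrow(steps)), function(i)
    phi_psii(steps$Ft[i], steps$Fm_prime[i]), numeric(1))
  # rETR keeps the sign of a (rare, noisy) negative yield; clipping biases
  tibble(ppfd = steps$ppfd, phi_psii = phi,
         rETR = etr_factor * phi * steps$ppfd)
}

#' Saturating light-response fit
#'
#' Fits the exponential saturation model
#' rETR(I) = rETR_max (1 - exp(-alpha I / rETR_max)) to light-curve points
#' by nonlinear least squares, returning the plateau `retr_max` and initial
#' slope `alpha`. Used to verify that simulated light curves recover their
#' generating parameters; not a coefficient of the group analysis.
#'
#' @param points tibble from [light_curve()] (columns `ppfd`, `rETR`).
#' @return list with `retr_max` and `alpha`.
#' @export
fit_light_curve <- function(points) {
  df <- as.data.frame(points)
  if (nrow(df) < 3) {
    pk_stop("need at least 3 light-curve points to fit",
            "pamkit_validation_error")
  }
  start <- list(retr_max = max(df$rETR) * 1.2,
                alpha = df$rETR[1] / max(df$ppfd[1], 1e-9))
  fit <- tryCatch(
    nls(rETR ~ retr_max * (1 - exp(-alpha * ppfd / retr_max)),
        data = df, start = start,
        # scaleOffset keeps the convergence test meaningful on noise-free
        # (zero-residual) data
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      pk_stop(sprintf("light-curve fit failed: %s", conditionMessage(e)),
              "pamkit_numerical_error")
    }
  )
  as.list(coef(fit))
}
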