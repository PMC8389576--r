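#' Simulation parameters for a factorial PAM study
#'
#' Bundles the per-group ground-truth physiology with instrument-level
#' settings for simulating a cytotype x photoperiod experiment. Each row of
#' `groups` describes one of the eight cells (cytotypes 2x, 4x, 6x_29,
#' 6x_35 crossed with 10 h and 16.5 h photoperiods):
#'
#' \describe{
#'   \item{phi_max_true}{dark-adapted maximum PSII yield, in (0, 1).}
#'   \item{npq_ss}{steady-state NPQ reached under the Kautsky actinic
#'     phase, >= 0.}
#'   \item{qi_frac}{fraction of npq_ss that does not relax in darkness
#'     (the photoinhibitory part), in [0, 1].}
#'   \item{closed_frac_ss}{steady-state fraction of closed PSII centers
#'     under actinic light, in [0, 1].}
#'   \item{retr_max}{light-curve rETR plateau, >= 0.}
#'   \item{alpha_lc}{initial light-curve slope; must satisfy
#'     `alpha_lc <= etr_factor * phi_max_true` so the low-light yield limit
#'     equals phi_max_true.}
#'   \item{tau1_ms, tau2_ms, tau3_ms}{OJIP rise time constants, strictly
#'     increasing, ms.}
#'   \item{w1, w2, w3}{non-negative OJIP phase weights summing to 1.}
#' }
#'
#' @param groups data frame with columns `cytotype`, `photoperiod_h` and
#'   the ground-truth columns above, one row per cell.
#' @param f0_base dark-adapted minimal fluorescence, a.u., > 0.
#' @param noise_cv multiplicative measurement noise, coefficient of
#'   variation, >= 0.
#' @param n_per_cell plants per cell: a single integer or a named vector
#'   keyed `"<cytotype>:<photoperiod_h>"`.
#' @param seed integer RNG seed for the whole study.
#' @param tau_npq_s NPQ induction/relaxation time constant (s).
#' @param tau_closed_s closed-fraction time constant (s).
#' @param etr_factor photosystem partition factor used by the light-curve
#'   model (and by the matching analysis), > 0.
#' @return A list of class `sim_params`.
#' @seealso [default_sim_params()] for the shipped preset.
#' @export
sim_params <- function(groups, f0_base = 500, noise_cv = 0.02,
                       n_per_cell = 8, seed = 1,
                       tau_npq_s = 10, tau_closed_s = 3,
                       etr_factor = 0.5) {
  groups <- as.data.frame(groups)
  need <- c("cytotype", "photoperiod_h", "phi_max_true", "npq_ss",
            "qi_frac", "closed_frac_ss", "retr_max", "alpha_lc",
            "tau1_ms", "tau2_ms", "tau3_ms", "w1", "w2", "w3")
  missing_cols <- setdiff(need, names(groups))
  if (length(missing_cols)) {
    pk_stop(sprintf("groups missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "pamkit_param_error")
  }
  if (any(!groups$cytotype %in% CYTOTYPE_LEVELS) ||
      any(!groups$photoperiod_h %in% PHOTOPERIOD_LEVELS)) {
    pk_stop("groups cytotype/photoperiod_h outside the enumerated levels",
            "pamkit_param_error")
  }
  if (any(groups$phi_max_true <= 0 | groups$phi_max_true >= 1)) {
    pk_stop("phi_max_true must lie strictly in (0, 1)", "pamkit_param_error")
  }
  if (any(groups$npq_ss < 0) || any(groups$retr_max < 0) ||
      any(groups$alpha_lc < 0)) {
    pk_stop("npq_ss, retr_max and alpha_lc must be >= 0",
            "pamkit_param_error")
  }
  if (any(groups$qi_frac < 0 | groups$qi_frac > 1) ||
      any(groups$closed_frac_ss < 0 | groups$closed_frac_ss > 1)) {
    pk_stop("qi_frac and closed_frac_ss must lie in [0, 1]",
            "pamkit_param_error")
  }
  if (any(groups$alpha_lc > etr_factor * groups$phi_max_true + 1e-9)) {
    pk_stop("alpha_lc must not exceed etr_factor * phi_max_true (low-light yield limit)",
            "pamkit_param_error")
  }
  taus <- as.matrix(groups[, c("tau1_ms", "tau2_ms", "tau3_ms")])
  if (any(taus <= 0) || any(taus[, 2] <= taus[, 1]) ||
      any(taus[, 3] <= taus[, 2])) {
    pk_stop("OJIP time constants must be positive and strictly increasing",
            "pamkit_param_error")
  }
  w <- as.matrix(groups[, c("w1", "w2", "w3")])
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-9)) {
    pk_stop("OJIP weights must be non-negative and sum to 1 (tol 1e-9)",
            "pamkit_param_error")
  }
  check_number(f0_base, "f0_base", lower = .Machine$double.xmin)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(tau_npq_s, "tau_npq_s", lower = .Machine$double.xmin)
  check_number(tau_closed_s, "tau_closed_s", lower = .Machine$double.xmin)
  check_number(etr_factor, "etr_factor", lower = .Machine$double.xmin)
  if (is.null(names(n_per_cell))) {
    check_number(n_per_cell, "n_per_cell", lower = 1, upper = 1000)
  } else if (any(n_per_cell < 1)) {
    pk_stop("all n_per_cell entries must be >= 1", "pamkit_design_error")
  }
  structure(
    list(groups = groups, f0_base = f0_base, noise_cv = noise_cv,
         n_per_cell = n_per_cell, seed = as.integer(seed),
         tau_npq_s = tau_npq_s, tau_closed_s = tau_closed_s,
         etr_factor = etr_factor),
    class = "sim_params"
  )
}

#' Shipped synthetic group preset
#'
#' A purely synthetic set of per-cell ground-truth values that mimics the
#' qualitative pattern of interest — the 6x_35 cytotype has a depressed
#' maximum yield and, together with 4x, elevated steady-state NPQ, and the
#' long photoperiod mildly raises NPQ — without being estimated from any
#' measured data. Intended as a demo and test harness, not as a description
#' of any real plant material.
#'
#' @inheritParams sim_params
#' @return A `sim_params` object covering all 8 cells.
#' @export
default_sim_params <- function(n_per_cell = 8, seed = 1, noise_cv = 0.02,
                               f0_base = 500) {
  base <- expand.grid(cytotype = CYTOTYPE_LEVELS,
                      photoperiod_h = PHOTOPERIOD_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  phi <- c("2x" = 0.80, "4x" = 0.79, "6x_29" = 0.80, "6x_35" = 0.72)
  npq <- c("2x" = 0.80, "4x" = 1.10, "6x_29" = 0.85, "6x_35" = 1.15)
  rmx <- c("2x" = 60, "4x" = 52, "6x_29" = 58, "6x_35" = 45)
  base$phi_max_true <- unname(phi[base$cytotype])
  base$npq_ss <- unname(npq[base$cytotype]) +
    ifelse(base$photoperiod_h > 10, 0.10, 0)
  base$qi_frac <- 0.25
  base$closed_frac_ss <- 0.30
  base$retr_max <- unname(rmx[base$cytotype])
  base$alpha_lc <- 0.5 * base$phi_max_true
  base$tau1_ms <- 0.9
  base$tau2_ms <- 12
  base$tau3_ms <- 200
  base$w1 <- 0.55
  base$w2 <- 0.25
  base$w3 <- 0.20
  sim_params(base, f0_base = f0_base, noise_cv = noise_cv,
             n_per_cell = n_per_cell, seed = seed)
}

#' Read / write simulation parameters as JSON
#'
#' Round-trips a [sim_params()] object; weight sums survive serialization
#' to within 1e-9 (values are written at full precision).
#'
#' @param params a `sim_params` object.
#' @param path JSON path.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  if (!file.exists(path)) {
    pk_stop(sprintf("config file '%s' does not exist", path),
            "pamkit_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  npc <- x$n_per_cell
  if (is.list(npc)) npc <- unlist(npc)
  sim_params(x$groups, f0_base = x$f0_base, noise_cv = x$noise_cv,
             n_per_cell = npc, seed = x$seed, tau_npq_s = x$tau_npq_s,
             tau_closed_s = x$tau_closed_s, etr_factor = x$etr_factor)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d groups, f0_base=%g, noise_cv=%g, seed=%d\n",
              nrow(x$groups), x$f0_base, x$noise_cv, x$seed))
  print(x$groups[, c("cytotype", "photoperiod_h", "phi_max_true",
                     "npq_ss", "retr_max")])
  invisible(x)
}
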