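# Synthetic PAM experiment generator. The generative models are the
# simplest forms that reproduce the qualitative features the analysis
# needs: a sum-of-exponentials OJIP rise (three phases giving the O-J-I-P
# inflections), first-order NPQ and closed-fraction kinetics for the
# Kautsky induction/relaxation, and an exponential saturating light
# response for the light curve. Noise is multiplicative log-normal
# (mean 1, coefficient of variation `noise_cv`) because fluorescence is
# strictly positive; additive Gaussian noise could produce negative signal.

# One RNG stream per (plant, protocol), derived by stable string hashing so
# per-plant traces do not depend on generation order.
stable_seed <- function(seed, ...) {
  s <- paste(..., sep = "|")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  as.integer(h)
}

mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

# vectorized F0' estimator shared by the analysis (f0_prime) and the
# Kautsky generative model, so simulation and analysis agree by definition
f0p_vec <- function(F0, FM, FMp) F0 / ((FM - F0) / FM + F0 / FMp)

group_row <- function(params, group) {
  g <- params$groups
  i <- which(g$cytotype == group$cytotype &
               g$photoperiod_h == group$photoperiod_h)
  if (length(i) != 1L) {
    pk_stop(sprintf("no unique parameter row for cell (%s, %g h)",
                    group$cytotype, group$photoperiod_h),
            "pamkit_param_error")
  }
  g[i, , drop = FALSE]
}

#' Factorial plant design
#'
#' Enumerates plants over the full cytotype x photoperiod factorial (eight
#' cells), with `n_per_cell` plants per cell — a scalar, or a named vector
#' keyed `"<cytotype>:<photoperiod_h>"` to emulate unbalanced designs such
#' as the 3-11 plants per cell of a real campaign.
#'
#' @param n_per_cell integer in [1, 1000], or a named per-cell vector.
#' @param seed integer; recorded with each plant so downstream simulation
#'   is reproducible.
#' @return A tibble with columns `plant_id` (unique), `cytotype`,
#'   `photoperiod_h`, `seed`.
#' @export
make_design <- function(n_per_cell = 8, seed = 1) {
  cells <- expand.grid(cytotype = CYTOTYPE_LEVELS,
                       photoperiod_h = PHOTOPERIOD_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(cells$cytotype, cells$photoperiod_h, sep = ":")
  if (is.null(names(n_per_cell))) {
    check_number(n_per_cell, "n_per_cell", lower = 1, upper = 1000,
                 class = "pamkit_design_error")
    n <- rep(as.integer(n_per_cell), nrow(cells))
  } else {
    missing_cells <- setdiff(key, names(n_per_cell))
    if (length(missing_cells)) {
      pk_stop(sprintf("n_per_cell map misses cell(s): %s",
                      paste(missing_cells, collapse = ", ")),
              "pamkit_design_error")
    }
    n <- as.integer(n_per_cell[key])
    if (any(n < 1) || any(n > 1000)) {
      pk_stop("every n_per_cell entry must lie in [1, 1000]",
              "pamkit_design_error")
    }
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tibble(
      plant_id = sprintf("%s_%gh_p%02d", cells$cytotype[i],
                         cells$photoperiod_h[i], seq_len(n[i])),
      cytotype = cells$cytotype[i],
      photoperiod_h = cells$photoperiod_h[i],
      seed = as.integer(seed)
    )
  })
  do.call(rbind, rows)
}

#' Simulate a fast (OJIP) fluorescence transient
#'
#' Noise-free model: a three-phase exponential rise
#' F(t) = F0 + FV sum_k w_k (1 - exp(-t / tau_k)), with
#' FV = F0 phi_max / (1 - phi_max) so that the asymptote satisfies
#' (FM - F0)/FM = phi_max exactly. Sampled on a log-uniform grid from
#' 10 us to 2 s (80 points), then multiplied by log-normal noise.
#'
#' @param params a [sim_params()].
#' @param group list or one-row data frame with `cytotype` and
#'   `photoperiod_h` selecting the parameter cell.
#' @param seed integer; defaults to the study seed in `params`.
#' @param plant_id identifier stored in the trace metadata and hashed into
#'   the per-trace RNG stream.
#' @param n_points number of log-spaced samples (>= 60).
#' @param t_min_s,t_max_s sampling span in seconds.
#' @return An OJIP [fluor_trace()].
#' @export
simulate_ojip <- function(params, group, seed = NULL, plant_id = "plant",
                          n_points = 80, t_min_s = 1e-5, t_max_s = 2) {
  stopifnot(inherits(params, "sim_params"))
  g <- group_row(params, group)
  seed <- seed %||% params$seed
  if (n_points < 60) {
    pk_stop("n_points must be >= 60 to resolve the transient",
            "pamkit_param_error")
  }
  set.seed(stable_seed(seed, plant_id, "OJIP"))
  t <- exp(seq(log(t_min_s), log(t_max_s), length.out = n_points))
  F0 <- params$f0_base
  FV <- F0 * g$phi_max_true / (1 - g$phi_max_true)
  taus_s <- c(g$tau1_ms, g$tau2_ms, g$tau3_ms) / 1000
  w <- c(g$w1, g$w2, g$w3)
  rise <- colSums(w * (1 - exp(-outer(1 / taus_s, t))))
  f <- (F0 + FV * rise) * mult_noise(length(t), params$noise_cv)
  fluor_trace(
    t, f, rep(default_protocol("OJIP")$ojip_pulse_ppfd, length(t)),
    rep(TRUE, length(t)), "OJIP",
    meta = list(plant_id = plant_id, cytotype = g$cytotype,
                photoperiod_h = g$photoperiod_h, seed = seed)
  )
}

# Closed-form Kautsky kinetics; `t` is absolute trace time.
kc_model <- function(params, g, protocol) {
  off <- setNames(phase_offsets(protocol), protocol$phases$name)
  dur <- setNames(protocol$phases$duration_s, protocol$phases$name)
  t_on <- off[["actinic"]]
  t_off <- off[["dark_recovery"]]
  F0 <- params$f0_base
  FM <- F0 / (1 - g$phi_max_true)
  npq_end <- g$npq_ss * (1 - exp(-(t_off - t_on) / params$tau_npq_s))
  npq_floor <- g$npq_ss * g$qi_frac
  c_end <- g$closed_frac_ss * (1 - exp(-(t_off - t_on) / params$tau_closed_s))

  npq_at <- function(t) {
    ifelse(t < t_on, 0,
      ifelse(t < t_off,
        g$npq_ss * (1 - exp(-(t - t_on) / params$tau_npq_s)),
        npq_floor + (npq_end - npq_floor) *
          exp(-(t - t_off) / params$tau_npq_s)))
  }
  c_at <- function(t) {
    ifelse(t < t_on, 0,
      ifelse(t < t_off,
        g$closed_frac_ss * (1 - exp(-(t - t_on) / params$tau_closed_s)),
        c_end * exp(-(t - t_off) / params$tau_closed_s)))
  }
  fmp_at <- function(t) FM / (1 + npq_at(t))
  f_meas_at <- function(t) {
    fmp <- fmp_at(t)
    f0p <- f0p_vec(F0, FM, fmp)
    f0p + (fmp - f0p) * c_at(t)
  }
  list(F0 = F0, FM = FM, npq_at = npq_at, c_at = c_at,
       fmp_at = fmp_at, f_meas_at = f_meas_at)
}

# Sampling grid for pulsed protocols: `sample_dt_s` between pulses,
# `pulse_dt_s` (1 kHz default) inside the 0.8 s pulse windows.
pulsed_grid <- function(protocol) {
  total <- sum(protocol$phases$duration_s)
  base <- seq(protocol$sample_dt_s, total, by = protocol$sample_dt_s)
  win <- pulse_windows(protocol)
  in_pulse <- rep(FALSE, length(base))
  for (i in seq_len(nrow(win))) {
    in_pulse <- in_pulse | (base >= win$start_s[i] & base <= win$end_s[i])
  }
  t <- base[!in_pulse]
  flag <- rep(FALSE, length(t))
  for (i in seq_len(nrow(win))) {
    tp <- seq(win$start_s[i], win$end_s[i], by = protocol$pulse_dt_s)
    t <- c(t, tp)
    flag <- c(flag, rep(TRUE, length(tp)))
  }
  o <- order(t)
  list(time_s = t[o], pulse_flag = flag[o])
}

phase_actinic_at <- function(protocol, t) {
  off <- phase_offsets(protocol)
  idx <- findInterval(t, c(off, sum(protocol$phases$duration_s)),
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(protocol$phases)] <- nrow(protocol$phases)
  protocol$phases$actinic_ppfd[idx]
}

#' Simulate a Kautsky induction-decay (KC) trace
#'
#' Generative model: under actinic light NPQ rises first-order toward
#' `npq_ss` (time constant `tau_npq_s`, default 10 s) and in the dark
#' relaxes toward `npq_ss * qi_frac`; the quenched maximum is
#' FM'(t) = FM / (1 + NPQ(t)). The closed-center fraction c(t) relaxes
#' first-order toward `closed_frac_ss` in light (time constant
#' `tau_closed_s`, default 3 s) and back to 0 in darkness. Measuring-light
#' fluorescence is F(t) = F0'(t) + (FM'(t) - F0'(t)) c(t), with F0'(t)
#' computed by the same estimator the analysis uses ([f0_prime()]); inside
#' saturating-pulse windows the emitted value is FM'(t).
#'
#' @inheritParams simulate_ojip
#' @param protocol a KC [protocol_spec()] with dark, actinic and
#'   dark-recovery phases, each carrying its pulses.
#' @return A KC [fluor_trace()].
#' @export
simulate_kautsky <- function(params, group, protocol = default_protocol("KC"),
                             seed = NULL, plant_id = "plant") {
  stopifnot(inherits(params, "sim_params"))
  g <- group_row(params, group)
  seed <- seed %||% params$seed
  for (need in c("dark", "actinic", "dark_recovery")) {
    if (!need %in% protocol$phases$name || !length(protocol$pulses[[need]])) {
      pk_stop(sprintf("KC protocol lacks a '%s' phase with a pulse", need),
              "pamkit_protocol_error")
    }
  }
  set.seed(stable_seed(seed, plant_id, "KC"))
  model <- kc_model(params, g, protocol)
  grid <- pulsed_grid(protocol)
  f <- ifelse(grid$pulse_flag, model$fmp_at(grid$time_s),
              model$f_meas_at(grid$time_s))
  f <- f * mult_noise(length(f), params$noise_cv)
  actinic <- ifelse(grid$pulse_flag, protocol$saturating_ppfd,
                    phase_actinic_at(protocol, grid$time_s))
  fluor_trace(grid$time_s, f, actinic, grid$pulse_flag, "KC",
              meta = list(plant_id = plant_id, cytotype = g$cytotype,
                          photoperiod_h = g$photoperiod_h, seed = seed))
}

# Light-curve steady-state model shared by the simulator and ground truth.
lc_model <- function(params, g) {
  F0 <- params$f0_base
  FM <- F0 / (1 - g$phi_max_true)
  retr_at <- function(I) {
    ifelse(I <= 0, 0, g$retr_max * (1 - exp(-g$alpha_lc * I / g$retr_max)))
  }
  phi_at <- function(I) {
    ifelse(I <= 0, g$alpha_lc / params$etr_factor,
           retr_at(I) / (params$etr_factor * I))
  }
  # mild saturating NPQ so FM' declines with intensity, as on a real leaf
  fmp_at <- function(I) FM / (1 + g$npq_ss * I / (I + 100))
  list(F0 = F0, FM = FM, retr_at = retr_at, phi_at = phi_at,
       fmp_at = fmp_at, ft_at = function(I) fmp_at(I) * (1 - phi_at(I)))
}

#' Simulate a rapid light curve (LC) trace
#'
#' At every actinic step of intensity I the true effective yield is
#' phi(I) = rETR(I) / (etr_factor * I), with the exponential saturating
#' response rETR(I) = retr_max (1 - exp(-alpha_lc I / retr_max)); the
#' constraint `alpha_lc <= etr_factor * phi_max_true` makes the yield
#' approach phi_max as I goes to 0. Each step emits a steady (F(t), FM')
#' pair consistent with phi(I); the trace opens with a dark super pulse
#' revealing F0 and FM.
#'
#' @inheritParams simulate_ojip
#' @param steps actinic intensities, umol photons m-2 s-1, non-empty,
#'   non-negative and non-decreasing; defaults to the
#'   10, 20, 50, 100, 300, 500 ladder.
#' @param step_duration_s seconds per actinic step.
#' @return An LC [fluor_trace()].
#' @export
simulate_light_curve <- function(params, group,
                                 steps = c(10, 20, 50, 100, 300, 500),
                                 seed = NULL, plant_id = "plant",
                                 step_duration_s = 20) {
  stopifnot(inherits(params, "sim_params"))
  g <- group_row(params, group)
  seed <- seed %||% params$seed
  if (length(steps) == 0 || any(steps < 0) || is.unsorted(steps)) {
    pk_stop("steps must be non-empty, non-negative and non-decreasing",
            "pamkit_protocol_error")
  }
  set.seed(stable_seed(seed, plant_id, "LC"))
  protocol <- default_protocol("LC", lc_steps = steps,
                               lc_step_duration_s = step_duration_s)
  model <- lc_model(params, g)
  grid <- pulsed_grid(protocol)
  I <- phase_actinic_at(protocol, grid$time_s)
  dark <- grid$time_s <= protocol$phases$duration_s[1]
  f <- ifelse(grid$pulse_flag,
              ifelse(dark, model$FM, model$fmp_at(I)),
              ifelse(dark, model$F0, model$ft_at(I)))
  f <- f * mult_noise(length(f), params$noise_cv)
  actinic <- ifelse(grid$pulse_flag, protocol$saturating_ppfd, I)
  fluor_trace(grid$time_s, f, actinic, grid$pulse_flag, "LC",
              meta = list(plant_id = plant_id, cytotype = g$cytotype,
                          photoperiod_h = g$photoperiod_h, seed = seed,
                          steps = steps))
}

#' Ground-truth coefficient values implied by the generative models
#'
#' Evaluates the simulators' closed forms for one parameter cell: the
#' Kautsky landmark truths at each pulse time and the coefficient values a
#' noise-free analysis should recover. Used for end-to-end verification
#' and recorded in the ground-truth table of [simulate_study()].
#'
#' @inheritParams simulate_kautsky
#' @return A list: `FM`, per-pulse `Fm_prime`/`Ft`/`Fm_dprime` truths, and
#'   the coefficient list (`phi_max`, `NPQ`, `qE`, `qI`, `qP`, `qL`, `PQ`,
#'   `retr_max`, `alpha_lc`).
#' @export
kc_ground_truth <- function(params, group,
                            protocol = default_protocol("KC")) {
  stopifnot(inherits(params, "sim_params"))
  g <- group_row(params, group)
  model <- kc_model(params, g, protocol)
  off <- setNames(phase_offsets(protocol), protocol$phases$name)
  t_light <- off[["actinic"]] + protocol$pulses$actinic
  t_dark <- off[["dark_recovery"]] + protocol$pulses$dark_recovery
  t_ss <- t_light[length(t_light)]

  fmp_ss <- model$fmp_at(t_ss)
  f0p_ss <- f0p_vec(model$F0, model$FM, fmp_ss)
  ft_ss <- model$f_meas_at(t_ss)
  qP_true <- 1 - model$c_at(t_ss)
  list(
    FM = model$FM,
    Fm_prime = model$fmp_at(t_light),
    Ft = model$f_meas_at(t_light),
    Fm_dprime = model$fmp_at(t_dark),
    coefficients = list(
      phi_max = g$phi_max_true,
      NPQ = g$npq_ss,
      qI = g$npq_ss * g$qi_frac,
      qE = g$npq_ss * (1 - g$qi_frac),
      qP = qP_true,
      qL = qP_true * f0p_ss / ft_ss,
      PQ = 1 - qP_true,
      retr_max = g$retr_max,
      alpha_lc = g$alpha_lc
    )
  )
}

#' Simulate a complete factorial study
#'
#' One LC, one KC and one OJIP trace per plant of the factorial design,
#' plus a long ground-truth table of the true coefficient values behind
#' every plant. Per-plant RNG streams are derived by stable hashing of
#' (seed, plant_id, protocol), so a plant's traces do not depend on the
#' order of generation.
#'
#' @param params a [sim_params()].
#' @param seed optional integer overriding `params$seed`.
#' @param kc_protocol the KC [protocol_spec()].
#' @param lc_steps light-curve intensities.
#' @return A list: `design` (tibble from [make_design()]), `traces` (named
#'   by plant_id, each a list with `LC`, `KC`, `OJIP`), and `truth` — a
#'   tibble (plant_id, cytotype, photoperiod_h, coefficient, value) of
#'   ground-truth values.
#' @export
simulate_study <- function(params, seed = NULL,
                           kc_protocol = default_protocol("KC"),
                           lc_steps = c(10, 20, 50, 100, 300, 500)) {
  stopifnot(inherits(params, "sim_params"))
  seed <- seed %||% params$seed
  design <- make_design(params$n_per_cell, seed)
  traces <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(design))) {
    pid <- design$plant_id[i]
    grp <- list(cytotype = design$cytotype[i],
                photoperiod_h = design$photoperiod_h[i])
    traces[[pid]] <- list(
      LC = simulate_light_curve(params, grp, steps = lc_steps, seed = seed,
                                plant_id = pid),
      KC = simulate_kautsky(params, grp, protocol = kc_protocol,
                            seed = seed, plant_id = pid),
      OJIP = simulate_ojip(params, grp, seed = seed, plant_id = pid)
    )
    tru <- kc_ground_truth(params, grp, kc_protocol)$coefficients
    truth_rows[[pid]] <- tibble(
      plant_id = pid, cytotype = grp$cytotype,
      photoperiod_h = grp$photoperiod_h,
      coefficient = names(tru), value = unlist(tru)
    )
  }
  list(design = design, traces = traces,
       truth = do.call(rbind, truth_rows))
}
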