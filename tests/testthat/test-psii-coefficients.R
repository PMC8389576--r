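# Quantum yields, light-curve points and quenching arithmetic.

test_that("phi_psii and phi_max compute the standard ratios", {
  expect_equal(phi_psii(1500, 1500), 0)
  expect_equal(phi_psii(600, 1500), 0.6)
  expect_equal(phi_psii(0.2 * 1500, 1500), 0.8)
  expect_warning(out <- phi_psii(1600, 1500), class = "pamkit_negative_yield")
  expect_lt(out, 0)

  expect_equal(phi_max(500, 2500), 0.8)
  expect_equal(phi_max(500 * 10, 2500 * 10), 0.8)  # scale invariance
  expect_error(phi_max(2500, 2500), class = "pamkit_validation_error")
})

test_that("daily light integral reproduces the growth-chamber doses", {
  expect_equal(daily_light_integral(250, 10)$dli, 9.0)
  expect_equal(round(daily_light_integral(250, 16.5)$dli, 1), 14.8)
  expect_equal(daily_light_integral(250, 16.5)$dli, 14.85)
  expect_equal(daily_light_integral(0, 12)$dli, 0)
  expect_error(daily_light_integral(250, 25), class = "pamkit_validation_error")
})

test_that("rETR is the yield-intensity product", {
  expect_equal(retr(0.6, 300, 0.5)$rETR, 90)
  expect_equal(retr(0.6, 0, 0.5)$rETR, 0)
  expect_equal(retr(0.3, 400, 0.5)$rETR, 2 * retr(0.3, 200, 0.5)$rETR)
})

test_that("light_curve maps one landmark pair to one point per step", {
  steps <- data.frame(ppfd = c(10, 20, 50, 100, 300, 500),
                      Ft = 900, Fm_prime = 1500)
  pts <- light_curve(steps)
  expect_equal(nrow(pts), 6)
  expect_equal(pts$phi_psii, rep(0.4, 6))
  all_closed <- data.frame(ppfd = c(10, 100), Ft = 1500, Fm_prime = 1500)
  expect_equal(light_curve(all_closed)$rETR, c(0, 0))
})

test_that("noise-free simulated light curve matches the generator response within 2%", {
  p <- nf_params()
  g <- p$groups[p$groups$cytotype == "4x" & p$groups$photoperiod_h == 16.5, ]
  grp <- list(cytotype = "4x", photoperiod_h = 16.5)
  tr <- simulate_light_curve(p, grp)
  pts <- light_curve(extract_lc_landmarks(tr, default_protocol("LC")))
  truth <- g$retr_max * (1 - exp(-g$alpha_lc * pts$ppfd / g$retr_max))
  expect_equal(pts$rETR, truth, tolerance = 0.02)
})

test_that("NPQ, qI and qE follow the Stern-Volmer forms and decompose exactly", {
  expect_equal(npq(2500, 1250), 1.0)
  expect_equal(npq(2500, 2500), 0)
  expect_equal(npq(2500, 2000), 0.25)
  expect_warning(npq(2000, 2500), class = "pamkit_negative_quenching")
  expect_equal(qi(2500, 2000), 0.25)
  expect_equal(qi(2500, 2500), 0)
  expect_equal(qe(1.0, 0.25), 0.75)
  expect_warning(out <- qe(0.2, 0.5), class = "pamkit_negative_quenching")
  expect_equal(out, -0.3)
})

test_that("F0' estimator has the no-quenching limit and worked value", {
  expect_equal(f0_prime(500, 2500, 2500), 500)
  expect_equal(f0_prime(500, 2500, 1250), 500 / (0.8 + 0.4))
  expect_equal(round(f0_prime(500, 2500, 1250), 2), 416.67)
  # quenching always lowers the estimate
  for (fmp in c(2400, 2000, 1500, 800)) {
    expect_lt(f0_prime(500, 2500, fmp), 500)
  }
})

test_that("qP and qL span the open/closed extremes and the worked case", {
  expect_equal(qp(416.67, 1250, 416.67), 1)
  expect_equal(ql(1, 416.67, 416.67), 1)
  expect_equal(qp(1250, 1250, 416.67), 0)
  expect_equal(ql(0, 416.67, 1250), 0)
  qP <- qp(600, 1250, 416.6667)
  expect_equal(qP, 650 / 833.3333, tolerance = 1e-6)
  expect_equal(round(qP, 3), 0.78)
  expect_equal(round(ql(qP, 416.6667, 600), 3), 0.542)
})

test_that("PQ is the closed-center complement by default", {
  expect_equal(as.numeric(pq_coefficient(1)), 0)
  expect_equal(as.numeric(pq_coefficient(0)), 1)
  expect_equal(as.numeric(pq_coefficient(0.78)), 0.22)
  expect_equal(attr(pq_coefficient(0.5), "convention"), "one_minus_qP")
  expect_equal(as.numeric(pq_coefficient(0.3, "qP")), 0.3)
})

test_that("kc_coefficients recovers the kinetic model within its tolerances", {
  p <- nf_params()
  p$groups$npq_ss <- 1
  p$groups$qi_frac <- 0.25
  qc <- kc_coefficients(extract_kc_landmarks(simulate_kautsky(p, cell_2x10)))
  expect_equal(qc$NPQ, 1 * (1 - exp(-5.5)), tolerance = 0.02)
  # relaxation law at the last dark pulse (63 s into darkness)
  npq_end <- 1 - exp(-6)
  expect_equal(qc$qI, 0.25 + (npq_end - 0.25) * exp(-6.3), tolerance = 0.05)
  expect_equal(qc$NPQ, qc$qE + qc$qI)  # exact decomposition
})

test_that("kc_coefficients of an unquenched trace is zero within noise", {
  p <- default_sim_params(n_per_cell = 1, seed = 21, noise_cv = 0.005)
  p$groups$npq_ss <- 0
  qc <- suppressWarnings(
    kc_coefficients(extract_kc_landmarks(simulate_kautsky(p, cell_2x10))))
  expect_lt(abs(qc$NPQ), 0.03)
  expect_lt(abs(qc$qI), 0.03)
  expect_lt(abs(qc$qE), 0.05)
})

test_that("quenching coefficients are scale invariant over random landmark sets", {
  for (i in 1:25) {
    lv <- rand_kc_landmark_values(i)
    c1 <- c(NPQ = npq(lv$FM, lv$FMp), qI = qi(lv$FM, lv$FMpp),
            qP = qp(lv$Ft, lv$FMp, lv$F0p),
            F0p_ratio = f0_prime(lv$F0, lv$FM, lv$FMp) / lv$F0)
    s <- exp(runif(1, -3, 3))
    F0p_s <- f0_prime(lv$F0 * s, lv$FM * s, lv$FMp * s)
    c2 <- c(NPQ = npq(lv$FM * s, lv$FMp * s),
            qI = qi(lv$FM * s, lv$FMpp * s),
            qP = qp(lv$Ft * s, lv$FMp * s, F0p_s),
            F0p_ratio = F0p_s / (lv$F0 * s))
    expect_equal(c2, c1, tolerance = 1e-12)
    # ordering invariant whenever F0' <= F(t)
    if (lv$F0p <= lv$Ft) {
      expect_lte(ql(c1[["qP"]], lv$F0p, lv$Ft), c1[["qP"]] + 1e-12)
    }
  }
})
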