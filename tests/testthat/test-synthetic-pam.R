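# Synthetic PAM study generator.

test_that("make_design enumerates the full factorial", {
  d <- make_design(5, seed = 1)
  expect_equal(nrow(d), 4 * 2 * 5)
  expect_false(anyDuplicated(d$plant_id) > 0)
  expect_equal(sort(unique(d$cytotype)), sort(c("2x", "4x", "6x_29", "6x_35")))
  expect_equal(sort(unique(d$photoperiod_h)), c(10, 16.5))
  # deterministic
  expect_identical(d, make_design(5, seed = 1))
})

test_that("make_design honours a per-cell size map in the 3-11 range", {
  cells <- as.vector(outer(c("2x", "4x", "6x_29", "6x_35"), c(10, 16.5),
                           paste, sep = ":"))
  set.seed(3)
  sizes <- setNames(sample(3:11, 8, replace = TRUE), cells)
  d <- make_design(sizes, seed = 2)
  got <- table(paste(d$cytotype, d$photoperiod_h, sep = ":"))
  expect_equal(as.integer(got[cells]), as.integer(sizes))
  expect_true(all(got >= 3 & got <= 11))
})

test_that("make_design rejects empty cells", {
  expect_error(make_design(0), class = "pamkit_design_error")
  expect_error(make_design(c("2x:10" = 0)), class = "pamkit_design_error")
})

test_that("noise-free OJIP transient saturates at F0/(1-phi_max)", {
  p <- nf_params()
  # fast time constants so the 2 s window reaches the asymptote
  p$groups$tau1_ms <- 0.5; p$groups$tau2_ms <- 5; p$groups$tau3_ms <- 60
  tr <- simulate_ojip(p, cell_2x10)
  phi <- p$groups$phi_max_true[p$groups$cytotype == "2x" &
                                 p$groups$photoperiod_h == 10]
  expect_equal(max(tr$fluorescence), p$f0_base / (1 - phi),
               tolerance = 0.002)
})

test_that("OJIP asymptote encodes phi_max exactly: phi=0.8, F0=500 -> FM=2500", {
  p <- nf_params()
  p$groups$phi_max_true <- 0.8
  p$groups$tau1_ms <- 0.5; p$groups$tau2_ms <- 5; p$groups$tau3_ms <- 60
  tr <- simulate_ojip(p, cell_2x10, t_max_s = 5)
  expect_equal(max(tr$fluorescence), 2500, tolerance = 1e-3)
})

test_that("simulators are deterministic given the seed", {
  p <- default_sim_params(n_per_cell = 1, seed = 11, noise_cv = 0.05)
  a <- simulate_ojip(p, cell_2x10, plant_id = "x")
  b <- simulate_ojip(p, cell_2x10, plant_id = "x")
  expect_identical(a$fluorescence, b$fluorescence)
  a <- simulate_kautsky(p, cell_2x10, plant_id = "x")
  b <- simulate_kautsky(p, cell_2x10, plant_id = "x")
  expect_identical(a$fluorescence, b$fluorescence)
  # different plants get different noise
  c <- simulate_kautsky(p, cell_2x10, plant_id = "y")
  expect_false(identical(a$fluorescence, c$fluorescence))
})

test_that("noise-free OJIP transient is strictly non-decreasing", {
  p <- nf_params()
  for (cy in c("2x", "6x_35")) {
    tr <- simulate_ojip(p, list(cytotype = cy, photoperiod_h = 16.5))
    expect_true(all(diff(tr$fluorescence) >= 0))
  }
})

test_that("Kautsky with no quenching keeps every pulse at FM", {
  p <- nf_params()
  p$groups$npq_ss <- 0
  p$groups$closed_frac_ss <- 0
  tr <- simulate_kautsky(p, cell_2x10)
  FM <- p$f0_base / (1 - p$groups$phi_max_true[1])
  pulses <- tr$fluorescence[tr$pulse_flag]
  expect_true(all(abs(pulses - FM) < 1e-9 * FM))
})

test_that("Kautsky NPQ kinetics follow the first-order law at the 55 s pulse", {
  p <- nf_params()
  p$groups$npq_ss <- 1
  gt <- kc_ground_truth(p, cell_2x10)
  ratio <- gt$Fm_prime[5] / gt$FM
  # 1 / (1 + (1 - exp(-5.5)))
  expect_gt(ratio, 0.500)
  expect_lt(ratio, 0.503)
})

test_that("dark relaxation with qi_frac = 0 returns FM'' to FM within 1%", {
  p <- nf_params()
  p$groups$npq_ss <- 1
  p$groups$qi_frac <- 0
  gt <- kc_ground_truth(p, cell_2x10)
  expect_equal(gt$Fm_dprime[3] / gt$FM, 1, tolerance = 0.01)
})

test_that("light curve plateaus at retr_max and is linear at low light", {
  p <- nf_params()
  g <- p$groups[p$groups$cytotype == "2x" & p$groups$photoperiod_h == 10, ]
  tr <- simulate_light_curve(p, cell_2x10, steps = c(1, 2, 5, 2000, 3000))
  pts <- light_curve(
    extract_lc_landmarks(tr, default_protocol("LC",
                                              lc_steps = c(1, 2, 5, 2000, 3000))))
  # saturating-limit: top step within 1% of retr_max
  expect_equal(pts$rETR[5], g$retr_max, tolerance = 0.01)
  # linear limit: alpha*I within 2% at the lowest steps
  expect_equal(pts$rETR[1], g$alpha_lc * 1, tolerance = 0.02)
  expect_equal(pts$rETR[2], g$alpha_lc * 2, tolerance = 0.02)
})

test_that("the standard intensity ladder yields six pulse windows after the dark pulse", {
  p <- nf_params()
  tr <- simulate_light_curve(p, cell_2x10)
  runs <- rle(tr$pulse_flag)
  expect_equal(sum(runs$values), 7)  # 1 dark + 6 steps
  expect_error(simulate_light_curve(p, cell_2x10, steps = c(100, 50)),
               class = "pamkit_protocol_error")
})

test_that("simulate_study yields one trace per plant per protocol and a full truth table", {
  p <- default_sim_params(n_per_cell = 3, seed = 5, noise_cv = 0.02)
  st <- simulate_study(p)
  expect_equal(nrow(st$design), 24)
  expect_equal(length(st$traces), 24)
  expect_true(all(vapply(st$traces, function(x)
    all(c("LC", "KC", "OJIP") %in% names(x)), logical(1))))
  expect_equal(length(unique(st$truth$plant_id)), 24)
  # truth is a property of the parameters, not of the noise seed
  st2 <- simulate_study(p, seed = 99)
  expect_equal(
    aggregate(value ~ coefficient + cytotype, st$truth, mean),
    aggregate(value ~ coefficient + cytotype, st2$truth, mean))
  expect_false(identical(
    st$traces[[1]]$KC$fluorescence,
    st2$traces[[1]]$KC$fluorescence))
})

test_that("parameter validation rejects malformed inputs", {
  p <- default_sim_params()
  bad <- p$groups; bad$phi_max_true[1] <- 1.2
  expect_error(sim_params(bad), class = "pamkit_param_error")
  bad <- p$groups; bad$tau2_ms <- bad$tau1_ms
  expect_error(sim_params(bad), class = "pamkit_param_error")
  bad <- p$groups; bad$w1 <- bad$w1 + 0.01
  expect_error(sim_params(bad), class = "pamkit_param_error")
  bad <- p$groups; bad$alpha_lc <- 0.9
  expect_error(sim_params(bad), class = "pamkit_param_error")
})

test_that("OJIP weights survive a config serialization round-trip to 1e-9", {
  p <- default_sim_params(n_per_cell = 4, seed = 3)
  p$groups$w1 <- 1 / 3; p$groups$w2 <- 1 / 3; p$groups$w3 <- 1 / 3
  p <- sim_params(p$groups, f0_base = p$f0_base, noise_cv = p$noise_cv,
                  n_per_cell = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_params(p, f)
  p2 <- read_sim_params(f)
  w <- p2$groups[, c("w1", "w2", "w3")]
  expect_true(all(abs(rowSums(w) - 1) <= 1e-9))
  expect_equal(p2$groups, p$groups)
})
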