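# ANOVA, studentized range, post-hoc tests and letters.

test_that("studentized range reduces to sqrt(2)|t| for two groups", {
  for (df in c(5, 12, 40)) {
    expect_equal(studentized_range_quantile(0.95, 2, df),
                 sqrt(2) * qt(0.975, df), tolerance = 1e-4)
    q <- 2.7
    expect_equal(studentized_range_cdf(q, 2, df),
                 1 - 2 * pt(-q / sqrt(2), df), tolerance = 1e-6)
  }
})

test_that("studentized range cdf is strictly increasing and matches base R", {
  qs <- seq(0.5, 6, by = 0.5)
  vals <- vapply(qs, studentized_range_cdf, numeric(1), k = 4, df = 10)
  expect_true(all(diff(vals) > 0))
  # base R's ptukey/qtukey as independent oracle
  for (k in c(3, 6, 8)) {
    for (df in c(6, 25)) {
      expect_equal(studentized_range_cdf(3.1, k, df), ptukey(3.1, k, df),
                   tolerance = 1e-5)
      expect_equal(studentized_range_quantile(0.95, k, df),
                   qtukey(0.95, k, df), tolerance = 1e-4)
    }
  }
})

test_that("the 95% quantile agrees with a 200,000-draw Monte-Carlo estimate", {
  set.seed(42)
  ndraw <- 200000
  z <- matrix(rnorm(3 * ndraw), ncol = 3)
  s <- sqrt(rchisq(ndraw, 10) / 10)
  qmc <- quantile((apply(z, 1, max) - apply(z, 1, min)) / s, 0.95)
  expect_equal(studentized_range_quantile(0.95, 3, 10), unname(qmc),
               tolerance = 0.015 / 4)
})

test_that("two-way ANOVA partitions degrees of freedom and flags bad designs", {
  tb <- make_norm_table(1, n_per_cell = 6)
  an <- two_way_anova(tb, "phi_max")
  expect_equal(sum(an$table$df), nrow(tb) - 1)
  expect_true(all(an$table$sum_sq >= 0))
  expect_equal(an$df_resid, 48 - 8)
  # empty cell
  drop <- tb[!(tb$cytotype == "4x" & tb$photoperiod_h == 16.5), ]
  err <- tryCatch(two_way_anova(drop, "phi_max"),
                  pamkit_validation_error = function(e) e)
  expect_match(conditionMessage(err), "4x")
  # all observations identical -> degenerate
  tb$value <- 1
  expect_error(two_way_anova(tb, "phi_max"),
               class = "pamkit_degenerate_data_error")
  # missing coefficient names the available ones
  err <- tryCatch(two_way_anova(make_norm_table(2), "NPQ"),
                  pamkit_validation_error = function(e) e)
  expect_match(conditionMessage(err), "phi_max")
})

test_that("a 3-residual-SD cytotype shift is detected with high power", {
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    tb <- make_norm_table(1000 + r, n_per_cell = 8, sd = 1,
                          shift_cells = c("6x_35:10", "6x_35:16.5"),
                          shift_sd = 3)
    an <- two_way_anova(tb, "phi_max")
    p <- an$table$p_value[an$table$term == "cytotype"]
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("the cytotype F test holds its size under label permutation", {
  set.seed(77)
  tb <- make_norm_table(99, n_per_cell = 8)
  labels <- as.data.frame(tb)[, c("cytotype", "photoperiod_h")]
  vals <- tb$value
  nperm <- 2000
  rej <- 0
  for (i in seq_len(nperm)) {
    perm <- sample(nrow(labels))
    ptb <- tibble::tibble(
      plant_id = tb$plant_id, cytotype = labels$cytotype[perm],
      photoperiod_h = labels$photoperiod_h[perm],
      coefficient = "phi_max", value = vals)
    an <- two_way_anova(ptb, "phi_max")
    if (an$table$p_value[an$table$term == "cytotype"] < 0.05) rej <- rej + 1
  }
  expect_gte(rej / nperm, 0.035)
  expect_lte(rej / nperm, 0.065)
})

test_that("Tukey HSD: identical cells are never separated; separated cells match brute force", {
  tb <- make_norm_table(5, n_per_cell = 6)
  an <- two_way_anova(tb, "phi_max")
  ph <- tukey_hsd(an)
  expect_equal(nrow(ph$comparisons), choose(8, 2))
  expect_true(letters_consistent(ph$letters, posthoc_sig_matrix(ph)))

  # brute-force decisions with a Monte-Carlo critical value
  set.seed(8)
  ndraw <- 100000
  z <- matrix(rnorm(8 * ndraw), ncol = 8)
  s <- sqrt(rchisq(ndraw, an$df_resid) / an$df_resid)
  qmc <- unname(quantile((apply(z, 1, max) - apply(z, 1, min)) / s, 0.95))
  for (r in seq_len(nrow(ph$comparisons))) {
    cmp <- ph$comparisons[r, ]
    brute <- abs(cmp$diff) > qmc * cmp$se
    # skip knife-edge cases within MC error of the boundary
    if (abs(abs(cmp$diff) / cmp$se - qmc) > 0.02) {
      expect_equal(cmp$significant, brute)
    }
  }
})

test_that("Tukey with two groups decides like a two-sample t test", {
  tb <- make_norm_table(6, n_per_cell = 8, shift_cells = c("2x:10"),
                        shift_sd = 1.2)
  an <- two_way_anova(tb, "phi_max")
  ph <- tukey_hsd(an, factors = "photoperiod")
  expect_equal(nrow(ph$comparisons), 1)
  # pooled t test on the same split, same residual variance context
  q2 <- studentized_range_quantile(0.95, 2, an$df_resid)
  expect_equal(q2, sqrt(2) * qt(0.975, an$df_resid), tolerance = 1e-4)
})

test_that("Duncan equals Tukey for two groups and never rejects less overall", {
  tb <- make_norm_table(16, n_per_cell = 7, shift_cells = c("6x_35:10"),
                        shift_sd = 2)
  an <- two_way_anova(tb, "phi_max")
  t2 <- tukey_hsd(an, factors = "photoperiod")
  d2 <- duncan_mrt(an, factors = "photoperiod")
  expect_equal(d2$comparisons$significant, t2$comparisons$significant)

  for (r in 1:40) {
    tbr <- make_norm_table(3000 + r, n_per_cell = 6, sd = 1,
                           shift_cells = c("4x:10", "6x_35:16.5"),
                           shift_sd = runif(1, 0, 3))
    anr <- two_way_anova(tbr, "phi_max")
    tu <- posthoc_sig_matrix(tukey_hsd(anr))
    du <- posthoc_sig_matrix(duncan_mrt(anr))
    expect_true(all(du[tu]))  # every Tukey rejection is a Duncan rejection
  }
})

test_that("Duncan separates three well-separated marginal means with distinct letters", {
  tb <- make_norm_table(31, n_per_cell = 8, sd = 1,
                        shift_cells = c("4x:10", "4x:16.5"), shift_sd = 10)
  tb$value[tb$cytotype == "6x_35"] <- tb$value[tb$cytotype == "6x_35"] + 20
  tb$value[tb$cytotype == "6x_29"] <- tb$value[tb$cytotype == "6x_29"] + 30
  an <- two_way_anova(tb, "phi_max")
  ph <- duncan_mrt(an, factors = "cytotype")
  expect_true(all(ph$comparisons$significant))
  expect_equal(length(unique(ph$letters)), 4)
  expect_true(all(nchar(ph$letters) == 1))
})

test_that("compact letter display satisfies its contract on canonical cases", {
  # no pair significant -> everyone shares 'a'
  m <- matrix(FALSE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(compact_letter_display(m)), rep("a", 4))
  # all pairs significant -> all distinct letters
  m8 <- matrix(TRUE, 8, 8, dimnames = list(LETTERS[1:8], LETTERS[1:8]))
  diag(m8) <- FALSE
  cl <- compact_letter_display(m8)
  expect_equal(length(unique(cl)), 8)
  # chain A != C, A = B, B = C
  m3 <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m3["A", "C"] <- m3["C", "A"] <- TRUE
  expect_equal(compact_letter_display(m3),
               c(A = "a", B = "ab", C = "b"))
  # non-symmetric input rejected
  bad <- m3; bad["A", "B"] <- TRUE
  expect_error(compact_letter_display(bad), class = "pamkit_validation_error")
})

test_that("letters match significance for arbitrary random patterns", {
  for (i in 1:40) {
    set.seed(400 + i)
    k <- sample(3:9, 1)
    m <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.4
    for (r in which(on)) {
      m[pairs[r, 1], pairs[r, 2]] <- m[pairs[r, 2], pairs[r, 1]] <- TRUE
    }
    dimnames(m) <- list(paste0("g", 1:k), paste0("g", 1:k))
    cl <- compact_letter_display(m)
    expect_true(letters_consistent(as.list(cl), m))
  }
})

test_that("analyze_coefficient packages ANOVA, posthoc and letters", {
  tb <- make_norm_table(51, n_per_cell = 5, shift_cells = c("6x_35:10",
                                                            "6x_35:16.5"),
                        shift_sd = 6, coefficient = "NPQ")
  res <- analyze_coefficient(tb, "NPQ", method = "duncan")
  expect_s3_class(res$anova, "pam_anova")
  expect_s3_class(res$posthoc, "posthoc_result")
  expect_equal(sort(names(res$letters)),
               sort(unique(paste(tb$cytotype, tb$photoperiod_h, sep = ":"))))
  expect_true(letters_consistent(res$letters,
                                 posthoc_sig_matrix(res$posthoc)))
  err <- tryCatch(analyze_coefficient(tb, "qL"),
                  pamkit_validation_error = function(e) e)
  expect_match(conditionMessage(err), "NPQ")
})
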