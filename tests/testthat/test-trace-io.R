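# TSV / CSV round-trips and strict validation.

test_that("trace TSV round-trip is exact", {
  p <- default_sim_params(n_per_cell = 1, seed = 2, noise_cv = 0.05)
  tr <- simulate_kautsky(p, cell_2x10, plant_id = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_identical(tr2$time_s, tr$time_s)
  expect_identical(tr2$fluorescence, tr$fluorescence)
  expect_identical(tr2$actinic_ppfd, tr$actinic_ppfd)
  expect_identical(tr2$pulse_flag, tr$pulse_flag)
  expect_identical(trace_protocol_id(tr2), "KC")
  expect_equal(trace_meta(tr2)$plant_id, "rt")
})

test_that("non-monotone time is rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(time_s = seq(0.1, 2, by = 0.1), fluorescence = 500,
                   actinic_ppfd = 0, pulse_flag = 0)
  df$time_s[16] <- df$time_s[14]   # backward step at data row 16 = line 17
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(read_trace(f), pamkit_format_error = function(e) e)
  expect_s3_class(err, "pamkit_format_error")
  expect_match(conditionMessage(err), "line 17")
})

test_that("empty and malformed trace files give format errors, not crashes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_error(read_trace(f), class = "pamkit_format_error")
  writeLines("time_s\tfluorescence\tactinic_ppfd\tpulse_flag", f)
  expect_error(read_trace(f), class = "pamkit_format_error")
  writeLines(c("time_s\tfluor", "0.1\t5"), f)
  expect_error(read_trace(f), class = "pamkit_format_error")
  writeLines(c("time_s\tfluorescence\tactinic_ppfd\tpulse_flag",
               "0.1\t500\t0\t0", "0.2\t-3\t0\t0"), f)
  err <- tryCatch(read_trace(f), pamkit_format_error = function(e) e)
  expect_match(conditionMessage(err), "line 3")
  expect_error(read_trace(file.path(tempdir(), "nope.tsv")),
               class = "pamkit_io_error")
})

test_that("coefficient table CSV round-trips and counts rows", {
  p <- default_sim_params(n_per_cell = 5, seed = 4, noise_cv = 0.01)
  d <- make_design(5, 4)
  tb <- coefficient_table(tibble::tibble(
    plant_id = rep(d$plant_id, each = 5),
    cytotype = rep(d$cytotype, each = 5),
    photoperiod_h = rep(d$photoperiod_h, each = 5),
    coefficient = rep(c("NPQ", "qE", "qI", "qP", "qL"), nrow(d)),
    value = rnorm(5 * nrow(d))
  ))
  expect_equal(nrow(tb), 40 * 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(tb, f)
  tb2 <- read_coefficients(f)
  expect_equal(as.data.frame(tb2), as.data.frame(tb))
})

test_that("coefficient table rejects duplicates and unknown names", {
  base <- tibble::tibble(plant_id = "p1", cytotype = "2x",
                         photoperiod_h = 10, coefficient = "NPQ", value = 1)
  expect_error(coefficient_table(rbind(base, base)),
               class = "pamkit_validation_error")
  bad <- base; bad$coefficient <- "NQP"
  err <- tryCatch(coefficient_table(bad),
                  pamkit_validation_error = function(e) e)
  expect_s3_class(err, "pamkit_validation_error")
  expect_match(conditionMessage(err), "NPQ")  # lists the valid vocabulary
  ok <- base; ok$coefficient <- "rETR@16.5"
  expect_s3_class(coefficient_table(ok), "coefficient_table")
})

test_that("random fixtures round-trip stably", {
  tmp <- withr::local_tempdir()
  for (i in 1:60) {
    set.seed(i)
    n <- sample(5:40, 1)
    tr <- fluor_trace(
      time_s = cumsum(runif(n, 1e-4, 0.5)),
      fluorescence = runif(n, 1e-3, 1e4),
      actinic_ppfd = sample(c(0, 10, 300, 2400), n, replace = TRUE),
      pulse_flag = runif(n) < 0.3,
      protocol_id = sample(c("LC", "KC", "OJIP", "YIELD"), 1),
      meta = list(plant_id = sprintf("p%d", i)))
    f <- file.path(tmp, sprintf("t%d.tsv", i))
    write_trace(tr, f)
    tr2 <- read_trace(f)
    expect_identical(as.data.frame(tr2), as.data.frame(tr))
  }
})

test_that("protocol JSON round-trips", {
  f <- withr::local_tempfile(fileext = ".json")
  pr <- default_protocol("KC")
  write_protocol(pr, f)
  pr2 <- read_protocol(f)
  expect_equal(pr2$phases$duration_s, pr$phases$duration_s)
  expect_equal(pr2$pulses$actinic, pr$pulses$actinic)
  expect_equal(pr2$measuring_ppfd, 0.09)
  expect_equal(pr2$saturating_ppfd, 2400)
})
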