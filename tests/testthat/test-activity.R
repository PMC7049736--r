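test_that("standard curve fits recover exact and noisy calibrations", {
  # exact line uM = 0.01 * RFU
  pts <- tibble::tibble(rfu = c(0, 100, 200, 300), um = 0.01 * c(0, 100, 200, 300))
  cv <- suppressWarnings(fit_standard_curve(pts))
  expect_equal(cv$slope, 0.01, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)

  # degenerate design: one distinct RFU value
  expect_error(fit_standard_curve(tibble::tibble(rfu = rep(50, 4), um = 1:4)),
               class = "ptcflex_degenerate_curve")

  # noisy seeded points: truth within the fit's 95% CI
  set.seed(3)
  rfu <- seq(0, 1000, length.out = 30)
  noisy <- tibble::tibble(rfu = rfu, um = 0.02 * rfu + 0.1 + rnorm(30, sd = 0.05))
  cvn <- fit_standard_curve(noisy)
  ci <- stats::confint(cvn$fit)["rfu", ]
  expect_gt(0.02, ci[1])
  expect_lt(0.02, ci[2])

  # broom-style accessors
  expect_equal(nrow(tidy(cvn)), 2)
  expect_equal(glance(cvn)$slope, cvn$slope)
})

test_that("trace conversion is a floored affine map with unit bookkeeping", {
  cv <- list(slope = 0.01, intercept = 0)
  tr <- tibble::tibble(sample_id = "m", time_h = 0:3, signal = c(0, 0, 0, 0), unit = "RFU")
  expect_equal(convert_trace(tr, cv)$signal, rep(0, 4))
  tr$signal <- c(100, 200, 300, 400)
  out <- convert_trace(tr, cv)
  expect_equal(out$signal, c(1, 2, 3, 4))
  expect_true(all(out$unit == "uM"))

  # negative concentrations floored with a warning
  cvn <- list(slope = 0.01, intercept = -0.5)
  tr$signal <- c(10, 20, 100, 200)
  expect_warning(out <- convert_trace(tr, cvn), "floored")
  expect_equal(out$signal, c(0, 0, 0.5, 1.5))

  # unit mismatch refused
  expect_error(convert_trace(out, cv), class = "ptcflex_unit_mismatch")
})

test_that("bulk rate is the OLS slope over the early window", {
  # noiseless line 0.5 uM/h
  tr <- tibble::tibble(sample_id = "WT", time_h = seq(0, 3, 0.25),
                       signal = 0.5 * seq(0, 3, 0.25))
  expect_equal(suppressWarnings(estimate_bulk_rate(tr))$bulk_rate, 0.5,
               tolerance = 1e-12)

  # saturating trace generated at 1.03 uM/h: estimate within 10%
  syn <- synth_kinetics(true_rate = 1.03, plateau = 10, noise_cv = 0, seed = 1)
  cv <- suppressWarnings(fit_standard_curve(syn$curve_points))
  rate <- estimate_bulk_rate(convert_trace(syn$traces, cv))$bulk_rate
  expect_lt(abs(rate - 1.03) / 1.03, 0.10)

  # too few points inside the window
  sparse <- tibble::tibble(sample_id = "x", time_h = c(0, 1, 3, 4, 5),
                           signal = c(0, 1, 3, 4, 5))
  expect_error(estimate_bulk_rate(sparse), "Fewer than 3 points")
})

test_that("endpoint yield summarises the plateau", {
  flat <- tibble::tibble(sample_id = "x", time_h = seq(0, 20, 0.5), signal = 5)
  expect_equal(endpoint_yield(flat)$yield, 5)
  expect_equal(endpoint_yield(flat, method = "last")$yield, 5)

  # saturating trace with k * t_end = 8: plateau estimate within 2% of truth
  tr <- exp_trace("x", rate = 2, plateau = 5, horizon = 20)
  expect_lt(abs(endpoint_yield(tr)$yield - 5) / 5, 0.02)

  # un-saturated monotone rise: plateau estimate exceeds the midpoint value
  lin <- tibble::tibble(sample_id = "x", time_h = seq(0, 10, 0.5),
                        signal = seq(0, 10, 0.5))
  expect_gt(endpoint_yield(lin)$yield, lin$signal[lin$time_h == 5])

  expect_error(endpoint_yield(flat[0, ]))
})

test_that("relative activity normalizes the wild type to one", {
  expect_equal(relative_activity(5, 5), 1)
  expect_equal(relative_activity(0, 5), 0)
  # 21% of wild type, as for a strongly impaired 2585 mutant
  expect_equal(relative_activity(0.21 * 8, 8), 0.21)
  expect_error(relative_activity(1, 0), class = "ptcflex_invalid_wt_yield")
  expect_error(relative_activity(1, -2), class = "ptcflex_invalid_wt_yield")
})

test_that("activity records process the wild type to relative activity exactly 1", {
  syn <- purrr::map_dfr(
    list(c("WT", 1), c("A2451C", 0.5), c("A2451G", 0.2), c("A2451U", 0.1)),
    function(s) exp_trace(s[1], rate = 1.03 * as.numeric(s[2]),
                          plateau = 10 * as.numeric(s[2]))
  )
  rec <- suppressWarnings(activity_records(syn, wt_id = "WT"))
  expect_identical(rec$relative_activity[rec$sample_id == "WT"], 1)
  expect_equal(rec$relative_activity[rec$sample_id == "A2451C"], 0.5, tolerance = 1e-9)
  expect_error(activity_records(dplyr::filter(syn, sample_id != "WT")), "not found")
})

test_that("rates and relative activities are invariant under standard-curve rescaling", {
  base <- synth_kinetics(sample_id = "WT", true_rate = 1.0, plateau = 8,
                         noise_cv = 0, seed = 5)
  mut <- synth_kinetics(sample_id = "M", true_rate = 0.4, plateau = 3.2,
                        noise_cv = 0, seed = 6)
  traces <- dplyr::bind_rows(base$traces, mut$traces)
  cv1 <- list(slope = 0.01, intercept = 0)
  # same physical signal expressed in 5x larger RFU with a 5x smaller slope
  traces5 <- dplyr::mutate(traces, signal = signal * 5)
  cv5 <- list(slope = 0.01 / 5, intercept = 0)
  r1 <- suppressWarnings(activity_records(traces, cv1))
  r5 <- suppressWarnings(activity_records(traces5, cv5))
  expect_equal(r1$relative_activity, r5$relative_activity, tolerance = 1e-12)
  expect_equal(r1$bulk_rate, r5$bulk_rate, tolerance = 1e-12)
})

test_that("flexibility scores sum mutant activities with the two flags", {
  score3 <- flexibility_scores(tibble::tibble(
    sample_id = c("A2451C", "A2451G", "A2451U"), relative_activity = c(1, 1, 1)))
  expect_identical(score3$score, 3)
  expect_true(score3$flag_flex_ge_1)
  expect_true(score3$flag_any_ge_75pct)

  score0 <- flexibility_scores(tibble::tibble(
    sample_id = c("A2451C", "A2451G", "A2451U"), relative_activity = c(0, 0, 0)))
  expect_identical(score0$score, 0)
  expect_false(score0$flag_flex_ge_1)
  expect_false(score0$flag_any_ge_75pct)

  # 0.94 + 0.10 + 0.05 = 1.09: both flags set
  s <- flexibility_scores(tibble::tibble(
    sample_id = c("A2062C", "A2062G", "A2062U"),
    relative_activity = c(0.05, 0.10, 0.94)))
  expect_equal(s$score, 1.09)
  expect_true(s$flag_flex_ge_1)
  expect_true(s$flag_any_ge_75pct)
})

test_that("flexibility scoring validates completeness and is monotone", {
  expect_error(flexibility_scores(tibble::tibble(
    sample_id = c("A2451C", "A2451G"), relative_activity = c(1, 1))),
    class = "ptcflex_incomplete_position")
  expect_error(flexibility_scores(tibble::tibble(
    sample_id = c("A2451C", "A2451C", "A2451G", "A2451U"),
    relative_activity = c(1, 1, 1, 1))),
    class = "ptcflex_duplicate_mutant")

  # monotone non-decreasing in each mutant's relative activity
  set.seed(9)
  for (i in 1:10) {
    acts <- runif(3)
    base <- flexibility_scores(tibble::tibble(
      sample_id = c("A2451C", "A2451G", "A2451U"), relative_activity = acts))
    bump <- acts
    j <- sample(3, 1)
    bump[j] <- bump[j] + runif(1)
    bumped <- flexibility_scores(tibble::tibble(
      sample_id = c("A2451C", "A2451G", "A2451U"), relative_activity = bump))
    expect_gte(bumped$score, base$score)
  }
})
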