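test_that("blank correction subtracts the per-timepoint blank mean", {
  times <- seq(0, 60, by = 10)
  plate <- rbind(
    data.frame(well = "A1", day = 1, time_min = times, od600 = 0.20,
               is_blank = FALSE, condition = "High"),
    data.frame(well = "B1", day = 1, time_min = times, od600 = 0.04,
               is_blank = FALSE, condition = "Low"),
    data.frame(well = "Z1", day = 1, time_min = times, od600 = 0.04,
               is_blank = TRUE, condition = "blank"))
  corr <- blank_correct(plate)
  expect_equal(corr$od600[corr$well == "A1"], rep(0.16, length(times)))
  expect_equal(corr$od600[corr$well == "B1"], rep(0, length(times)))
  expect_false(any(corr$blank_flag))
  expect_error(blank_correct(plate[!plate$is_blank, ]), "no blank")
})

test_that("features computed after constant-offset correction equal the truth", {
  curve <- make_exp_curve(rate = 0.85, od0 = 0.005, hours = 12)
  offset <- 0.05
  plate <- rbind(
    data.frame(well = "A1", day = 1, time_min = curve$times,
               od600 = curve$od + offset, is_blank = FALSE,
               condition = "High"),
    data.frame(well = "Z1", day = 1, time_min = curve$times, od600 = offset,
               is_blank = TRUE, condition = "blank"))
  corr <- blank_correct(plate)
  sub <- corr[corr$well == "A1", ]
  expect_equal(exponential_rate(sub$time_min, sub$od600),
               exponential_rate(curve$times, curve$od))
  expect_equal(time_to_leave_exponential(sub$time_min, sub$od600),
               time_to_leave_exponential(curve$times, curve$od))
})

test_that("derivative curve reproduces the exponential identity", {
  curve <- make_exp_curve(rate = 0.85, od0 = 0.01, hours = 4)
  d <- derivative_curve(curve$times, curve$od, smooth = FALSE)
  sel <- d$od < 0.16
  expect_equal(d$dod_dt[sel] / d$od[sel], rep(0.85, sum(sel)),
               tolerance = 0.01)

  flat <- derivative_curve(curve$times, rep(0.3, length(curve$times)))
  expect_equal(flat$dod_dt, rep(0, nrow(flat)))
})

test_that("two-phase traces peak their derivative between the landmarks", {
  p <- simulate_growth_plate(noise_sd = 0, erratic_prob = 0, od0 = 0.002,
                             blank_offset = 0, seed = 1)
  sub <- p[p$well == "A1", ]
  d <- derivative_curve(sub$time_min, sub$od600)
  expect_gt(d$od[which.max(d$dod_dt)], 0.16)
  expect_lt(d$od[which.max(d$dod_dt)], 0.3)
})

test_that("exponential rate is exact on noiseless log-linear data", {
  c1 <- make_exp_curve(rate = 0.85, od0 = 0.01, hours = 5)
  expect_equal(exponential_rate(c1$times, c1$od), 0.85, tolerance = 1e-6)
  c2 <- make_exp_curve(rate = 0.5, od0 = 0.02, hours = 6)
  expect_equal(exponential_rate(c2$times, c2$od), 0.5, tolerance = 1e-6)
  # too few points inside the fitting window
  expect_true(is.na(exponential_rate(c(0, 10, 20), c(0.01, 0.011, 0.012))))
})

test_that("time to leave exponential interpolates the 0.16 crossing", {
  c1 <- make_exp_curve(rate = 0.85, od0 = 0.01, hours = 6)
  t1 <- time_to_leave_exponential(c1$times, c1$od)
  expect_equal(t1, log(0.16 / 0.01) / 0.85, tolerance = 1e-3)

  expect_equal(time_to_leave_exponential(c(0, 10), c(0.16, 0.2)), 0)
  expect_true(is.na(time_to_leave_exponential(c1$times, c1$od / 100)))

  # shifting the curve half an hour earlier shifts t_exit by exactly 0.5 h
  shifted <- 0.01 * exp(0.85 * (c1$times / 60 + 0.5))
  expect_equal(t1 - time_to_leave_exponential(c1$times, shifted), 0.5)
})

test_that("saturating OD is the windowed end-of-day mean", {
  times <- seq(0, 600, by = 10)
  expect_equal(saturating_od(times, rep(0.5, length(times))), 0.5)
  ramp <- 0.48 + pmax(times - 540, 0) / 60 * 0.02
  expect_equal(saturating_od(times, ramp), 0.49, tolerance = 0.005)
  expect_error(saturating_od(c(0, 30), c(0.1, 0.2)), "window")
})

test_that("erratic traces are flagged; clean and noise-floor traces are not", {
  p <- simulate_growth_plate(noise_sd = 0, erratic_prob = 0, od0 = 0.002,
                             blank_offset = 0, seed = 2)
  sub <- p[p$well == "A1", ]
  expect_false(flag_erratic(sub$time_min, sub$od600))

  od <- sub$od600
  j <- which(od > 0.3)[1]
  od[j] <- od[j] * 0.5
  expect_true(flag_erratic(sub$time_min, od))

  set.seed(3)
  blank <- rnorm(100, 0.01, 0.002)
  expect_false(flag_erratic(seq(0, 990, by = 10), blank))
})

test_that("condition summaries compute mean and CV with erratic wells excluded", {
  feats <- data.frame(
    well = c("A1", "A2", "A3"), day = 1, condition = "High",
    rate = c(0.8, 0.9, 5), t_exit = c(4, 4, 4), od_sat = c(0.4, 0.4, 0.4),
    erratic = c(FALSE, FALSE, TRUE))
  s <- condition_summary(feats)
  rate_row <- s[s$feature == "rate", ]
  expect_equal(rate_row$mean, 0.85)
  expect_equal(rate_row$cv, sd(c(0.8, 0.9)) / 0.85, tolerance = 1e-9)
  expect_equal(rate_row$cv, 0.0832, tolerance = 1e-3)
  expect_equal(rate_row$n_wells, 2)
  expect_equal(rate_row$n_erratic, 1)

  # identical replicates: cv = 0; order invariance; scale invariance of cv
  feats2 <- feats[c(2, 1), ]; feats2$rate <- 0.7
  s2 <- condition_summary(feats2)
  expect_equal(s2$cv[s2$feature == "rate"], 0)
  feats3 <- feats[1:2, ]
  feats3$rate <- feats3$rate * 7
  s3 <- condition_summary(feats3)
  expect_equal(s3$cv[s3$feature == "rate"],
               s[s$feature == "rate", "cv"])
})

test_that("replicate rate jitter propagates to the programmed CV", {
  cvs <- vapply(1:25, function(s) {
    p <- simulate_growth_plate(rate_sd = 0.05, noise_sd = 0,
                               erratic_prob = 0, seed = s)
    feats <- extract_growth_features(blank_correct(p))
    smry <- condition_summary(feats)
    mean(smry$cv[smry$feature == "rate"])
  }, numeric(1))
  expect_gt(mean(cvs), 0.045)   # sd/mean = 0.05/0.85 ~ 0.059
  expect_lt(mean(cvs), 0.072)
})

test_that("population fold change follows the exponential identity", {
  expect_equal(population_fold_change(0.85, 0.5), exp(0.425))
  expect_equal(population_fold_change(0.85, 0.5), 1.53, tolerance = 0.005)
  expect_equal(population_fold_change(1.23, 0), 1)
  expect_equal(population_fold_change(0.85, 1), 2.34, tolerance = 0.005)
  expect_error(population_fold_change(0.85, -1), ">= 0")
})
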