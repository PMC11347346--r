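tab <- reference_bed_table()
reg <- as_regimen_frame(tab)

test_that("no-repopulation BED reproduces every reference value to 2 decimals", {
  expect_equal(round_half_up(bed_simp(reg), 2), tab$simp)
  expect_equal(bed_simp(fractionation_regimen(25, 2.4)), 74.40)
  expect_equal(bed_simp(fractionation_regimen(18, 3)), 70.20)
})

test_that("BED_simp limits and errors behave", {
  # vanishing quadratic term: BED tends to the physical dose
  expect_equal(bed_simp(data.frame(fractions = 30,
                                   dose_per_fraction = 1e-9)),
               30e-9, tolerance = 1e-6)
  expect_error(bed_simp(fractionation_regimen(10, 2), r = -1), "positive")
  expect_error(fractionation_regimen(0, 2), "positive integer")
  expect_error(fractionation_regimen(10, -2), "positive")
  expect_error(fractionation_regimen(10, 2, fractions_per_day = 3), "1.*2")
})

test_that("elapsed-day conventions and derived durations are consistent", {
  d35 <- duration_from_fractions(35)
  expect_equal(d35$duration_weeks, 7)
  expect_equal(d35$elapsed_days, 46)
  expect_equal(duration_from_fractions(60, fractions_per_day = 2)$duration_weeks, 6)
  expect_equal(duration_from_fractions(5)$duration_weeks, 1)
  expect_equal(duration_from_fractions(5)$elapsed_days, 4)
  # whole-week schedules: calendar count equals 7w - 3
  for (m in c(5, 10, 20, 35, 40)) {
    expect_equal(duration_from_fractions(m)$elapsed_days,
                 duration_from_fractions(m, convention = "7w-3")$elapsed_days)
  }
  # single-day schedule has zero elapsed time
  expect_equal(duration_from_fractions(1)$elapsed_days, 0)
})

test_that("repopulation models reduce to the no-repopulation BED", {
  p_di <- repopulation_params_di(g = 0)
  short <- fractionation_regimen(10, 3) # 2 weeks < T_k = 28.6 d
  expect_equal(bed_di(short, p_di), bed_simp(short))
  # C -> Inf: accelerated repopulation never triggers
  p_dd <- repopulation_params_dd(C = 1e9, g = 0)
  for (i in which(tab$bid == 0)) {
    r1 <- reg[i, , drop = FALSE]
    expect_equal(bed_dd(r1, p_dd), bed_simp(r1))
  }
})

test_that("dose-dependent BED matches the expanded common-denominator form", {
  # independent reconstruction: numerator written over the common
  # denominator r*alpha as r*lam*(exp(-k) - 1)*max(0, T - C/k)
  #   + (alpha*d*m - T*g)*r + m*alpha*d^2
  p <- repopulation_params_dd()
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(10:45, 1)
    d <- runif(1, 1, 3.5)
    r1 <- data.frame(fractions = m, dose_per_fraction = d)
    T <- duration_from_fractions(m)$elapsed_days
    k <- m * p$alpha * d * (d + p$r) / (p$r * T)
    printed <- (p$r * p$lam * (exp(-k) - 1) * max(0, T - p$C / k) +
                  (p$alpha * d * m - T * p$g) * p$r +
                  m * p$alpha * d^2) / (p$r * p$alpha)
    expect_equal(bed_dd(r1, p), printed, tolerance = 1e-12)
  }
})

test_that("anchor calibration reproduces all once-daily reference rows", {
  cal_di <- calibrate_repopulation(
    data.frame(fractions = 35, dose_per_fraction = 2, target = 64.17),
    model = "DI")
  cal_dd <- calibrate_repopulation(
    data.frame(fractions = 35, dose_per_fraction = 2, target = 62.19),
    model = "DD")
  expect_gt(cal_di$g, 0)
  expect_gt(cal_dd$g, 0)
  expect_equal(cal_di$residuals, 0, tolerance = 1e-10)
  qd <- tab$bid == 0
  di <- bed_di(reg[qd, ], repopulation_params_di(g = cal_di$g))
  dd <- bed_dd(reg[qd, ], repopulation_params_dd(g = cal_dd$g))
  expect_lt(max(abs(di - tab$di[qd])), 0.5)
  expect_lt(max(abs(dd - tab$dd[qd])), 0.1)
})

test_that("calibration handles trivial and infeasible anchors", {
  # anchor equal to the g = 0 model value gives g = 0
  r0 <- data.frame(fractions = 35, dose_per_fraction = 2)
  target0 <- bed_dd(r0, repopulation_params_dd(g = 0))
  cal <- calibrate_repopulation(cbind(r0, target = target0), model = "DD")
  expect_equal(cal$g, 0, tolerance = 1e-10)
  # a target above the g = 0 value cannot be fit with g >= 0
  expect_error(
    calibrate_repopulation(cbind(r0, target = target0 + 5), model = "DD"),
    "calibration failed")
  # default parameter objects carry the anchor-calibrated g
  g_di <- calibrate_repopulation(
    data.frame(fractions = 35, dose_per_fraction = 2, target = 64.17),
    model = "DI")$g
  expect_equal(repopulation_params_di()$g, g_di)
})

test_that("BED values move the right way with dose, fractions and time", {
  p_di <- repopulation_params_di()
  p_dd <- repopulation_params_dd()
  base <- data.frame(fractions = 30, dose_per_fraction = 2)
  T0 <- 39
  for (fn in list(function(r1, T) bed_simp(r1),
                  function(r1, T) bed_di(r1, p_di, T_days = T),
                  function(r1, T) bed_dd(r1, p_dd, T_days = T))) {
    up_d <- transform(base, dose_per_fraction = 2.2)
    up_m <- transform(base, fractions = 32)
    expect_gt(fn(up_d, T0), fn(base, T0))
    expect_gt(fn(up_m, T0), fn(base, T0))
  }
  # longer treatment never increases the repopulation-aware BEDs
  expect_lte(bed_di(base, p_di, T_days = 50), bed_di(base, p_di, T_days = 39))
  expect_lte(bed_dd(base, p_dd, T_days = 50), bed_dd(base, p_dd, T_days = 39))
})

test_that("negative BED warns instead of clamping", {
  p <- repopulation_params_di()
  expect_warning(v <- bed_di(data.frame(fractions = 2,
                                        dose_per_fraction = 0.5),
                             p, T_days = 500), "negative")
  expect_lt(v, 0)
})

test_that("comparison table carries differences against the standard regimen", {
  bt <- bed_table(reg, r_values = 10)
  std <- which(reg$fractions == 35)
  expect_equal(bt$diff_bed_simp_10[std], 0)
  expect_equal(bt$diff_bed_di_10[std], 0)
  expect_equal(bt$diff_bed_dd_10[std], 0)
  i18 <- which(reg$fractions == 18)
  expect_equal(bt$diff_bed_simp_10[i18], -13.80)
  # hypofractionated rows gain on the DD scale but lose on the simple scale
  for (i in match(c(18, 20, 25), reg$fractions)) {
    expect_gt(bt$diff_bed_dd_10[i], 0)
    expect_lt(bt$diff_bed_simp_10[i], 0)
  }
  # row order does not matter beyond sorting
  perm <- sample(nrow(reg))
  bt2 <- bed_table(reg[perm, ], r_values = 10)
  expect_equal(bt2[order(perm), ], bt, ignore_attr = TRUE)
  # sensitivity ratios produce one column set per alpha/beta value
  bt3 <- bed_table(reg[std, , drop = FALSE], r_values = c(7, 13))
  expect_true(all(c("bed_dd_7", "bed_dd_13") %in% names(bt3)))
})

test_that("half-up rounding matches tabulated presentation on exact ties", {
  expect_equal(round_half_up(70.125), 70.13)
  expect_equal(round_half_up(-70.125), -70.13)
  expect_equal(round_half_up(20 * 2.75 * 1.275), 70.13)
})

test_that("regimen frequency table bookkeeping matches the published cohort", {
  tab1 <- radcure_regimen_table()
  s <- regimen_summary(tab1)
  expect_equal(s$total_patients, 3346)
  expect_equal(s$modal_regimen$fractions, 35)
  expect_equal(s$modal_regimen$total_dose, 70)
  expect_equal(s$n_other_regimens_over_threshold, 4)
})
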