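# Shared effectful randomized cohort (true RMST(8y) effect 0.5 years).
rand_spec <- solve_bed_loghr(randomized_cohort_spec(n_patients = 2500,
                                                    seed = 41),
                             target = 0.5, horizon = 8)
rand_cohort <- local({
  d <- sample_cohort(rand_spec)
  d$W <- binarize(d$bed_dd, 61.8)
  d
})
task48 <- causal_task("W", horizons = c(4, 8))

test_that("task definition enforces the covariate contract", {
  expect_error(causal_task(covariates = c("Age", "bed_di")), "BED")
  expect_error(causal_task(horizons = c(-1, 3)), "positive")
  t <- causal_task(horizons = c(8, 2, 2))
  expect_equal(t$horizons, c(2, 8))
})

test_that("uncensored randomized data reduce to the arm-mean difference", {
  spec <- randomized_cohort_spec(n_patients = 1200, seed = 43,
                                 censoring_params = list(rate = 0,
                                                         admin_cap = Inf))
  d <- sample_cohort(spec)
  d$W <- binarize(d$bed_dd, 61.8)
  est <- estimate_effects(d, task48, folds = 1, seed = 2,
                          propensity = "constant", outcome = "constant")
  for (h in c(4, 8)) {
    emp <- mean(pmin(d$time[d$W == 1], h)) - mean(pmin(d$time[d$W == 0], h))
    got <- est$ate$estimate[est$ate$estimand == "RMST" &
                              est$ate$horizon == h]
    expect_equal(got, emp, tolerance = 1e-10)
    emp_sp <- 100 * (mean(d$time[d$W == 1] > h) - mean(d$time[d$W == 0] > h))
    got_sp <- est$ate$estimate[est$ate$estimand == "SP" &
                                 est$ate$horizon == h]
    expect_equal(got_sp, emp_sp, tolerance = 1e-8)
  }
})

test_that("the estimator recovers a known randomized effect", {
  truth <- true_effects(rand_spec, horizons = c(4, 8))
  est <- estimate_effects(rand_cohort, task48, seed = 7,
                          propensity = "glm", outcome = "cox")
  a <- est$ate
  for (h in c(4, 8)) {
    row <- a[a$estimand == "RMST" & a$horizon == h, ]
    expect_lt(abs(row$estimate - truth$rmst_effect[truth$horizon == h]),
              2 * row$se)
    row_sp <- a[a$estimand == "SP" & a$horizon == h, ]
    expect_lt(abs(row_sp$estimate - truth$sp_effect[truth$horizon == h]),
              2.5 * row_sp$se)
    expect_gt(row$se, 0)
  }
  # report invariants
  expect_true(all(abs(a$estimate[a$estimand == "SP"]) <= 100))
  expect_true(all(a$estimate[a$estimand == "RMST"] <=
                    a$horizon[a$estimand == "RMST"]))
  expect_equal(nrow(est$fold_effects), 2 * 2 * 10)
})

test_that("forest nuisances agree with parametric nuisances", {
  sub <- rand_cohort[1:900, ]
  est_f <- estimate_effects(sub, causal_task("W", horizons = 8),
                            folds = 5, seed = 3, propensity = "forest",
                            outcome = "forest", num_trees = 60)
  est_p <- estimate_effects(sub, causal_task("W", horizons = 8),
                            folds = 5, seed = 3, propensity = "glm",
                            outcome = "cox")
  r_f <- est_f$ate[est_f$ate$estimand == "RMST", ]
  r_p <- est_p$ate[est_p$ate$estimand == "RMST", ]
  expect_lt(abs(r_f$estimate - r_p$estimate),
            2 * sqrt(r_f$se^2 + r_p$se^2))
})

test_that("misspecifying one nuisance keeps the confounded estimate honest", {
  spec <- cohort_spec(
    n_patients = 3000, seed = 47, confounding = 0.9,
    regimen_weights = data.frame(fractions = c(35L, 25L),
                                 dose_per_fraction = c(2, 2),
                                 fractions_per_day = 1L,
                                 prob = c(0.5, 0.5)))
  spec$effect_params$bed_loghr <- rand_spec$effect_params$bed_loghr
  d <- sample_cohort(spec)
  d$W <- binarize(d$bed_dd, 61.8)
  truth <- true_effects(spec, horizons = 8)$rmst_effect
  task8 <- causal_task("W", horizons = 8)

  # naive unadjusted arm contrast is biased under confounding
  naive <- mean(pmin(d$time[d$W == 1], 8)) -
    mean(pmin(d$time[d$W == 0], 8))
  est_both <- estimate_effects(d, task8, seed = 5, propensity = "glm",
                               outcome = "cox")
  r <- est_both$ate[est_both$ate$estimand == "RMST", ]
  expect_gt(abs(naive - truth), abs(r$estimate - truth))
  expect_lt(abs(r$estimate - truth), 2 * r$se)

  # one wrong nuisance at a time: still consistent
  for (args in list(list(propensity = "constant", outcome = "cox"),
                    list(propensity = "glm", outcome = "constant"))) {
    est <- do.call(estimate_effects,
                   c(list(data = d, task = task8, seed = 5), args))
    r1 <- est$ate[est$ate$estimand == "RMST", ]
    expect_lt(abs(r1$estimate - truth), 2.5 * r1$se)
  }

  # both wrong: bias of the order of the naive contrast reappears
  est0 <- estimate_effects(d, task8, seed = 5, propensity = "constant",
                           outcome = "constant")
  r0 <- est0$ate[est0$ate$estimand == "RMST", ]
  expect_gt(abs(r0$estimate - truth), 2 * r0$se)
})

test_that("held-out effects agree with training effects", {
  idx <- with_seed(8, sample(nrow(rand_cohort), 1750))
  tr <- rand_cohort[idx, ]
  te <- rand_cohort[-idx, ]
  e_tr <- estimate_effects(tr, causal_task("W", horizons = 8), seed = 2,
                           propensity = "glm", outcome = "cox")
  e_te <- estimate_effects(te, causal_task("W", horizons = 8), seed = 2,
                           propensity = "glm", outcome = "cox")
  r_tr <- e_tr$ate[e_tr$ate$estimand == "RMST", ]
  r_te <- e_te$ate[e_te$ate$estimand == "RMST", ]
  expect_lt(abs(r_tr$estimate - r_te$estimate),
            2 * sqrt(r_tr$se^2 + r_te$se^2))
})

test_that("degenerate treatments and positivity violations are refused", {
  d <- rand_cohort[1:300, ]
  d$W <- 1L
  expect_error(estimate_effects(d, task48), "arms")
  # near-deterministic treatment given Age: propensities pile outside
  d2 <- rand_cohort[1:800, ]
  d2$W <- as.integer(d2$Age > stats::median(d2$Age))
  expect_error(
    suppressWarnings(estimate_effects(d2, causal_task("W", horizons = 8),
                                      seed = 2, propensity = "glm",
                                      outcome = "constant")),
    "positivity")
})

test_that("horizons beyond the follow-up cap are dropped with a warning", {
  expect_warning(
    est <- estimate_effects(rand_cohort[1:600, ],
                            causal_task("W", horizons = c(4, 40)),
                            folds = 3, seed = 2, propensity = "constant",
                            outcome = "constant"),
    "horizon")
  expect_equal(est$horizons, 4)
})

test_that("intercept-only projection returns the average effect", {
  est <- estimate_effects(rand_cohort[1:1000, ],
                          causal_task("W", horizons = 8), folds = 5,
                          seed = 4, propensity = "glm", outcome = "cox")
  b <- blp(est, "RMST", horizon = 8, covariates = character(0))
  a <- est$ate[est$ate$estimand == "RMST" & est$ate$horizon == 8, ]
  expect_equal(b$estimate[b$term == "(Intercept)"], a$estimate,
               tolerance = 1e-10)
  # full projection reports robust inference per covariate
  b2 <- blp(est, "RMST", horizon = 8)
  expect_setequal(setdiff(b2$term, "(Intercept)"),
                  c("Sex", "Smoking_PY", "Stage_numeric", "HPV_Positive",
                    "HPV_Unknown", "Chemo", "RT_year", "Age"))
  expect_true(all(b2$se > 0))
  # collinear covariates are dropped, not fatal
  est$covariate_data$Age2 <- est$covariate_data$Age
  expect_warning(b3 <- blp(est, "RMST", horizon = 8,
                           covariates = c("Age", "Age2")), "collinear")
  expect_false("Age2" %in% b3$term)
})

test_that("stage-restricted benefit surfaces as negative stage projection", {
  spec <- randomized_cohort_spec(
    n_patients = 6000, seed = 53,
    effect_params = list(bed_loghr = -0.55,
                         effect_modifier = list(variable = "Stage_numeric",
                                                max_value = 2)))
  d <- sample_cohort(spec)
  d$W <- binarize(d$bed_dd, 61.8)
  est <- estimate_effects(d, causal_task("W", horizons = 8), seed = 6,
                          propensity = "glm", outcome = "cox")
  b <- blp(est, "RMST", horizon = 8)
  st <- b[b$term == "Stage_numeric", ]
  expect_lt(st$estimate, 0)
  expect_lt(st$p_value, 0.05)

  # per-patient effects differ by stratum in the generator's direction
  pp <- per_patient_effects(est, "RMST", horizon = 8, se_method = "none",
                            seed = 2)
  low <- d$Stage_numeric <= 2
  expect_gt(mean(pp$cate[low]), mean(pp$cate[!low]))
})

test_that("per-patient effects summarise the score distribution", {
  est <- estimate_effects(rand_cohort, task48, seed = 9,
                          propensity = "glm", outcome = "cox")
  pp <- per_patient_effects(est, "SP", se_method = "jackknife", seed = 3)
  expect_length(pp$cate, nrow(rand_cohort))
  expect_true(all(pp$cate_se > 0))
  expect_true(pp$horizon %in% c(4, 8))
  expect_s3_class(pp$histogram, "histogram")
  # homogeneous-effect generator: CATE spread stays modest
  a <- est$ate[est$ate$estimand == "SP" & est$ate$horizon == pp$horizon, ]
  expect_lt(sd(pp$cate), 3 * abs(a$estimate))
  # null scores give CATEs centred at zero
  null_d <- placebo_treatment(rand_cohort, "W", seed = 11)
  est0 <- estimate_effects(null_d, causal_task("W", horizons = 8),
                           folds = 5, seed = 9, propensity = "constant",
                           outcome = "constant")
  pp0 <- per_patient_effects(est0, "SP", horizon = 8, se_method = "none")
  a0 <- est0$ate[est0$ate$estimand == "SP", ]
  expect_lt(abs(mean(pp0$cate)), max(3 * a0$se, 2))
})

test_that("logrank comparison matches the observed-minus-expected oracle", {
  d <- data.frame(time = c(2, 4, 5, 7, 9, 10),
                  event = c(1, 1, 0, 1, 1, 0),
                  g = c(1, 0, 1, 0, 1, 0))
  got <- km_logrank(d, d$g)
  oracle <- logrank_oracle(d$time, d$event, d$g)
  expect_equal(got$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-10)

  # identical arms: zero statistic, p = 1
  dd <- rbind(d, d)
  dd$g <- rep(c(0, 1), each = 6)
  same <- km_logrank(dd, dd$g)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  d0 <- d; d0$event[d0$g == 1] <- 0
  expect_error(km_logrank(d0, d0$g), "no events")
})
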