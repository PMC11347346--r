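test_that("cohort generation is reproducible and structurally valid", {
  spec <- cohort_spec(n_patients = 500, seed = 9)
  d1 <- sample_cohort(spec)
  d2 <- sample_cohort(spec)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(
    as.data.frame(sample_cohort(cohort_spec(n_patients = 500, seed = 10))),
    as.data.frame(d1)))
  expect_true(all(d1$time > 0))
  expect_true(all(d1$cause[d1$event == 0] == "none"))
  expect_true(all(d1$cause[d1$event == 1] != "none"))
  expect_true(all(d1$HPV_Positive + d1$HPV_Unknown <= 1))
  sites <- c("Esophagus", "Hypopharynx", "Larynx", "Lip_Oral_Cavity",
             "Nasal_Cavity", "Oropharynx")
  expect_true(all(rowSums(d1[, sites]) <= 1))
  expect_true(all(d1$Stage_numeric %in% 0:4))
})

test_that("generated marginals match the spec within Monte-Carlo error", {
  spec <- cohort_spec(n_patients = 2000, seed = 21)
  d <- sample_cohort(spec)
  cp <- spec$covariate_params
  n <- nrow(d)
  # binomial proportions within 3 MC standard errors
  for (chk in list(c(mean(d$Sex), cp$p_male),
                   c(mean(d$Chemo), cp$p_chemo),
                   c(mean(d$HPV_Positive), cp$hpv_probs[["positive"]]),
                   c(mean(d$Smoking_PY == 0), cp$smoking_p_zero))) {
    se <- sqrt(chk[2] * (1 - chk[2]) / n)
    expect_lt(abs(chk[1] - chk[2]), 3 * se)
  }
  expect_lt(abs(mean(d$Age) - cp$age_mean), 3 * cp$age_sd / sqrt(n))
  expect_lt(abs(mean(d$Stage_numeric) -
                  sum(0:4 * cp$stage_probs)), 3 * 1.1 / sqrt(n))
})

test_that("default regimen mix reproduces the registry pattern", {
  d <- sample_cohort(cohort_spec(n_patients = 3346, seed = 4))
  counts <- sort(table(paste(d$fractions, d$total_dose)), decreasing = TRUE)
  expect_equal(names(counts)[1], "35 70")           # modal regimen
  expect_gte(sum(counts[-1] > 50), 4)               # other common regimens
})

test_that("treatment positivity holds across covariate strata", {
  d <- sample_cohort(cohort_spec(n_patients = 3000, seed = 5))
  W <- binarize(d$bed_dd, 61.8)
  for (s in split(W, d$Stage_numeric)) {
    if (length(s) < 50) next
    expect_gt(mean(s), 0.05)
    expect_lt(mean(s), 0.95)
  }
  for (s in split(W, d$Chemo)) {
    expect_gt(mean(s), 0.05)
    expect_lt(mean(s), 0.95)
  }
})

test_that("confounding switch links stage to regimen choice", {
  spec_c <- cohort_spec(n_patients = 4000, seed = 6, confounding = 0.8)
  d <- sample_cohort(spec_c)
  W <- binarize(d$bed_dd, 61.8)
  expect_gt(cor(W, d$Stage_numeric), 0.1)
  spec_0 <- cohort_spec(n_patients = 4000, seed = 6, confounding = 0)
  W0 <- binarize(sample_cohort(spec_0)$bed_dd, 61.8)
  expect_lt(abs(cor(W0, sample_cohort(spec_0)$Stage_numeric)), 0.05)
})

test_that("oracle effects vanish under a null generator and small horizons", {
  null_spec <- randomized_cohort_spec(n_patients = 100, seed = 1,
                                      effect_params = list(bed_loghr = 0))
  te <- true_effects(null_spec, horizons = c(1, 5, 10))
  expect_equal(te$rmst_effect, rep(0, 3))
  expect_equal(te$sp_effect, rep(0, 3))
  eff <- randomized_cohort_spec(n_patients = 100, seed = 1)
  tiny <- true_effects(eff, horizons = 0.001)
  expect_lt(abs(tiny$rmst_effect), 1e-4)
})

test_that("survival-probability effect rises then plateaus over horizons", {
  spec <- randomized_cohort_spec(n_patients = 100, seed = 2)
  te <- true_effects(spec, horizons = c(1, 2, 4, 6, 8, 10, 12))
  sp <- te$sp_effect
  expect_gt(sp[4], sp[1])                 # early rise
  expect_lt(abs(sp[7] - sp[6]), abs(sp[3] - sp[1]))  # flattening
  expect_true(all(diff(te$rmst_effect) > 0))
})

test_that("randomized arms reproduce the configured restricted-mean gap", {
  spec <- randomized_cohort_spec(n_patients = 5000, seed = 31,
                                 censoring_params = list(rate = 0,
                                                         admin_cap = Inf))
  spec <- solve_bed_loghr(spec, target = 0.5, horizon = 8)
  d <- sample_cohort(spec)
  expect_true(all(d$event == 1))
  W <- binarize(d$bed_dd, 61.8)
  emp <- mean(pmin(d$time[W == 1], 8)) - mean(pmin(d$time[W == 0], 8))
  # Monte-Carlo error of a difference of truncated means at this n
  se <- sqrt(var(pmin(d$time, 8)) * (1 / sum(W) + 1 / sum(1 - W)))
  expect_lt(abs(emp - 0.5), 3 * se)
})

test_that("cohort CSV round-trip is lossless and schema-checked", {
  d <- sample_cohort(cohort_spec(n_patients = 120, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  d2 <- read_cohort(path)
  plain <- as.data.frame(d)
  attr(plain, "spec") <- NULL
  expect_identical(plain, as.data.frame(d2))

  broken <- d; broken$time <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(broken), path2, row.names = FALSE)
  expect_error(read_cohort(path2), "time")

  nb <- as.data.frame(d); nb$Chemo[1] <- 2
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(nb, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "Chemo")

  extra <- d; extra$mystery <- 1
  path4 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(extra, path4)
  expect_message(d4 <- read_cohort(path4), "mystery")
  expect_true("mystery" %in% names(d4))
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(n_patients = 0), "positive")
  expect_error(cohort_spec(covariate_params = list(p_male = 1.4)), "0, 1")
  w <- data.frame(fractions = 35L, dose_per_fraction = 2,
                  fractions_per_day = 1L, prob = 0.7)
  expect_error(cohort_spec(regimen_weights = w), "sum to 1")
})
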