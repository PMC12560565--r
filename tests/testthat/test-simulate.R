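test_that("simulation is deterministic given config and seed", {
  cfg <- cohort_config()
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, seed = 6)))
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_cohort(cfg, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated cohorts respect the design and instrument invariants", {
  co <- simulate_cohort(cohort_config(), seed = 2)
  expect_equal(nrow(co), 80L)
  expect_equal(as.integer(table(co$arm)), rep(20L, 4))
  expect_identical(co$stratum,
                   ifelse(co$arm %in% c("MTX_DN", "TOFA_DN"), "DN", "DF"))
  expect_true(all(co$tjc68 >= 2 & co$tjc68 <= 68))
  expect_true(all(co$sjc66 >= 2 & co$sjc66 <= 66))
  expect_true(all(co$lei %in% 0:6))
  expect_true(all(co$haq >= 0 & co$haq <= 3))
  expect_true(all(co$bsa >= 0 & co$bsa <= 100))
  expect_true(all(co$vas_pain >= 0 & co$vas_pain <= 100))
  # DMARD-naive patients can have no TNFi history
  expect_true(all(co$tnfi_history[co$stratum == "DN"] == 0))
  # all 16 baseline covariates are present in the default config
  expect_true(all(default_candidates() %in% names(co)))
  expect_length(default_candidates(), 16L)
})

test_that("responder flag is exactly the MDA of the generated week-16 data", {
  co <- simulate_cohort(cohort_config(n_per_arm = 100), seed = 3)
  rechecked <- compute_mda(co[, !names(co) %in%
                                c("mda_criteria_met", "is_mda",
                                  "mda_imputed")], suffix = "_w16")
  expect_identical(co$is_mda, rechecked$is_mda)
  expect_identical(co$mda_week16, as.integer(rechecked$is_mda))
  expect_true(all(rechecked$mda_criteria_met[rechecked$is_mda] >= 5))
  expect_true(all(rechecked$mda_criteria_met[!rechecked$is_mda] <= 4))
})

test_that("a flat outcome model yields a 50% response rate", {
  cfg <- cohort_config(true_intercept = 0, true_beta = c(haq = 0),
                       true_treatment_effects = c(MTX_DN = 0, TOFA_DN = 0,
                                                  ETN_DF = 0, TOFA_DF = 0),
                       n_per_arm = 500)
  co <- simulate_cohort(cfg, seed = 4)
  expect_true(all(abs(co$true_prob - 0.5) < 1e-12))
  expect_lt(abs(mean(co$mda_week16) - 0.5), 0.05) # 3 SE at n = 2000 is 0.034
})

test_that("an unpenalized refit recovers the generative coefficient", {
  cfg <- cohort_config(true_intercept = 0, true_beta = c(haq = -1.2),
                       true_treatment_effects = c(MTX_DN = 0, TOFA_DN = 0,
                                                  ETN_DF = 0, TOFA_DF = 0),
                       n_per_arm = 1250)
  co <- simulate_cohort(cfg, seed = 8)
  fit <- glm(mda_week16 ~ haq, family = binomial(), data = co)
  expect_lt(abs(coef(fit)[["haq"]] - (-1.2)), 0.1)
  expect_lt(abs(coef(fit)[["(Intercept)"]]), 0.1)
})

test_that("default config keeps the overall response rate near 50%", {
  rates <- vapply(1:10, function(s) {
    mean(simulate_cohort(cohort_config(n_per_arm = 250), seed = 100 + s)$mda_week16)
  }, numeric(1))
  expect_true(mean(rates) > 0.45 && mean(rates) < 0.55)
})

test_that("covariate moments and correlations match the configured model", {
  co <- simulate_cohort(cohort_config(n_per_arm = 2500), seed = 12)
  # vas_pain ~ Normal(50, 20): mean within 3 SE at n = 10000
  expect_lt(abs(mean(co$vas_pain) - 50), 3 * 20 / sqrt(10000))
  expect_lt(abs(sd(co$vas_pain) - 20), 1)
  # configured latent correlation between the two patient-reported VAS
  expect_lt(abs(cor(co$vas_pain, co$vas_patient_global) - 0.6), 0.08)
  # DF stratum has longer disease duration by construction
  expect_gt(median(co$disease_duration[co$stratum == "DF"]),
            median(co$disease_duration[co$stratum == "DN"]))
})

test_that("arm assignment is independent of covariates within stratum", {
  pvals <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_config(), seed = 200 + s)
    dn <- co[co$stratum == "DN", ]
    t.test(haq ~ arm, data = dn)$p.value
  }, numeric(1))
  # p-values should look uniform; a systematic imbalance would pile near 0
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)
})

test_that("configuration errors name the offending component", {
  expect_error(cohort_config(covariates = utils::modifyList(
    default_covariate_specs(),
    list(crp = covariate_spec("crp", "continuous", "lognormal",
                              list(meanlog = 0, sdlog = -1))))), "crp")
  expect_error(cohort_config(true_beta = c(nonexistent = 1)), "nonexistent")
  expect_error(cohort_config(true_treatment_effects =
                               c(MTX_DN = 0.5, TOFA_DN = 0, ETN_DF = 0,
                                 TOFA_DF = 0)), "reference")
  expect_error(
    cohort_config(true_interactions = list(
      list(predictor = "haq", arm = "PBO", effect = 1))), "PBO")
  expect_error(simulate_cohort(cohort_config()), "seed")
})
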