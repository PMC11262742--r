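test_that("simulation is deterministic given the seed", {
  cfg <- small_config()
  a <- simulate_claims(cfg, seed = 5)
  b <- simulate_claims(cfg, seed = 5)
  expect_equal(a$claims, b$claims)
  expect_equal(a$truth, b$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_claims(a$claims, f1); write_claims(b$claims, f2)
  expect_identical(readLines(f1), readLines(f2))
  c <- simulate_claims(cfg, seed = 6)
  expect_false(identical(a$claims, c$claims))
})

test_that("centre specs honour configured counts and prevalences", {
  specs <- generate_centres(simulation_config(), seed = 2)
  expect_equal(nrow(specs), 907L)
  expect_equal(as.vector(table(specs$category)), c(60L, 390L, 457L))
  honest <- generate_centres(small_config(
    fraud_prevalence = c(volume_inflation = 0, positivity_suppression = 0,
                         digit_rounding = 0, fabrication = 0)), seed = 2)
  expect_true(all(lengths(honest$behaviours) == 0))
})

test_that("adding centres to the last category leaves earlier centres' draws unchanged", {
  w <- study_window("2021-04-08", "2021-06-30")
  cfg1 <- simulation_config(n_centres = c(pharmacy = 5L, practice = 5L, private = 5L),
                            window = w)
  cfg2 <- simulation_config(n_centres = c(pharmacy = 5L, practice = 5L, private = 7L),
                            window = w)
  s1 <- generate_centres(cfg1, seed = 3)
  s2 <- generate_centres(cfg2, seed = 3)
  expect_equal(s2[1:15, ], s1)
  cl1 <- generate_claims(s1, cfg1, seed = 3)$claims
  cl2 <- generate_claims(s2, cfg2, seed = 3)$claims
  expect_equal(cl2[cl2$centre_id %in% s1$centre_id, ], cl1)
})

test_that("digit rounding forces last digits onto multiples of the base", {
  cfg <- small_config(fraud_prevalence = c(volume_inflation = 0,
                                           positivity_suppression = 0,
                                           digit_rounding = 1, fabrication = 0))
  sim <- simulate_claims(cfg, seed = 9)
  expect_true(all(sim$claims$n_tests %% 5 == 0))
  expect_true(all(last_digit(sim$claims$n_tests) %in% c(0L, 5L)))
})

test_that("fabrication confines volumes to the configured band", {
  cfg <- small_config(fraud_prevalence = c(volume_inflation = 0,
                                           positivity_suppression = 0,
                                           digit_rounding = 0, fabrication = 1))
  sim <- simulate_claims(cfg, seed = 9)
  expect_true(all(sim$claims$n_tests >= 480 & sim$claims$n_tests <= 520))
})

test_that("honest pooled positivity tracks a flat weekly curve", {
  # With a constant 2% curve, no centre heterogeneity and no fraud, pooled
  # positives/tests is binomial around 0.02; at the ~200k tests generated
  # here the 99.9% interval is well inside [0.017, 0.023].
  w <- study_window("2021-04-08", "2021-12-31")
  cfg <- simulation_config(
    n_centres = c(private = 180L), window = w,
    fraud_prevalence = c(volume_inflation = 0, positivity_suppression = 0,
                         digit_rounding = 0, fabrication = 0),
    weekly_positivity = rep(0.02, w$n_weeks), centre_pos_sd = 0)
  sim <- simulate_claims(cfg, seed = 21)
  expect_gt(nrow(sim$claims), 10000)
  pooled <- sum(sim$claims$n_positive) / sum(sim$claims$n_tests)
  expect_gt(pooled, 0.017)
  expect_lt(pooled, 0.023)
})

test_that("honest centres with wide daily spread approach Benford's law", {
  # Leading-digit chi-squared of honest centres should exceed the 0.95
  # quantile of chi-squared(8) for about 5% of centres once the day-level
  # spread is wide (log10-sd 0.8) and centres have >= 300 active days.
  cfg <- simulation_config(
    n_centres = c(private = 400L),
    fraud_prevalence = c(volume_inflation = 0, positivity_suppression = 0,
                         digit_rounding = 0, fabrication = 0),
    day_sdlog = 0.8 * log(10),
    lifetime_median = 600, lifetime_sdlog = 0.1, activity_range = c(0.9, 1))
  sim <- simulate_claims(cfg, seed = 1)
  s <- summarise_centres(sim$claims)
  keep <- s$n_active_days >= 300
  expect_gt(sum(keep), 100)
  chi2 <- vapply(which(keep), function(i)
    digit_chi2(s$leading_digits[[i]], benford_probability(1:9)), 0)
  exceed <- mean(chi2 > qchisq(0.95, 8))
  expect_gt(exceed, 0.03)
  expect_lt(exceed, 0.07)
})

test_that("fabricated narrow-band counts concentrate leading digits above honest levels", {
  cfg <- simulation_config(
    n_centres = c(private = 120L),
    fraud_prevalence = c(volume_inflation = 0, positivity_suppression = 0,
                         digit_rounding = 0, fabrication = 0.25),
    lifetime_median = 600, lifetime_sdlog = 0.2, activity_range = c(0.9, 1))
  sim <- simulate_claims(cfg, seed = 13)
  s <- summarise_centres(sim$claims)
  fab <- vapply(sim$truth$behaviours, function(v) "fabrication" %in% v, TRUE)
  fab <- fab[match(s$centre_id, sim$truth$centre_id)]
  chi2 <- vapply(seq_len(nrow(s)), function(i)
    digit_chi2(s$leading_digits[[i]], benford_probability(1:9)), 0)
  # band 480..520: essentially all mass on leading digits 4 and 5
  lead_mass <- vapply(which(fab), function(i) {
    p <- s$leading_digits[[i]] / sum(s$leading_digits[[i]])
    p[4] + p[5]
  }, 0)
  expect_true(all(lead_mass == 1))
  expect_gt(min(chi2[fab]), median(chi2[!fab]))
  expect_lt(suppressWarnings(wilcox.test(chi2[fab], chi2[!fab],
                                         alternative = "greater"))$p.value, 1e-6)
})

test_that("a degenerate config is rejected and labels are well-formed", {
  expect_error(simulation_config(n_centres = c(private = 0L)), "positive")
  expect_error(simulation_config(fraud_prevalence = c(volume_inflation = 1.2,
    positivity_suppression = 0, digit_rounding = 0, fabrication = 0)), "\\[0, 1\\]")
  expect_error(simulation_config(suppression_factor = 0), "suppression_factor")
  sim <- simulate_claims(small_config(), seed = 4)
  expect_true(all(sim$truth$suspected_conventional %in% 0:1))
  expect_true(all(sim$truth$corroborated %in% 0:1))
  expect_equal(sim$truth$is_fraud, lengths(sim$truth$behaviours) > 0)
})
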