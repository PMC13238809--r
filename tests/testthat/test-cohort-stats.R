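test_that("fraction summaries copy the MU report and keep identities", {
  plan <- toy_plan(2)
  res <- compare_fraction(plan, as_delivery(plan))
  s <- summarize_fraction(res)
  expect_equal(s$percent_skipped, 0)
  expect_equal(s$n_plan_events, 100L)
  withskip <- compare_fraction(plan, drop_events(plan, 0L, 0L, 9L))
  s2 <- summarize_fraction(withskip)
  expect_equal(s2$n_skipped, 1L)
  expect_equal(s2$percent_mu_reduction, s2$percent_skipped,
               tolerance = 1e-12)
})

test_that("patient summaries use sample statistics with hand-checked values", {
  fr <- data.frame(patient_id = "A", fraction = 1:3,
                   n_plan_events = 100L, n_skipped = c(1L, 2L, 3L),
                   percent_skipped = c(1, 2, 3),
                   mu_reduction = c(1, 2, 3) / 3,
                   percent_mu_reduction = c(1, 2, 3))
  s <- summarize_patient(fr)
  expect_equal(s$mean_skipped, 2)
  expect_equal(s$sd_skipped, 1)   # sample SD of {1,2,3}
  expect_equal(s$min_skipped, 1)
  expect_equal(s$max_skipped, 3)
  expect_equal(s$mean_percent_skipped, 2)
  expect_true(s$min_skipped <= s$mean_skipped &&
                s$mean_skipped <= s$max_skipped)
})

test_that("a single fraction gives SD 0 and is flagged by n_fractions", {
  fr <- data.frame(patient_id = "A", fraction = 1L, n_plan_events = 10L,
                   n_skipped = 4L, percent_skipped = 40,
                   mu_reduction = 4 / 3, percent_mu_reduction = 40)
  s <- summarize_patient(fr)
  expect_equal(s$n_fractions, 1L)
  expect_equal(s$mean_skipped, 4)
  expect_equal(s$sd_skipped, 0)
  expect_error(summarize_patient(fr[0, ]), "at least one")
  fr2 <- rbind(fr, transform(fr, patient_id = "B"))
  expect_error(summarize_patient(fr2), "multiple patient_ids")
})

test_that("the representative course reproduces the printed skip percentages", {
  # 20 fractions averaging 21.1 skips over 11,726 planned beam-on positions
  skips <- c(rep(22L, 18), 11L, 15L)
  expect_equal(mean(skips), 21.1)
  fr <- data.frame(patient_id = "R", fraction = 1:20,
                   n_plan_events = 11726L, n_skipped = skips,
                   percent_skipped = 100 * skips / 11726,
                   mu_reduction = skips / 3,
                   percent_mu_reduction = 100 * skips / 11726)
  s <- summarize_patient(fr)
  expect_equal(round(s$mean_percent_skipped, 2), 0.18)
})

test_that("linear_fit agrees with the closed-form normal equations", {
  set.seed(14)
  x <- runif(10, 0, 100)
  y <- 2.5 * x - 7 + rnorm(10)
  fit <- linear_fit(x, y)
  # independent closed-form oracle
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  expect_equal(fit$slope, slope, tolerance = 1e-9)
  expect_equal(fit$intercept, intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, r2, tolerance = 1e-9)
  expect_equal(fit$pearson_r, r, tolerance = 1e-9)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-9)
})

test_that("linear_fit handles exact and degenerate geometries", {
  x <- c(10, 20, 35, 50)
  fit <- linear_fit(x, x / 3)
  expect_equal(round(fit$r_squared, 3), 1)
  expect_equal(fit$slope, 1 / 3, tolerance = 1e-12)
  two <- linear_fit(c(1, 2), c(5, 9))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)
  expect_error(linear_fit(c(1), c(2)), "at least 2")
  expect_error(linear_fit(c(3, 3, 3), c(1, 2, 3)), "identical")
})

test_that("Pearson r is invariant to affine rescaling", {
  set.seed(2)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20, sd = 0.3)
  r0 <- linear_fit(x, y)$pearson_r
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    c_ <- runif(1, 0.1, 10); d <- rnorm(1)
    expect_equal(linear_fit(a * x + b, c_ * y + d)$pearson_r, r0,
                 tolerance = 1e-9)
  }
})

test_that("cohort fits capture the proportionality and association structure", {
  mu_const <- mu_per_firing_position(default_spec())
  # proportional mean MU reduction: R^2 = 1 and slope = the MU constant
  patients <- data.frame(
    patient_id = sprintf("P%d", 1:5),
    n_fractions = 5L,
    n_plan_events = c(9000L, 12000L, 15000L, 18000L, 21000L),
    mean_skipped = c(17, 23, 28, 35, 40),
    sd_skipped = 1, min_skipped = 10, max_skipped = 45,
    mean_percent_skipped = 100 * c(17, 23, 28, 35, 40) /
      c(9000, 12000, 15000, 18000, 21000),
    sd_percent_skipped = 0.01,
    mean_mu_reduction = mu_const * c(17, 23, 28, 35, 40),
    max_transition_rate = c(150, 210, 180, 260, 120),
    avg_transition_rate = c(50, 70, 60, 85, 40))
  cs <- cohort_summary(patients)
  expect_equal(cs$fit_mu_vs_skipped$r_squared, 1, tolerance = 1e-9)
  expect_equal(round(cs$fit_mu_vs_skipped$r_squared, 3), 1.000)
  expect_equal(cs$fit_mu_vs_skipped$slope, mu_const, tolerance = 1e-9)
  expect_equal(cs$fit_mu_vs_skipped$intercept, 0, tolerance = 1e-6)
  # skips grow with plan size -> positive association, cross-checked
  # against the direct Pearson formula
  x <- patients$n_plan_events; y <- patients$mean_skipped
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_gt(cs$fit_skipped_vs_total$pearson_r, 0)
  expect_equal(cs$fit_skipped_vs_total$pearson_r, r_direct,
               tolerance = 1e-9)
  expect_true(is.finite(cs$corr_skiprate_vs_transition))
  # two patients: both fits are exact lines
  cs2 <- cohort_summary(patients[1:2, ])
  expect_equal(cs2$fit_skipped_vs_total$r_squared, 1, tolerance = 1e-12)
  expect_equal(cs2$fit_mu_vs_skipped$r_squared, 1, tolerance = 1e-12)
  # one patient: fits omitted with a warning
  expect_warning(cs1 <- cohort_summary(patients[1, ]), "fewer than 2")
  expect_null(cs1$fit_mu_vs_skipped)
})

test_that("the cohort table renders mean +/- SD (range) rows", {
  cfg <- tiny_config(seed = 3L)
  analysis <- summarize_cohort(generate_cohort(cfg))
  lines <- format(analysis$summary)
  expect_true(any(grepl("Firing positions in the treatment plan", lines)))
  expect_true(any(grepl("±", lines)))
  expect_true(any(grepl("transition rate", lines)))
})

test_that("percent MU reduction equals percent skipped at every level", {
  cfg <- tiny_config(seed = 11L, skip_prob = 0.05)
  analysis <- summarize_cohort(generate_cohort(cfg))
  fr <- analysis$fractions
  expect_equal(fr$percent_mu_reduction, fr$percent_skipped,
               tolerance = 1e-9)
  p <- analysis$patients
  expect_equal(p$mean_mu_reduction / p$n_plan_events * 100 /
                 mu_per_firing_position(default_spec()),
               p$mean_percent_skipped, tolerance = 1e-9)
})
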