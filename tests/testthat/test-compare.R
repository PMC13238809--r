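test_that("indexing keeps only nonzero-MU events and enforces unique keys", {
  mu_const <- mu_per_firing_position(default_spec())
  seq <- toy_sequence(couch = rep(0L, 5), rotation = rep(0L, 5),
                      firing = 0:4,
                      mu = c(mu_const, 0, mu_const, 0, mu_const))
  idx <- index_events(seq)
  expect_equal(nrow(idx), 3L)
  expect_identical(idx$firing_index, c(0L, 2L, 4L))

  empty <- toy_sequence()
  expect_equal(nrow(index_events(empty)), 0L)

  dup <- toy_sequence(couch = c(0L, 0L), rotation = c(0L, 0L),
                      firing = c(3L, 3L))
  expect_error(index_events(dup), "duplicate")
})

test_that("an identical delivery has no skips and no misfires", {
  plan <- toy_plan(2)
  delivery <- as_delivery(plan)
  expect_equal(nrow(find_skipped(plan, delivery)), 0L)
  expect_equal(nrow(find_misfires(plan, delivery)), 0L)
  res <- compare_fraction(plan, delivery)
  expect_equal(res$mu_report$mu_reduction, 0)
  expect_equal(res$mu_report$percent_reduction, 0)
})

test_that("events removed from the delivery are reported as skipped, in plan order", {
  plan <- toy_plan(4)
  delivery <- drop_events(plan, couch = c(2L, 3L), rotation = c(0L, 0L),
                          firing = c(10L, 40L))
  skipped <- find_skipped(plan, delivery)
  expect_equal(nrow(skipped), 2L)
  expect_identical(skipped$couch_index, c(2L, 3L))
  expect_identical(skipped$firing_index, c(10L, 40L))
})

test_that("comparison preconditions are enforced", {
  plan <- toy_plan(1)
  other <- toy_plan(1, patient_id = "T2")
  expect_error(find_skipped(plan, other), "patient_id")
  delivery <- as_delivery(plan)
  expect_error(find_skipped(delivery, delivery), "fraction = 0")
  alien <- toy_plan(1, spec = machine_spec(gantry_rpm = 30))
  alien$patient_id <- plan$patient_id
  expect_error(find_skipped(plan, as_delivery(alien)), "specs differ")
})

test_that("misfires are classified as unplanned, mask-mismatch, or mu-anomaly", {
  plan <- toy_plan(2)
  mu_const <- mu_per_firing_position(plan$spec)

  # delivery strictly inside the plan -> no misfires
  sub <- drop_events(plan, 0L, 0L, 7L)
  expect_equal(nrow(find_misfires(plan, sub)), 0L)

  # extra event at an unplanned key
  extra <- as_delivery(plan)
  ev <- extra$events
  new <- ev[nrow(ev), , drop = FALSE]
  new$rotation_index <- 1L
  new$event_index <- new$event_index + 1L
  extra$events <- rbind(ev, new)
  mf <- find_misfires(plan, extra)
  expect_equal(nrow(mf), 1L)
  expect_equal(mf$reason, "unplanned")

  # one leaf flipped on a matched event
  flipped <- as_delivery(plan)
  mask <- flipped$events$leaf_mask[10]
  substr(mask, 1, 1) <- if (substr(mask, 1, 1) == "1") "0" else "1"
  flipped$events$leaf_mask[10] <- mask
  mf <- find_misfires(plan, flipped)
  expect_equal(nrow(mf), 1L)
  expect_equal(mf$reason, "mask-mismatch")

  # anomalous MU on a matched event
  wrong_mu <- as_delivery(plan)
  wrong_mu$events$mu[5] <- mu_const * 2
  mf <- find_misfires(plan, wrong_mu)
  expect_equal(nrow(mf), 1L)
  expect_equal(mf$reason, "mu-anomaly")
})

test_that("MU reconciliation follows the constant-quantum arithmetic", {
  plan <- toy_plan(1)  # 50 beam-on events
  delivery <- drop_events(plan, c(0L, 0L, 0L, 0L, 0L), rep(0L, 5),
                          c(1L, 2L, 3L, 4L, 5L))
  mu_const <- mu_per_firing_position(plan$spec)
  rep <- reconcile_mu(plan, delivery)
  expect_equal(rep$n_plan_events, 50L)
  expect_equal(rep$n_skipped, 5L)
  expect_equal(rep$mu_reduction, 5 * mu_const, tolerance = 1e-12)
  expect_equal(rep$percent_skipped, 10)
  expect_equal(rep$percent_reduction, rep$percent_skipped,
               tolerance = 1e-12)
  expect_error(
    reconcile_mu(toy_sequence(couch = 0L, rotation = 0L, firing = 0L,
                              mu = 0),
                 toy_sequence(fraction = 1L)),
    "no nonzero-MU")
})

test_that("representative-fraction skip arithmetic reproduces printed precision", {
  # 22 skipped of 11,726 planned beam-on positions -> 0.19% at 2 d.p.
  expect_equal(round(100 * 22 / 11726, 2), 0.19)
})

test_that("compare_fraction bundles skips, misfires, and MU consistently", {
  plan <- toy_plan(3)
  delivery <- drop_events(plan, c(0L, 2L), c(0L, 0L), c(3L, 44L))
  # add one unplanned event too
  ev <- delivery$events
  new <- ev[nrow(ev), , drop = FALSE]
  new$rotation_index <- 5L
  new$event_index <- new$event_index + 1L
  delivery$events <- rbind(ev, new)
  res <- compare_fraction(plan, delivery)
  expect_equal(res$mu_report$n_skipped, 2L)
  expect_equal(nrow(res$skipped), 2L)
  expect_equal(nrow(res$misfires), 1L)
  expect_equal(res$misfires$reason, "unplanned")
  expect_equal(nrow(res$leaf_discrepancies), 0L)
})

test_that("comparison recovers simulator ground truth across fault rates", {
  cases <- expand.grid(skip_prob = c(0, 0.01, 0.2), seed = 1:5)
  plan <- generate_plan(tiny_config(seed = 99L, n_patients = 1L), 1L)
  for (i in seq_len(nrow(cases))) {
    fx <- simulate_delivery(plan, fraction = 1L,
                            skip_prob = cases$skip_prob[i],
                            seed = 7000L + i)
    res <- compare_fraction(plan, fx$delivery)
    truth <- fx$ground_truth$skipped_keys
    expect_equal(nrow(res$skipped), nrow(truth))
    expect_identical(res$skipped$couch_index, truth$couch_index)
    expect_identical(res$skipped$rotation_index, truth$rotation_index)
    expect_identical(res$skipped$firing_index, truth$firing_index)
    expect_equal(nrow(res$misfires), 0L)
  }
})

test_that("injected misfires are recovered exactly", {
  plan <- generate_plan(tiny_config(seed = 5L, n_patients = 1L), 1L)
  fx <- simulate_delivery(plan, fraction = 1L, skip_prob = 0.001,
                          misfire_prob = 0.005, seed = 42L)
  res <- compare_fraction(plan, fx$delivery)
  truth <- fx$ground_truth$misfire_keys
  expect_gt(nrow(truth), 0L)
  expect_equal(nrow(res$misfires), nrow(truth))
  expect_true(all(res$misfires$reason == "mask-mismatch"))
  expect_identical(
    paste(res$misfires$couch_index, res$misfires$rotation_index,
          res$misfires$firing_index),
    paste(truth$couch_index, truth$rotation_index, truth$firing_index))
  expect_equal(nrow(res$leaf_discrepancies), nrow(truth))
  # exactly one leaf differs per discrepancy
  for (i in seq_len(nrow(res$leaf_discrepancies))) {
    a <- utf8ToInt(res$leaf_discrepancies$plan_mask[i])
    b <- utf8ToInt(res$leaf_discrepancies$delivered_mask[i])
    expect_equal(sum(a != b), 1L)
  }
})

test_that("each additional skip reduces MU by exactly one machine constant", {
  plan <- toy_plan(2)
  mu_const <- mu_per_firing_position(plan$spec)
  d1 <- drop_events(plan, 0L, 0L, 10L)
  d2 <- drop_events(plan, c(0L, 1L), c(0L, 0L), c(10L, 20L))
  r1 <- reconcile_mu(plan, d1)
  r2 <- reconcile_mu(plan, d2)
  expect_equal(r2$mu_reduction - r1$mu_reduction, mu_const,
               tolerance = 1e-12)
})

test_that("comparison results serialize to the documented JSON report", {
  plan <- toy_plan(2)
  delivery <- drop_events(plan, 1L, 0L, 30L)
  res <- compare_fraction(plan, delivery)
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison_json(res, path)
  report <- jsonlite::read_json(path)
  expect_equal(report$n_skipped, 1L)
  expect_equal(report$n_plan_events, 100L)
  expect_equal(length(report$skipped_keys), 1L)
  expect_equal(report$mu$reduction,
               mu_per_firing_position(plan$spec), tolerance = 1e-9)
})
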