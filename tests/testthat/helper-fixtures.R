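# Small builders shared across the suite. Everything is generated in code;
# no fixture files.

# a compact configuration: short target, few rotations, quick to simulate
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_patients = 2L,
    ptv_length_mm_range = c(20, 40),
    couch_margin_steps = 0L,
    rotations_per_couch_range = c(1L, 2L),
    fractions_range = c(2L, 3L),
    seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# mask string with the given leaves (1-based positions) open
mask_with_open <- function(open_leaves, n_leaves = 64L) {
  bits <- rep("0", n_leaves)
  bits[open_leaves] <- "1"
  paste(bits, collapse = "")
}

# hand-built sequence: one event per row of the supplied key matrix
toy_sequence <- function(patient_id = "T1", fraction = 0L,
                         couch = integer(), rotation = integer(),
                         firing = integer(), mu = NULL, masks = NULL,
                         spec = default_spec()) {
  n <- length(couch)
  mu_const <- mu_per_firing_position(spec)
  if (is.null(mu)) mu <- rep(mu_const, n)
  if (is.null(masks)) masks <- rep(mask_with_open(1:8), n)
  events <- data.frame(
    event_index = seq_len(n) - 1L,
    couch_index = couch,
    couch_mm = couch * spec$couch_step_mm,
    rotation_index = rotation,
    firing_index = firing,
    gantry_deg = gantry_angle_of(firing, 0, spec),
    mu = mu,
    leaf_mask = masks,
    stringsAsFactors = FALSE
  )
  beamlet_sequence(patient_id, fraction, events, spec)
}

# a small plan covering n_couch couch positions, one rotation each,
# all firing positions beam-on
toy_plan <- function(n_couch = 2L, patient_id = "T1", spec = default_spec()) {
  fp <- spec$fp_per_rotation
  toy_sequence(
    patient_id = patient_id, fraction = 0L,
    couch = rep(seq_len(n_couch) - 1L, each = fp),
    rotation = rep(0L, n_couch * fp),
    firing = rep(seq_len(fp) - 1L, n_couch),
    spec = spec
  )
}

# drop the events at the given (couch, rotation, firing) keys and renumber
drop_events <- function(seq, couch, rotation, firing, fraction = 1L) {
  keys <- paste(couch, rotation, firing, sep = ":")
  ev <- seq$events
  ev_keys <- paste(ev$couch_index, ev$rotation_index, ev$firing_index,
                   sep = ":")
  ev <- ev[!(ev_keys %in% keys), , drop = FALSE]
  ev$event_index <- seq_len(nrow(ev)) - 1L
  beamlet_sequence(seq$patient_id, fraction, ev, seq$spec, seq$plan_mu)
}

# reuse a plan's events as a delivered fraction
as_delivery <- function(plan, fraction = 1L) {
  beamlet_sequence(plan$patient_id, fraction, plan$events, plan$spec,
                   plan$plan_mu)
}

expect_same_sequence <- function(a, b) {
  expect_identical(a$patient_id, b$patient_id)
  expect_identical(a$fraction, b$fraction)
  expect_equal(a$plan_mu, b$plan_mu, tolerance = 1e-6)
  expect_identical(nrow(a$events), nrow(b$events))
  for (col in c("event_index", "couch_index", "rotation_index",
                "firing_index", "leaf_mask")) {
    expect_identical(a$events[[col]], b$events[[col]])
  }
  expect_true(all(abs(a$events$couch_mm - b$events$couch_mm) <= 1e-3))
  expect_true(all(abs(a$events$gantry_deg - b$events$gantry_deg) <= 1e-3))
  expect_true(all(abs(a$events$mu - b$events$mu) <= 1e-6))
}
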