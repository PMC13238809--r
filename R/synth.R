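#' Configuration for the synthetic plan generator and delivery simulator
#'
#' The simulator emulates the delivery mechanics of a ring-gantry machine
#' with a binary MLC: one-pass couch motion on a 2.1 mm grid, complete
#' gantry rotations of `fp_per_rotation` firing events per stationary couch
#' segment, a constant MU quantum at beam-on positions, and contiguous-run
#' binary apertures. Skips are independent Bernoulli draws per nonzero-MU
#' firing position, reflecting transient hardware faults that are not
#' correlated with beam modulation; misfires flip one leaf of a retained
#' event.
#'
#' Defaults describe the study conditions the toolkit targets: target
#' lengths of 43-200 mm, 5-33 fractions per patient, a skip probability of
#' 0.0019 (calibrated so a ~16,000-position plan skips about 30 positions,
#' a 0.19% rate), no misfires, and 30% zero-MU firing positions.
#'
#' @param n_patients Number of patients in a cohort.
#' @param ptv_length_mm_range Min/max target length along the couch, mm.
#' @param couch_margin_steps Extra couch steps added on each end of the
#'   target.
#' @param rotations_per_couch_range Min/max complete gantry rotations per
#'   stationary couch segment.
#' @param aperture_model One of `"random-contiguous"` (one contiguous open
#'   run per event, random position and width), `"sweep"` (the run drifts
#'   one leaf per firing position), `"static"` (fixed run).
#' @param open_fraction_range Min/max fraction of leaves open per event.
#' @param zero_mu_fraction Probability that a firing position carries zero
#'   MU (leaves still move; the pulse is withheld by the plan).
#' @param skip_prob Per-position probability that delivery skips a
#'   nonzero-MU firing position.
#' @param misfire_prob Per-position probability that a retained nonzero-MU
#'   event is delivered with one leaf flipped.
#' @param fractions_range Min/max number of treatment fractions per
#'   patient.
#' @param seed Integer master seed; all randomness derives from it through
#'   per-patient/per-fraction substreams.
#' @param spec A [machine_spec()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 10L,
                         ptv_length_mm_range = c(43, 200),
                         couch_margin_steps = 3L,
                         rotations_per_couch_range = c(5L, 9L),
                         aperture_model = c("random-contiguous", "sweep",
                                            "static"),
                         open_fraction_range = c(0.1, 0.6),
                         zero_mu_fraction = 0.3,
                         skip_prob = 0.0019,
                         misfire_prob = 0,
                         fractions_range = c(5L, 33L),
                         seed = 1L,
                         spec = default_spec()) {
  aperture_model <- match.arg(aperture_model)
  cfg <- list(
    n_patients = as.integer(n_patients),
    ptv_length_mm_range = as.numeric(ptv_length_mm_range),
    couch_margin_steps = as.integer(couch_margin_steps),
    rotations_per_couch_range = as.integer(rotations_per_couch_range),
    aperture_model = aperture_model,
    open_fraction_range = as.numeric(open_fraction_range),
    zero_mu_fraction = as.numeric(zero_mu_fraction),
    skip_prob = as.numeric(skip_prob),
    misfire_prob = as.numeric(misfire_prob),
    fractions_range = as.integer(fractions_range),
    seed = as.integer(seed),
    spec = spec
  )
  if (cfg$n_patients < 1L) {
    stop("synth_config: n_patients must be >= 1", call. = FALSE)
  }
  for (nm in c("ptv_length_mm_range", "rotations_per_couch_range",
               "open_fraction_range", "fractions_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop("synth_config: ", nm, " must be an ordered (min, max) pair",
           call. = FALSE)
    }
  }
  if (cfg$ptv_length_mm_range[1] <= 0 || cfg$fractions_range[1] < 1L) {
    stop("synth_config: degenerate range", call. = FALSE)
  }
  if (cfg$rotations_per_couch_range[1] < 1L) {
    stop("synth_config: rotations_per_couch_range must be >= 1",
         call. = FALSE)
  }
  if (cfg$open_fraction_range[1] < 0 || cfg$open_fraction_range[2] > 1) {
    stop("synth_config: open_fraction_range must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$couch_margin_steps < 0L) {
    stop("synth_config: couch_margin_steps must be >= 0", call. = FALSE)
  }
  for (nm in c("zero_mu_fraction", "skip_prob", "misfire_prob")) {
    p <- cfg[[nm]]
    if (length(p) != 1L || is.na(p) || p < 0 || p >= 1) {
      # skip_prob = 1 (skip everything) is allowed as a saturation case
      if (!(nm == "skip_prob" && isTRUE(p == 1))) {
        stop("synth_config: ", nm, " must lie in [0, 1)", call. = FALSE)
      }
    }
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patient(s), %d-%d fractions, seed %d\n",
              x$n_patients, x$fractions_range[1], x$fractions_range[2],
              x$seed))
  cat(sprintf("  target length %g-%g mm (+%d margin steps), %d-%d rotations/couch\n",
              x$ptv_length_mm_range[1], x$ptv_length_mm_range[2],
              x$couch_margin_steps, x$rotations_per_couch_range[1],
              x$rotations_per_couch_range[2]))
  cat(sprintf("  aperture %s (open fraction %g-%g), zero-MU %g\n",
              x$aperture_model, x$open_fraction_range[1],
              x$open_fraction_range[2], x$zero_mu_fraction))
  cat(sprintf("  skip_prob %g, misfire_prob %g\n", x$skip_prob,
              x$misfire_prob))
  invisible(x)
}

# deterministic per-(patient, fraction) substream seed in [0, 2^31-2];
# multiplicative-congruential mixing keeps every product exact in doubles
substream_seed <- function(seed, patient_index, fraction) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  h <- (h * 69069 + patient_index + 1) %% m
  h <- (h * 69069 + fraction + 1) %% m
  as.integer(h)
}

# one contiguous open run per event -> 0/1 mask strings
make_masks <- function(n_events, config) {
  nl <- config$spec$n_leaves
  fr <- config$open_fraction_range
  model <- config$aperture_model
  if (model == "random-contiguous") {
    len <- pmax(1L, round(stats::runif(n_events, fr[1], fr[2]) * nl))
    len <- pmin(len, nl)
    start <- floor(stats::runif(n_events) * (nl - len + 1))
  } else {
    len0 <- max(1L, min(nl, round(mean(fr) * nl)))
    len <- rep(len0, n_events)
    start0 <- floor(stats::runif(1) * (nl - len0 + 1))
    start <- if (model == "sweep") {
      (start0 + seq_len(n_events) - 1L) %% (nl - len0 + 1L)
    } else {
      rep(start0, n_events)
    }
  }
  idx <- seq_len(nl) - 1L
  open <- outer(start, idx, "<=") & outer(start + len - 1L, idx, ">=")
  chars <- c("0", "1")
  cols <- lapply(seq_len(nl), function(j) chars[open[, j] + 1L])
  do.call(paste0, cols)
}

#' Generate a synthetic treatment plan
#'
#' Draws a target length, lays out couch segments on the machine's couch
#' grid (plus margin steps), fills each stationary segment with complete
#' gantry rotations of `fp_per_rotation` firing events, assigns the machine
#' MU constant to each event with probability `1 - zero_mu_fraction`, and
#' builds contiguous-run binary apertures per the configured model. Every
#' rotation starts at gantry angle 0 and the couch advances monotonically,
#' so generated plans pass [validate_sequence()] by construction.
#'
#' @param config A [synth_config()].
#' @param patient_index Positive integer; selects the per-patient random
#'   substream and names the patient `P<index>`.
#' @return A plan [beamlet_sequence()] (`fraction = 0`).
#' @export
generate_plan <- function(config, patient_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  spec <- config$spec
  fp <- spec$fp_per_rotation
  set.seed(substream_seed(config$seed, patient_index, 0L))
  L <- stats::runif(1, config$ptv_length_mm_range[1],
                    config$ptv_length_mm_range[2])
  n_couch <- as.integer(ceiling(L / spec$couch_step_mm)) +
    2L * config$couch_margin_steps
  rr <- config$rotations_per_couch_range
  rot_per_couch <- if (rr[1] == rr[2]) {
    rep(rr[1], n_couch)
  } else {
    sample(rr[1]:rr[2], n_couch, replace = TRUE)
  }
  ev_per_couch <- rot_per_couch * fp
  n <- sum(ev_per_couch)
  couch_index <- rep(seq_len(n_couch) - 1L, ev_per_couch)
  rotation_index <- unlist(lapply(rot_per_couch, function(r) {
    rep(seq_len(r) - 1L, each = fp)
  }), use.names = FALSE)
  firing_index <- sequence(rep(fp, sum(rot_per_couch))) - 1L
  mu_const <- mu_per_firing_position(spec)
  mu <- mu_const * (stats::runif(n) >= config$zero_mu_fraction)
  events <- data.frame(
    event_index = seq_len(n) - 1L,
    couch_index = couch_index,
    couch_mm = couch_index * spec$couch_step_mm,
    rotation_index = rotation_index,
    firing_index = firing_index,
    gantry_deg = gantry_angle_of(firing_index, 0, spec),
    mu = mu,
    leaf_mask = make_masks(n, config),
    stringsAsFactors = FALSE
  )
  beamlet_sequence(
    patient_id = sprintf("P%02d", patient_index),
    fraction = 0L,
    events = events,
    spec = spec,
    plan_mu = sum(mu > 0) * mu_const
  )
}

#' Simulate one delivered fraction with fault injection
#'
#' Each nonzero-MU plan event is independently omitted with probability
#' `skip_prob` (a skipped firing position); with probability
#' `misfire_prob`, a retained nonzero-MU event is delivered with one
#' uniformly chosen leaf flipped (a mask-mismatch misfire). Zero-MU events
#' pass through unchanged. The injected faults are returned as ground
#' truth, keyed by `(couch_index, rotation_index, firing_index)`, so every
#' analysis stage can be checked against what the simulator actually did.
#'
#' @param plan A plan [beamlet_sequence()].
#' @param fraction Fraction number to assign to the delivery (>= 1).
#' @param skip_prob,misfire_prob Fault probabilities in `[0, 1]` /
#'   `[0, 1)`.
#' @param seed Integer seed for this fraction's random substream.
#' @return List with `delivery` (a `beamlet_sequence`) and `ground_truth`
#'   (list of `skipped_keys` and `misfire_keys` data frames with columns
#'   `couch_index`, `rotation_index`, `firing_index`).
#' @export
simulate_delivery <- function(plan, fraction = 1L, skip_prob = 0.0019,
                              misfire_prob = 0, seed = 1L) {
  stopifnot(inherits(plan, "beamlet_sequence"))
  if (skip_prob < 0 || skip_prob > 1) {
    stop("simulate_delivery: skip_prob must lie in [0, 1]", call. = FALSE)
  }
  if (misfire_prob < 0 || misfire_prob >= 1) {
    stop("simulate_delivery: misfire_prob must lie in [0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  ev <- plan$events
  nz <- ev$mu > 0
  skip <- nz & stats::runif(nrow(ev)) < skip_prob
  key_cols <- c("couch_index", "rotation_index", "firing_index")
  skipped_keys <- ev[skip, key_cols, drop = FALSE]
  rownames(skipped_keys) <- NULL
  ev <- ev[!skip, , drop = FALSE]
  nz <- ev$mu > 0
  misfire <- nz & stats::runif(nrow(ev)) < misfire_prob
  misfire_keys <- ev[misfire, key_cols, drop = FALSE]
  rownames(misfire_keys) <- NULL
  if (any(misfire)) {
    nl <- plan$spec$n_leaves
    for (i in which(misfire)) {
      leaf <- sample.int(nl, 1L)
      mask <- ev$leaf_mask[i]
      bit <- substr(mask, leaf, leaf)
      substr(mask, leaf, leaf) <- if (bit == "1") "0" else "1"
      ev$leaf_mask[i] <- mask
    }
  }
  if (nrow(ev)) ev$event_index <- seq_len(nrow(ev)) - 1L
  delivery <- beamlet_sequence(
    patient_id = plan$patient_id,
    fraction = as.integer(fraction),
    events = ev,
    spec = plan$spec,
    plan_mu = plan$plan_mu
  )
  list(delivery = delivery,
       ground_truth = list(skipped_keys = skipped_keys,
                           misfire_keys = misfire_keys))
}

#' Generate a full synthetic cohort
#'
#' One plan per patient plus a per-patient number of simulated daily
#' fractions drawn from `fractions_range`. All randomness derives from
#' `config$seed` through per-patient/per-fraction substreams, so any
#' single plan or fraction is reproducible in isolation and the whole
#' cohort is deterministic for a fixed configuration.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort`, one element per patient:
#'   `plan` (a `beamlet_sequence`) and `fractions`, a list of
#'   [simulate_delivery()] results (`delivery` + `ground_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fr <- config$fractions_range
  cohort <- lapply(seq_len(config$n_patients), function(p) {
    plan <- generate_plan(config, p)
    set.seed(substream_seed(config$seed, p, 1000000L))
    n_fx <- if (fr[1] == fr[2]) fr[1] else sample(fr[1]:fr[2], 1L)
    fractions <- lapply(seq_len(n_fx), function(k) {
      simulate_delivery(plan, fraction = k,
                        skip_prob = config$skip_prob,
                        misfire_prob = config$misfire_prob,
                        seed = substream_seed(config$seed, p, k))
    })
    list(plan = plan, fractions = fractions)
  })
  structure(cohort, class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patient(s)\n", length(x)))
  for (pt in x) {
    cat(sprintf("  %s: %d events in plan (%d beam-on), %d fraction(s)\n",
                pt$plan$patient_id, nrow(pt$plan$events),
                sum(pt$plan$events$mu > 0), length(pt$fractions)))
  }
  invisible(x)
}

#' Write a cohort as a BLSQ directory tree
#'
#' Creates `<root>/<patient_id>/plan.blsq`, one `fx<k>.blsq` per fraction,
#' and a `fx<k>.truth.json` ground-truth file per fraction recording the
#' injected skipped and misfired keys.
#'
#' @param cohort A [generate_cohort()] result.
#' @param root Output directory (created if missing).
#' @return Invisibly, `root`.
#' @export
write_cohort <- function(cohort, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (pt in cohort) {
    pdir <- file.path(root, pt$plan$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    write_blsq(pt$plan, file.path(pdir, "plan.blsq"))
    for (k in seq_along(pt$fractions)) {
      fx <- pt$fractions[[k]]
      write_blsq(fx$delivery, file.path(pdir, sprintf("fx%d.blsq", k)))
      jsonlite::write_json(fx$ground_truth,
                           file.path(pdir, sprintf("fx%d.truth.json", k)),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(root)
}
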