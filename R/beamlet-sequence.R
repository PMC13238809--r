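#' Construct a beamlet sequence
#'
#' A beamlet sequence is the ordered list of beam firing events for one
#' treatment plan (`fraction = 0`) or one delivered fraction. Each event
#' records where the machine was (couch step, rotation and firing index,
#' gantry angle), how much it delivered (0 MU or the machine constant), and
#' the binary MLC aperture as a string of '0'/'1' characters, leaf 0 first.
#'
#' @param patient_id Patient identifier (text).
#' @param fraction Non-negative integer; 0 denotes the treatment plan.
#' @param events Data frame with columns `event_index`, `couch_index`,
#'   `couch_mm`, `rotation_index`, `firing_index`, `gantry_deg`, `mu`,
#'   `leaf_mask`. May have zero rows.
#' @param spec A [machine_spec()].
#' @param plan_mu Declared total plan MU (metadata). Defaults to the number
#'   of nonzero-MU events times the machine MU constant.
#' @return An object of class `beamlet_sequence`.
#' @seealso [read_blsq()], [write_blsq()], [validate_sequence()]
#' @export
beamlet_sequence <- function(patient_id, fraction, events,
                             spec = default_spec(), plan_mu = NULL) {
  stopifnot(inherits(spec, "machine_spec"))
  required <- c("event_index", "couch_index", "couch_mm", "rotation_index",
                "firing_index", "gantry_deg", "mu", "leaf_mask")
  if (!is.data.frame(events)) {
    stop("beamlet_sequence: events must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("beamlet_sequence: events missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events <- events[required]
  for (col in c("event_index", "couch_index", "rotation_index", "firing_index")) {
    events[[col]] <- as.integer(events[[col]])
  }
  for (col in c("couch_mm", "gantry_deg", "mu")) {
    events[[col]] <- as.numeric(events[[col]])
  }
  events$leaf_mask <- as.character(events$leaf_mask)
  rownames(events) <- NULL
  fraction <- as.integer(fraction)
  if (is.na(fraction) || fraction < 0L) {
    stop("beamlet_sequence: fraction must be a non-negative integer",
         call. = FALSE)
  }
  if (is.null(plan_mu)) {
    plan_mu <- sum(events$mu > 0) * mu_per_firing_position(spec)
  }
  structure(
    list(patient_id = as.character(patient_id),
         fraction = fraction,
         spec = spec,
         events = events,
         plan_mu = as.numeric(plan_mu)),
    class = "beamlet_sequence"
  )
}

#' @export
print.beamlet_sequence <- function(x, ...) {
  n <- nrow(x$events)
  nz <- sum(x$events$mu > 0)
  kind <- if (x$fraction == 0L) "plan" else sprintf("fraction %d", x$fraction)
  cat(sprintf("Beamlet sequence: patient %s, %s\n", x$patient_id, kind))
  cat(sprintf("  %d firing events (%d with beam on, %d zero-MU)\n",
              n, nz, n - nz))
  if (n > 0) {
    cat(sprintf("  couch %d position(s), %.1f to %.1f mm; plan MU %.1f\n",
                length(unique(x$events$couch_index)),
                min(x$events$couch_mm), max(x$events$couch_mm), x$plan_mu))
  }
  invisible(x)
}

# (couch, rotation, firing) key strings for event matching
event_key <- function(events) {
  paste(events$couch_index, events$rotation_index, events$firing_index,
        sep = ":")
}

# MU-comparison tolerance for "equal to the machine constant"
MU_TOL <- 1e-6

#' Validate a beamlet sequence against machine constraints
#'
#' Checks a sequence against the delivery mechanics of the machine: the
#' couch moves in one direction only and sits on the `couch_step_mm` grid;
#' gantry angles lie on the evenly spaced firing grid implied by each
#' rotation's start angle; every event delivers either 0 MU or the machine
#' constant; `(couch, rotation, firing)` keys are unique. Problems are
#' reported, not thrown: errors make `ok` false, while zero-MU events are
#' reported as informational warnings (they are legal and retained in
#' files; downstream analysis discards them).
#'
#' @param seq A `beamlet_sequence`.
#' @param couch_tol_mm Allowed deviation of `couch_mm` from the couch-step
#'   grid anchored at the sequence's first couch position, mm.
#' @param gantry_tol_deg Allowed deviation of `gantry_deg` from the firing
#'   grid, degrees.
#' @return An object of class `validation_report`: list with `ok` (logical)
#'   and `issues` (data frame with columns `severity`, `event_index`,
#'   `message`).
#' @export
validate_sequence <- function(seq, couch_tol_mm = 0.1, gantry_tol_deg = 0.5) {
  stopifnot(inherits(seq, "beamlet_sequence"))
  ev <- seq$events
  spec <- seq$spec
  issues <- list()
  add <- function(severity, event_index, message) {
    if (length(message) == 0) return()
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity,
      event_index = event_index,
      message = message,
      stringsAsFactors = FALSE
    )
  }
  n <- nrow(ev)
  if (n > 0) {
    # event order
    if (n > 1) {
      bad <- which(diff(ev$event_index) <= 0)
      add("error", ev$event_index[bad + 1L],
          rep("event_index not strictly increasing", length(bad)))
      # one-pass couch rule
      bad <- which(diff(ev$couch_mm) < 0)
      add("error", ev$event_index[bad + 1L],
          rep("couch_mm decreases (one-pass rule violated)", length(bad)))
    }
    # couch grid, anchored at the first event
    expected <- ev$couch_mm[1] +
      (ev$couch_index - ev$couch_index[1]) * spec$couch_step_mm
    bad <- which(abs(ev$couch_mm - expected) > couch_tol_mm)
    add("error", ev$event_index[bad],
        sprintf("couch_mm %.3f off the %.1f mm grid (expected %.3f)",
                ev$couch_mm[bad], spec$couch_step_mm, expected[bad]))
    # gantry grid: within each rotation, (gantry - firing * sector) must be
    # constant (the rotation's start angle); compare circularly to the
    # rotation's first event
    sector <- 360 / spec$fp_per_rotation
    resid <- (ev$gantry_deg - ev$firing_index * sector) %% 360
    rot_id <- paste(ev$couch_index, ev$rotation_index, sep = ":")
    first_resid <- resid[!duplicated(rot_id)]
    names(first_resid) <- rot_id[!duplicated(rot_id)]
    delta <- abs(resid - first_resid[rot_id])
    delta <- pmin(delta, 360 - delta)
    bad <- which(delta > gantry_tol_deg)
    add("error", ev$event_index[bad],
        sprintf("gantry_deg %.3f off the %.1f deg firing grid by %.3f deg",
                ev$gantry_deg[bad], sector, delta[bad]))
    # MU quantisation: 0 or the machine constant
    mu_const <- mu_per_firing_position(spec)
    bad <- which(ev$mu != 0 & abs(ev$mu - mu_const) > MU_TOL)
    add("error", ev$event_index[bad],
        sprintf("mu %.6f is neither 0 nor the machine constant %.6f",
                ev$mu[bad], mu_const))
    # leaf mask shape
    bad <- which(nchar(ev$leaf_mask) != spec$n_leaves |
                   grepl("[^01]", ev$leaf_mask))
    add("error", ev$event_index[bad],
        rep(sprintf("leaf_mask is not %d characters of 0/1", spec$n_leaves),
            length(bad)))
    # duplicate (couch, rotation, firing) keys
    key <- event_key(ev)
    bad <- which(duplicated(key))
    add("error", ev$event_index[bad],
        sprintf("duplicate (couch,rotation,firing) key %s", key[bad]))
    # zero-MU events are legal but noted
    zi <- which(ev$mu == 0)
    add("warning", ev$event_index[zi],
        rep("zero-MU firing position (discarded by analysis)", length(zi)))
  }
  issues <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(severity = character(), event_index = integer(),
               message = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(ok = !any(issues$severity == "error"), issues = issues),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  ne <- sum(x$issues$severity == "error")
  nw <- sum(x$issues$severity == "warning")
  cat(sprintf("Validation %s: %d error(s), %d warning(s)\n",
              if (x$ok) "OK" else "FAILED", ne, nw))
  show <- x$issues[x$issues$severity == "error", , drop = FALSE]
  if (nrow(show) > 10) show <- show[1:10, ]
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  [%s] event %s: %s\n", show$severity[i],
                show$event_index[i], show$message[i]))
  }
  if (ne > 10) cat(sprintf("  ... and %d more error(s)\n", ne - 10))
  invisible(x)
}
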