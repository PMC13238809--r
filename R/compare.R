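#' Index the nonzero-MU events of a sequence by machine position
#'
#' Builds the matching index used by the plan-vs-delivery comparison: every
#' firing event with nonzero MU, keyed by `(couch_index, rotation_index,
#' firing_index)`. Zero-MU events are discarded from the analysis and never
#' indexed. The machine fires on fixed couch and gantry grids, so integer
#' keys match unambiguously — no floating-point tolerance is involved.
#'
#' @param seq A [beamlet_sequence()].
#' @return The nonzero-MU events as a data frame with an added `key` column,
#'   one row per key.
#' @export
index_events <- function(seq) {
  stopifnot(inherits(seq, "beamlet_sequence"))
  ev <- seq$events[seq$events$mu > 0, , drop = FALSE]
  ev$key <- event_key(ev)
  dup <- duplicated(ev$key)
  if (any(dup)) {
    stop("index_events: duplicate (couch,rotation,firing) key among ",
         "nonzero-MU events: ", ev$key[dup][1], call. = FALSE)
  }
  rownames(ev) <- NULL
  ev
}

# shared precondition for all plan-vs-delivery comparisons
check_comparable <- function(plan, delivery) {
  stopifnot(inherits(plan, "beamlet_sequence"),
            inherits(delivery, "beamlet_sequence"))
  if (plan$fraction != 0L) {
    stop("plan sequence must have fraction = 0", call. = FALSE)
  }
  if (plan$patient_id != delivery$patient_id) {
    stop("plan and delivery patient_id differ ('", plan$patient_id,
         "' vs '", delivery$patient_id, "')", call. = FALSE)
  }
  if (!spec_equal(plan$spec, delivery$spec)) {
    stop("plan and delivery machine specs differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Find skipped firing positions
#'
#' A skipped firing position is a firing event with nonzero planned MU that
#' is missing from the daily delivery record: the machine withheld the
#' pulse, typically to mitigate a transient hardware fault. Returns the
#' plan's nonzero-MU events whose `(couch, rotation, firing)` key is absent
#' from the delivery's nonzero-MU index, in plan order.
#'
#' @param plan Plan sequence (`fraction = 0`).
#' @param delivery Delivered-fraction sequence for the same patient and
#'   machine.
#' @return Data frame of skipped plan events (with `key` column).
#' @export
find_skipped <- function(plan, delivery) {
  check_comparable(plan, delivery)
  plan_idx <- index_events(plan)
  deliv_idx <- index_events(delivery)
  skipped <- plan_idx[!(plan_idx$key %in% deliv_idx$key), , drop = FALSE]
  rownames(skipped) <- NULL
  skipped
}

#' Find misfires in a delivered fraction
#'
#' A misfire is any delivered nonzero-MU event inconsistent with the plan:
#' an event at a key the plan never fires (`"unplanned"`), a matched event
#' whose leaf mask differs from the planned aperture (`"mask-mismatch"`),
#' or an event whose MU deviates from the machine constant by more than
#' 1e-6 MU (`"mu-anomaly"`). A matched event with a differing mask counts
#' as a misfire, never as a skip.
#'
#' @inheritParams find_skipped
#' @return Data frame of delivered events with a `reason` column; zero rows
#'   when the delivery is plan-consistent.
#' @export
find_misfires <- function(plan, delivery) {
  check_comparable(plan, delivery)
  plan_idx <- index_events(plan)
  deliv_idx <- index_events(delivery)
  pos <- match(deliv_idx$key, plan_idx$key)
  mu_const <- mu_per_firing_position(plan$spec)
  unplanned <- is.na(pos)
  mask_mismatch <- !unplanned &
    deliv_idx$leaf_mask != plan_idx$leaf_mask[pos]
  mu_anomaly <- abs(deliv_idx$mu - mu_const) > MU_TOL
  reason <- character(nrow(deliv_idx))
  reason[mu_anomaly] <- "mu-anomaly"
  reason[mask_mismatch] <- "mask-mismatch"
  reason[unplanned] <- "unplanned"
  keep <- unplanned | mask_mismatch | mu_anomaly
  out <- deliv_idx[keep, , drop = FALSE]
  out$reason <- reason[keep]
  rownames(out) <- NULL
  out
}

#' Reconcile delivered MU against the plan
#'
#' Because the machine delivers one constant MU quantum per firing
#' position, MU totals are counts of nonzero-MU events times that constant.
#' The MU reduction in a fraction is therefore exactly proportional to the
#' number of skipped firing positions, and the percent MU reduction equals
#' the percent of firing positions skipped.
#'
#' @inheritParams find_skipped
#' @param spec Machine spec; defaults to the plan's.
#' @return An object of class `mu_report`: `plan_mu_total`,
#'   `delivered_mu_total`, `mu_reduction`, `percent_reduction`,
#'   `n_plan_events`, `n_skipped`, `percent_skipped`. Stored values are
#'   unrounded; rounding happens only at presentation.
#' @export
reconcile_mu <- function(plan, delivery, spec = plan$spec) {
  check_comparable(plan, delivery)
  mu_const <- mu_per_firing_position(spec)
  plan_idx <- index_events(plan)
  deliv_idx <- index_events(delivery)
  n_plan <- nrow(plan_idx)
  if (n_plan == 0L) {
    stop("reconcile_mu: plan has no nonzero-MU firing positions",
         call. = FALSE)
  }
  n_matched <- sum(deliv_idx$key %in% plan_idx$key)
  n_skipped <- n_plan - n_matched
  plan_mu_total <- n_plan * mu_const
  delivered_mu_total <- n_matched * mu_const
  mu_reduction <- plan_mu_total - delivered_mu_total
  structure(
    list(plan_mu_total = plan_mu_total,
         delivered_mu_total = delivered_mu_total,
         mu_reduction = mu_reduction,
         percent_reduction = 100 * mu_reduction / plan_mu_total,
         n_plan_events = n_plan,
         n_skipped = n_skipped,
         percent_skipped = 100 * n_skipped / n_plan),
    class = "mu_report"
  )
}

#' @export
print.mu_report <- function(x, ...) {
  cat(sprintf("MU reconciliation: plan %.1f MU, delivered %.1f MU\n",
              x$plan_mu_total, x$delivered_mu_total))
  cat(sprintf("  %d of %d firing positions skipped (%.2f%%), -%.1f MU (%.2f%%)\n",
              x$n_skipped, x$n_plan_events, x$percent_skipped,
              x$mu_reduction, x$percent_reduction))
  invisible(x)
}

#' Compare one delivered fraction against its plan
#'
#' Runs the full daily-QA comparison at each couch position: skipped firing
#' positions ([find_skipped()]), misfires ([find_misfires()]), leaf-mask
#' discrepancies at matched keys, and MU reconciliation ([reconcile_mu()]).
#' Deterministic for fixed inputs.
#'
#' @inheritParams reconcile_mu
#' @return An object of class `comparison_result`: `patient_id`, `fraction`,
#'   `skipped` (data frame), `misfires` (data frame with `reason`),
#'   `leaf_discrepancies` (key + plan/delivered masks), `mu_report`.
#' @export
compare_fraction <- function(plan, delivery, spec = plan$spec) {
  check_comparable(plan, delivery)
  skipped <- find_skipped(plan, delivery)
  misfires <- find_misfires(plan, delivery)
  mm <- misfires[misfires$reason == "mask-mismatch", , drop = FALSE]
  plan_idx <- index_events(plan)
  leaf_discrepancies <- data.frame(
    couch_index = mm$couch_index,
    rotation_index = mm$rotation_index,
    firing_index = mm$firing_index,
    plan_mask = plan_idx$leaf_mask[match(mm$key, plan_idx$key)],
    delivered_mask = mm$leaf_mask,
    stringsAsFactors = FALSE
  )
  structure(
    list(patient_id = delivery$patient_id,
         fraction = delivery$fraction,
         skipped = skipped,
         misfires = misfires,
         leaf_discrepancies = leaf_discrepancies,
         mu_report = reconcile_mu(plan, delivery, spec)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Plan-vs-delivery comparison: patient %s, fraction %d\n",
              x$patient_id, x$fraction))
  print(x$mu_report)
  cat(sprintf("  misfires: %d\n", nrow(x$misfires)))
  invisible(x)
}

#' Serialize a comparison result to a JSON report
#'
#' @param result A [compare_fraction()] result.
#' @param path Output path for the JSON report.
#' @return Invisibly, `path`.
#' @export
write_comparison_json <- function(result, path) {
  stopifnot(inherits(result, "comparison_result"))
  mu <- result$mu_report
  obj <- list(
    patient_id = result$patient_id,
    fraction = result$fraction,
    n_plan_events = mu$n_plan_events,
    n_skipped = mu$n_skipped,
    skipped_keys = result$skipped$key,
    misfires = if (nrow(result$misfires)) {
      result$misfires[c("couch_index", "rotation_index", "firing_index",
                        "reason")]
    } else {
      list()
    },
    mu = list(plan = mu$plan_mu_total,
              delivered = mu$delivered_mu_total,
              reduction = mu$mu_reduction,
              percent = mu$percent_reduction)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
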