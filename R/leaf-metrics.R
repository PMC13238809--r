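# leaf mask strings -> integer matrix (events x leaves), entries 0/1
mask_matrix <- function(masks, n_leaves) {
  if (length(masks) == 0L) {
    return(matrix(integer(), nrow = 0L, ncol = n_leaves))
  }
  codes <- utf8ToInt(paste(masks, collapse = "")) - 48L
  matrix(codes, ncol = n_leaves, byrow = TRUE)
}

#' Leaf transition profile of a beamlet sequence
#'
#' Quantifies how aggressively the aperture is modulated. Between two
#' consecutive firing events within the same couch segment, the number of
#' leaf state changes is the Hamming distance between the two leaf masks;
#' intervals never span couch shifts because the beam is off while the
#' couch moves, and each stationary couch segment is an independent stream.
#' All events contribute masks and dwell time, including zero-MU events —
#' the leaves keep moving whether or not the pulse fires.
#'
#' The maximum transition rate is taken over sliding windows of
#' `window_intervals` consecutive intervals inside one segment: the summed
#' changes in the window divided by the window duration
#' (`window_intervals / firing_frequency`). The default window is one full
#' rotation (`fp_per_rotation` intervals, i.e. one second at 60 RPM);
#' `window_intervals = 1` gives the instantaneous variant. A segment
#' shorter than the window contributes one whole-segment window. The
#' average rate is total changes divided by beam-on time, where beam-on
#' time is the total event count over the firing frequency.
#'
#' @param seq A [beamlet_sequence()].
#' @param spec Machine spec; defaults to the sequence's.
#' @param window_intervals Positive integer window length, in firing
#'   intervals.
#' @return An object of class `transition_profile`: `per_interval_changes`
#'   (integer vector over all within-segment intervals, in event order),
#'   `segment_of_interval` (couch index of each interval), `max_rate` and
#'   `avg_rate` (leaves/second), `beam_on_seconds`.
#' @export
transition_profile <- function(seq, spec = seq$spec,
                               window_intervals = spec$fp_per_rotation) {
  stopifnot(inherits(seq, "beamlet_sequence"))
  window_intervals <- as.integer(window_intervals)
  if (window_intervals < 1L) {
    stop("transition_profile: window_intervals must be >= 1", call. = FALSE)
  }
  ev <- seq$events
  freq <- firing_frequency(spec)
  beam_on_seconds <- nrow(ev) / freq
  if (nrow(ev) < 2L) {
    return(structure(
      list(per_interval_changes = integer(),
           segment_of_interval = integer(),
           max_rate = 0, avg_rate = 0,
           beam_on_seconds = beam_on_seconds,
           window_intervals = window_intervals),
      class = "transition_profile"
    ))
  }
  M <- mask_matrix(ev$leaf_mask, spec$n_leaves)
  changes_all <- rowSums(abs(M[-1L, , drop = FALSE] -
                               M[-nrow(M), , drop = FALSE]))
  same_segment <- ev$couch_index[-1L] == ev$couch_index[-nrow(ev)]
  changes <- as.integer(changes_all[same_segment])
  seg <- ev$couch_index[-1L][same_segment]
  if (length(changes) == 0L) {
    return(structure(
      list(per_interval_changes = integer(),
           segment_of_interval = integer(),
           max_rate = 0, avg_rate = 0,
           beam_on_seconds = beam_on_seconds,
           window_intervals = window_intervals),
      class = "transition_profile"
    ))
  }
  max_rate <- 0
  for (x in split(changes, seg)) {
    len <- length(x)
    if (len <= window_intervals) {
      rate <- sum(x) / (len / freq)
    } else {
      cs <- cumsum(c(0L, x))
      wsum <- cs[(window_intervals + 1L):(len + 1L)] -
        cs[1L:(len - window_intervals + 1L)]
      rate <- max(wsum) / (window_intervals / freq)
    }
    max_rate <- max(max_rate, rate)
  }
  structure(
    list(per_interval_changes = changes,
         segment_of_interval = seg,
         max_rate = max_rate,
         avg_rate = sum(changes) / beam_on_seconds,
         beam_on_seconds = beam_on_seconds,
         window_intervals = window_intervals),
    class = "transition_profile"
  )
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf(
    "Leaf transition profile: max %.1f, avg %.1f leaves/s (window %d intervals, beam-on %.1f s)\n",
    x$max_rate, x$avg_rate, x$window_intervals, x$beam_on_seconds))
  invisible(x)
}

#' Aggregate leaf-open and beam-on counts over couch and gantry
#'
#' Builds the three heatmap matrices used to compare a plan with a
#' delivered fraction: how many times each leaf is open at each couch
#' position (summed over gantry angles), how many times each leaf is open
#' at each gantry firing position (summed over couch positions), and how
#' many times the beam is on at each (couch position, firing position)
#' cell. Only nonzero-MU events are counted; gantry aggregation is by
#' firing index (`fp_per_rotation` bins), not raw angle, so plan-delivery
#' differences are bin-exact.
#'
#' @param seq A [beamlet_sequence()].
#' @param n_couch Number of couch columns; defaults to `max(couch_index)+1`
#'   so plan and delivery aggregates share a shape.
#' @return An object of class `aggregate_set`: integer matrices
#'   `leaf_by_couch` (`n_leaves` x `n_couch`), `leaf_by_gantry`
#'   (`n_leaves` x `fp_per_rotation`), `couch_by_gantry`
#'   (`n_couch` x `fp_per_rotation`).
#' @export
aggregate_open_counts <- function(seq, n_couch = NULL) {
  stopifnot(inherits(seq, "beamlet_sequence"))
  spec <- seq$spec
  ev <- seq$events
  if (is.null(n_couch)) {
    n_couch <- if (nrow(ev)) max(ev$couch_index) + 1L else 0L
  }
  fp <- spec$fp_per_rotation
  nl <- spec$n_leaves
  leaf_by_couch <- matrix(0L, nl, n_couch,
                          dimnames = list(leaf = seq_len(nl) - 1L,
                                          couch = seq_len(n_couch) - 1L))
  leaf_by_gantry <- matrix(0L, nl, fp,
                           dimnames = list(leaf = seq_len(nl) - 1L,
                                           firing = seq_len(fp) - 1L))
  couch_by_gantry <- matrix(0L, n_couch, fp,
                            dimnames = list(couch = seq_len(n_couch) - 1L,
                                            firing = seq_len(fp) - 1L))
  nz <- ev$mu > 0
  if (any(nz)) {
    M <- mask_matrix(ev$leaf_mask[nz], nl)
    couch <- ev$couch_index[nz]
    firing <- ev$firing_index[nz]
    by_couch <- rowsum(M, group = couch)
    leaf_by_couch[, as.integer(rownames(by_couch)) + 1L] <- t(by_couch)
    by_gantry <- rowsum(M, group = firing)
    leaf_by_gantry[, as.integer(rownames(by_gantry)) + 1L] <- t(by_gantry)
    tab <- table(factor(couch, levels = seq_len(n_couch) - 1L),
                 factor(firing, levels = seq_len(fp) - 1L))
    couch_by_gantry[] <- as.integer(tab)
  }
  structure(
    list(leaf_by_couch = leaf_by_couch,
         leaf_by_gantry = leaf_by_gantry,
         couch_by_gantry = couch_by_gantry),
    class = "aggregate_set"
  )
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat("Beamlet aggregation matrices:\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d x %d, sum %d\n", nm, nrow(x[[nm]]), ncol(x[[nm]]),
                sum(x[[nm]])))
  }
  invisible(x)
}

#' Plan-minus-delivery difference maps
#'
#' Element-wise subtraction of a delivered fraction's aggregation matrices
#' from the plan's. For skip-only deliveries (no misfires) every entry is a
#' non-negative integer; the `couch_by_gantry` difference sums to the number
#' of skipped firing positions and the leaf matrices' differences sum to
#' the open-leaf count over the skipped events.
#'
#' @param plan_agg Plan [aggregate_open_counts()] result.
#' @param deliv_agg Delivery aggregate of the same shape.
#' @return An `aggregate_set` of differences.
#' @export
difference_maps <- function(plan_agg, deliv_agg) {
  stopifnot(inherits(plan_agg, "aggregate_set"),
            inherits(deliv_agg, "aggregate_set"))
  for (nm in names(plan_agg)) {
    if (!identical(dim(plan_agg[[nm]]), dim(deliv_agg[[nm]]))) {
      stop("difference_maps: shape mismatch in '", nm, "'", call. = FALSE)
    }
  }
  structure(
    list(leaf_by_couch = plan_agg$leaf_by_couch - deliv_agg$leaf_by_couch,
         leaf_by_gantry = plan_agg$leaf_by_gantry - deliv_agg$leaf_by_gantry,
         couch_by_gantry = plan_agg$couch_by_gantry - deliv_agg$couch_by_gantry),
    class = "aggregate_set"
  )
}

#' Export aggregation matrices as CSV files
#'
#' One CSV per matrix (`<prefix>_leaf_by_couch.csv`, etc.), with row and
#' column headers carrying the leaf / couch / firing indices, ready for
#' heatmap plotting.
#'
#' @param agg An [aggregate_open_counts()] or [difference_maps()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_aggregate_csv <- function(agg, prefix) {
  stopifnot(inherits(agg, "aggregate_set"))
  paths <- character(0)
  for (nm in names(agg)) {
    path <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(agg[[nm]], path, row.names = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
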