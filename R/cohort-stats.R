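#' Summarize one compared fraction
#'
#' Flattens a [compare_fraction()] result into one row of per-fraction QA
#' statistics. Because one constant MU quantum is delivered per firing
#' position, the percent MU reduction always equals the percent of firing
#' positions skipped.
#'
#' @param result A `comparison_result`.
#' @return One-row data frame: `patient_id`, `fraction`, `n_plan_events`,
#'   `n_skipped`, `percent_skipped`, `mu_reduction`,
#'   `percent_mu_reduction`.
#' @export
summarize_fraction <- function(result) {
  stopifnot(inherits(result, "comparison_result"))
  mu <- result$mu_report
  data.frame(
    patient_id = result$patient_id,
    fraction = result$fraction,
    n_plan_events = mu$n_plan_events,
    n_skipped = mu$n_skipped,
    percent_skipped = mu$percent_skipped,
    mu_reduction = mu$mu_reduction,
    percent_mu_reduction = mu$percent_reduction,
    stringsAsFactors = FALSE
  )
}

# sample SD (n-1 denominator); 0 by convention for a single observation
sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Summarize a patient's treatment course
#'
#' Mean, sample standard deviation (n-1 denominator), and range of skipped
#' firing positions over a patient's fractions, plus percent-skipped and MU
#' statistics and the plan's leaf-modulation rates. The per-patient percent
#' skipped is the mean of the per-fraction percentages (mean of ratios).
#' With a single fraction the SD is reported as 0 and `n_fractions` flags
#' the degenerate case.
#'
#' @param fractions Data frame of [summarize_fraction()] rows, all for the
#'   same patient.
#' @param profile Optional [transition_profile()] of the patient's plan;
#'   supplies the transition-rate columns (NA when absent).
#' @return One-row data frame of per-patient statistics.
#' @export
summarize_patient <- function(fractions, profile = NULL) {
  if (!is.data.frame(fractions) || nrow(fractions) == 0L) {
    stop("summarize_patient: need at least one fraction summary",
         call. = FALSE)
  }
  if (length(unique(fractions$patient_id)) != 1L) {
    stop("summarize_patient: fractions span multiple patient_ids",
         call. = FALSE)
  }
  data.frame(
    patient_id = fractions$patient_id[1],
    n_fractions = nrow(fractions),
    n_plan_events = fractions$n_plan_events[1],
    mean_skipped = mean(fractions$n_skipped),
    sd_skipped = sample_sd(fractions$n_skipped),
    min_skipped = min(fractions$n_skipped),
    max_skipped = max(fractions$n_skipped),
    mean_percent_skipped = mean(fractions$percent_skipped),
    sd_percent_skipped = sample_sd(fractions$percent_skipped),
    mean_mu_reduction = mean(fractions$mu_reduction),
    max_transition_rate = if (is.null(profile)) NA_real_ else profile$max_rate,
    avg_transition_rate = if (is.null(profile)) NA_real_ else profile$avg_rate,
    stringsAsFactors = FALSE
  )
}

#' Ordinary least-squares line fit
#'
#' Simple linear regression of y on x via [stats::lm()], reporting the
#' slope, intercept, coefficient of determination
#' (`1 - SS_res / SS_tot`), and the Pearson correlation coefficient
#' (which carries the sign of the slope; `r_squared = pearson_r^2`).
#'
#' @param x,y Numeric vectors of equal length (>= 2 points, x not
#'   constant).
#' @return An object of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `n_points`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) {
    stop("linear_fit: need at least 2 points", call. = FALSE)
  }
  if (max(x) == min(x)) {
    stop("linear_fit: degenerate fit, all x values identical", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  r <- if (stats::sd(y) == 0) {
    # flat data: the line is exact; sign from the (zero) slope convention
    1
  } else {
    stats::cor(x, y)
  }
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         pearson_r = r,
         n_points = length(x)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n=%d): y = %.6g x + %.6g, R^2 = %.3f, r = %.2f\n",
              x$n_points, x$slope, x$intercept, x$r_squared, x$pearson_r))
  invisible(x)
}

#' Cohort-level summary with linear fits and correlations
#'
#' Cross-patient analysis of a QA cohort: an OLS fit of per-patient mean
#' skipped firing positions against total planned firing positions, an OLS
#' fit of per-patient mean MU reduction against mean skipped positions
#' (which has R^2 = 1 whenever a single machine MU constant governs all
#' patients, since the MU reduction is exactly proportional to the skip
#' count), and the Pearson correlation between mean percent skipped and
#' the plan's average leaf transition rate.
#'
#' @param patients Data frame of [summarize_patient()] rows.
#' @return An object of class `cohort_summary`: `patients`,
#'   `fit_skipped_vs_total`, `fit_mu_vs_skipped` (both `linear_fit` or NULL
#'   with a warning when fewer than 2 patients),
#'   `corr_skiprate_vs_transition` (NA when transition rates are absent).
#' @export
cohort_summary <- function(patients) {
  if (!is.data.frame(patients) || nrow(patients) == 0L) {
    stop("cohort_summary: need at least one patient summary", call. = FALSE)
  }
  fit_skipped_vs_total <- NULL
  fit_mu_vs_skipped <- NULL
  if (nrow(patients) >= 2L) {
    fit_skipped_vs_total <- linear_fit(patients$n_plan_events,
                                       patients$mean_skipped)
    fit_mu_vs_skipped <- linear_fit(patients$mean_skipped,
                                    patients$mean_mu_reduction)
  } else {
    warning("cohort_summary: fewer than 2 patients, fits omitted",
            call. = FALSE)
  }
  corr <- NA_real_
  tr <- patients$avg_transition_rate
  if (nrow(patients) >= 2L && !anyNA(tr) &&
      stats::sd(tr) > 0 && stats::sd(patients$mean_percent_skipped) > 0) {
    corr <- stats::cor(patients$mean_percent_skipped, tr)
  }
  structure(
    list(patients = patients,
         fit_skipped_vs_total = fit_skipped_vs_total,
         fit_mu_vs_skipped = fit_mu_vs_skipped,
         corr_skiprate_vs_transition = corr),
    class = "cohort_summary"
  )
}

# "mean +/- sd (min-max)" rows; digits per quantity mirror the report style:
# percentages 2 d.p., MU and rates and counts 1 d.p.
stat_row <- function(x, digits) {
  sprintf("%.*f ± %.*f (%.*f–%.*f)",
          digits, mean(x), digits, sample_sd(x),
          digits, min(x), digits, max(x))
}

#' Plain-text cohort statistics table
#'
#' A "Mean +/- StdDev (range)" table of the cohort's plan parameters and
#' beamlet-analysis statistics, one row per quantity.
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return Character vector of table lines.
#' @export
format.cohort_summary <- function(x, ...) {
  p <- x$patients
  rows <- c(
    "Parameter                                   Mean ± StdDev (range)",
    sprintf("%-43s %s", "Firing positions in the treatment plan",
            stat_row(p$n_plan_events, 1)),
    sprintf("%-43s %s", "Average skipped firing positions in delivery",
            stat_row(p$mean_skipped, 1)),
    sprintf("%-43s %s", "  relative to total firing positions (%)",
            stat_row(p$mean_percent_skipped, 2)),
    sprintf("%-43s %s", "Average MU reduction in delivery (MU)",
            stat_row(p$mean_mu_reduction, 1))
  )
  if (!anyNA(p$max_transition_rate)) {
    rows <- c(rows,
      sprintf("%-43s %s", "Maximum leaf transition rate (leaves/sec)",
              stat_row(p$max_transition_rate, 1)),
      sprintf("%-43s %s", "Average leaf transition rate (leaves/sec)",
              stat_row(p$avg_transition_rate, 1)))
  }
  rows
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d patient(s)\n", nrow(x$patients)))
  cat(format(x), sep = "\n")
  if (!is.null(x$fit_skipped_vs_total)) {
    cat("Mean skipped vs total firing positions: ")
    print(x$fit_skipped_vs_total)
  }
  if (!is.null(x$fit_mu_vs_skipped)) {
    cat("Mean MU reduction vs mean skipped: ")
    print(x$fit_mu_vs_skipped)
  }
  if (!is.na(x$corr_skiprate_vs_transition)) {
    cat(sprintf("Pearson r, percent skipped vs avg transition rate: %.2f\n",
                x$corr_skiprate_vs_transition))
  }
  invisible(x)
}

#' Analyze a full simulated or loaded cohort
#'
#' Runs the complete QA pipeline over a cohort: compares every delivered
#' fraction with its plan, summarizes fractions and patients, computes the
#' plan transition profiles, and builds the cohort-level fits.
#'
#' @param cohort A [generate_cohort()] result, or any list of elements with
#'   `$plan` (a `beamlet_sequence`) and `$fractions` (list of elements with
#'   `$delivery`).
#' @param window_intervals Transition-rate window, forwarded to
#'   [transition_profile()]; NULL for the default.
#' @return An object of class `cohort_analysis`: `fractions` (per-fraction
#'   data frame), `patients` (per-patient data frame), `summary`
#'   (a [cohort_summary()]).
#' @export
summarize_cohort <- function(cohort, window_intervals = NULL) {
  patients <- list()
  fractions <- list()
  for (pt in cohort) {
    plan <- pt$plan
    profile <- if (is.null(window_intervals)) {
      transition_profile(plan)
    } else {
      transition_profile(plan, window_intervals = window_intervals)
    }
    fr <- lapply(pt$fractions, function(fx) {
      summarize_fraction(compare_fraction(plan, fx$delivery))
    })
    fr <- do.call(rbind, fr)
    fractions[[length(fractions) + 1L]] <- fr
    patients[[length(patients) + 1L]] <- summarize_patient(fr, profile)
  }
  fractions <- do.call(rbind, fractions)
  patients <- do.call(rbind, patients)
  rownames(fractions) <- rownames(patients) <- NULL
  structure(
    list(fractions = fractions,
         patients = patients,
         summary = cohort_summary(patients)),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d patients, %d fractions\n",
              nrow(x$patients), nrow(x$fractions)))
  print(x$summary)
  invisible(x)
}
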