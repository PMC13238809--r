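#' Machine specification for a binary-MLC ring-gantry linac
#'
#' Bundles the machine constants every other computation relies on: the
#' number of binary MLC leaves, the number of evenly spaced firing positions
#' per gantry rotation, the gantry rotation speed, the couch step, the
#' nominal dose rate, and the collimation geometry. All angles are stored in
#' degrees and all couch positions in millimetres.
#'
#' The defaults describe a ring-gantry machine whose gantry rotates at
#' 60 RPM while the beam is pulsed at 50 evenly spaced firing positions per
#' rotation (7.2 degree sectors), with a 64-leaf binary MLC of 6.25 mm
#' projected leaf width, a 2.1 mm couch step, and a nominal dose rate of
#' 1000 MU/min.
#'
#' @param n_leaves Number of binary MLC leaves.
#' @param fp_per_rotation Firing positions per gantry rotation; divides the
#'   rotation into equal sectors of `360 / fp_per_rotation` degrees.
#' @param gantry_rpm Gantry rotation speed, rotations per minute.
#' @param couch_step_mm Couch increment between stationary segments, mm.
#' @param nominal_dose_rate Nominal dose rate, MU per minute.
#' @param leaf_width_mm Projected leaf width at isocenter, mm.
#' @param jaw_width_cm Jaw opening in the superior-inferior direction, cm.
#' @param field_width_cm Maximum lateral field width, cm.
#' @return An object of class `machine_spec`.
#' @seealso [firing_frequency()], [mu_per_firing_position()],
#'   [gantry_angle_of()]
#' @export
#' @examples
#' spec <- machine_spec()
#' firing_frequency(spec)       # 50 aperture updates per second
#' mu_per_firing_position(spec) # 1/3 MU per pulse
machine_spec <- function(n_leaves = 64L,
                         fp_per_rotation = 50L,
                         gantry_rpm = 60,
                         couch_step_mm = 2.1,
                         nominal_dose_rate = 1000,
                         leaf_width_mm = 6.25,
                         jaw_width_cm = 2,
                         field_width_cm = 40) {
  spec <- list(
    n_leaves = as.integer(n_leaves),
    fp_per_rotation = as.integer(fp_per_rotation),
    gantry_rpm = as.numeric(gantry_rpm),
    couch_step_mm = as.numeric(couch_step_mm),
    nominal_dose_rate = as.numeric(nominal_dose_rate),
    leaf_width_mm = as.numeric(leaf_width_mm),
    jaw_width_cm = as.numeric(jaw_width_cm),
    field_width_cm = as.numeric(field_width_cm)
  )
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (length(v) != 1L || is.na(v) || v <= 0) {
      stop("machine_spec: field '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(spec, class = "machine_spec")
}

#' Default machine specification
#'
#' Returns the stock machine constants (64 leaves, 50 firing positions per
#' rotation, 60 RPM, 2.1 mm couch step, 1000 MU/min, 2 cm jaw). A pure
#' constant: successive calls return identical values.
#'
#' @return A `machine_spec`.
#' @export
default_spec <- function() machine_spec()

#' Firing frequency (aperture updates per second)
#'
#' How many firing positions pass per second: `gantry_rpm / 60 *
#' fp_per_rotation`. For the default machine this is 50 per second.
#'
#' @param spec A `machine_spec`.
#' @return Firing positions per second.
#' @export
firing_frequency <- function(spec = default_spec()) {
  stopifnot(inherits(spec, "machine_spec"))
  spec$gantry_rpm / 60 * spec$fp_per_rotation
}

#' Monitor units delivered per firing position
#'
#' The machine delivers a constant MU quantum at every non-skipped firing
#' position: `nominal_dose_rate / (gantry_rpm * fp_per_rotation)`. This one
#' machine-level constant governs all plans and deliveries; with the default
#' constants it equals 1000/3000 = 1/3 MU.
#'
#' @param spec A `machine_spec`.
#' @return MU per firing position.
#' @export
mu_per_firing_position <- function(spec = default_spec()) {
  stopifnot(inherits(spec, "machine_spec"))
  spec$nominal_dose_rate / (spec$gantry_rpm * spec$fp_per_rotation)
}

#' Gantry angle at a firing index
#'
#' Maps a firing index within one rotation to a gantry angle on the evenly
#' spaced firing grid: `(start_angle + firing_index * 360/fp_per_rotation)
#' mod 360`. Angles follow an IEC-style convention: 0 degrees at the
#' vertical top, increasing in the machine's rotation direction. Vectorized
#' over `firing_index`.
#'
#' @param firing_index Integer(s) in `[0, fp_per_rotation)`.
#' @param start_angle Gantry angle of firing index 0 for this rotation,
#'   degrees.
#' @param spec A `machine_spec`.
#' @return Angle(s) in degrees, in `[0, 360)`.
#' @export
gantry_angle_of <- function(firing_index, start_angle = 0, spec = default_spec()) {
  stopifnot(inherits(spec, "machine_spec"))
  if (any(firing_index < 0 | firing_index >= spec$fp_per_rotation)) {
    stop("gantry_angle_of: firing_index must lie in [0, fp_per_rotation)",
         call. = FALSE)
  }
  (start_angle + firing_index * 360 / spec$fp_per_rotation) %% 360
}

#' @export
print.machine_spec <- function(x, ...) {
  cat("Binary-MLC ring-gantry machine spec\n")
  cat(sprintf("  leaves: %d (%.2f mm projected width)\n",
              x$n_leaves, x$leaf_width_mm))
  cat(sprintf("  firing positions/rotation: %d (%.1f deg sectors) at %g RPM\n",
              x$fp_per_rotation, 360 / x$fp_per_rotation, x$gantry_rpm))
  cat(sprintf("  couch step: %g mm; jaw: %g cm SI; field width: %g cm\n",
              x$couch_step_mm, x$jaw_width_cm, x$field_width_cm))
  cat(sprintf("  dose rate: %g MU/min -> %.6f MU per firing position\n",
              x$nominal_dose_rate, mu_per_firing_position(x)))
  invisible(x)
}

# exact field-wise comparison of two machine specs
spec_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' Write a machine spec to a plain-text config file
#'
#' One `key=value` pair per line, the same keys used in BLSQ file headers.
#'
#' @param spec A `machine_spec`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_machine_config <- function(spec, path) {
  stopifnot(inherits(spec, "machine_spec"))
  lines <- sprintf("%s=%s", names(unclass(spec)),
                   vapply(unclass(spec), format_num, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a machine spec from a plain-text config file
#'
#' @param path File of `key=value` lines as written by
#'   [write_machine_config()]. Unknown keys are an error; missing keys take
#'   the default value.
#' @return A `machine_spec`.
#' @export
read_machine_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)=(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop("read_machine_config: malformed line ", which(bad)[1], call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- as.numeric(vapply(kv, `[`, character(1), 3L))
  known <- names(formals(machine_spec))
  if (any(!keys %in% known)) {
    stop("read_machine_config: unknown key '",
         keys[!keys %in% known][1], "'", call. = FALSE)
  }
  do.call(machine_spec, as.list(stats::setNames(vals, keys)))
}

# render a number with full round-trip precision, no scientific notation
format_num <- function(x) {
  if (x == round(x)) sprintf("%d", as.integer(x)) else format(x, digits = 15)
}
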