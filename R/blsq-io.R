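#' Read a BLSQ beamlet sequence file
#'
#' BLSQ v1 is an open, human-diffable CSV dialect for beamlet sequence
#' logs. A file starts with a `#BLSQ v1` magic line, followed by `#key=value`
#' header lines (patient, fraction, plan MU, machine constants), exactly one
#' CSV column-header line, and one data row per firing event. The leaf mask
#' is a string of exactly `n_leaves` characters from `{0,1}`, leaf 0 first
#' (leaf 0 sits on the machine's negative lateral side). Files are UTF-8
#' with `\n` line endings and `.` as the decimal separator.
#'
#' @param path Path to a BLSQ file.
#' @return A [beamlet_sequence()].
#' @export
read_blsq <- function(path) {
  if (!file.exists(path)) {
    stop("read_blsq: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "#BLSQ v1") {
    stop("read_blsq: line 1 is not the '#BLSQ v1' magic line", call. = FALSE)
  }
  is_header <- startsWith(lines, "#")
  n_header <- which(!is_header)[1]
  if (is.na(n_header)) {
    stop("read_blsq: no column-header line found", call. = FALSE)
  }
  header_lines <- if (n_header > 2L) lines[2:(n_header - 1L)] else character()
  kv <- regmatches(header_lines, regexec("^#([A-Za-z_]+)=(.*)$", header_lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    stop("read_blsq: malformed header at line ", bad[1] + 1L, call. = FALSE)
  }
  meta <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                          vapply(kv, `[`, character(1), 2L))
  for (key in c("patient_id", "fraction", "plan_mu")) {
    if (!key %in% names(meta)) {
      stop("read_blsq: header key '", key, "' missing", call. = FALSE)
    }
  }
  spec_keys <- c("n_leaves", "fp_per_rotation", "gantry_rpm", "couch_step_mm",
                 "nominal_dose_rate", "leaf_width_mm", "jaw_width_cm",
                 "field_width_cm")
  spec_args <- lapply(intersect(spec_keys, names(meta)),
                      function(k) as.numeric(meta[[k]]))
  names(spec_args) <- intersect(spec_keys, names(meta))
  spec <- do.call(machine_spec, spec_args)

  columns <- c("event_index", "couch_index", "couch_mm", "rotation_index",
               "firing_index", "gantry_deg", "mu", "leaf_mask")
  if (lines[n_header] != paste(columns, collapse = ",")) {
    stop("read_blsq: unexpected column-header at line ", n_header,
         call. = FALSE)
  }
  data_lines <- lines[seq_len(length(lines) - n_header) + n_header]
  data_lines <- data_lines[nzchar(data_lines)]
  n <- length(data_lines)
  if (n == 0) {
    events <- data.frame(event_index = integer(), couch_index = integer(),
                         couch_mm = numeric(), rotation_index = integer(),
                         firing_index = integer(), gantry_deg = numeric(),
                         mu = numeric(), leaf_mask = character(),
                         stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(data_lines, ",", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 8L)) {
      bad <- which(nf != 8L)[1]
      stop("read_blsq: data row ", bad, " has ", nf[bad],
           " fields, expected 8", call. = FALSE)
    }
    m <- matrix(unlist(fields, use.names = FALSE), nrow = 8L)
    num <- function(i, col) {
      v <- suppressWarnings(as.numeric(m[i, ]))
      if (anyNA(v)) {
        stop("read_blsq: non-numeric '", col, "' at data row ",
             which(is.na(v))[1], call. = FALSE)
      }
      v
    }
    mask <- m[8L, ]
    bad <- which(nchar(mask) != spec$n_leaves | grepl("[^01]", mask))
    if (length(bad)) {
      stop("read_blsq: data row ", bad[1], ": leaf_mask is not ",
           spec$n_leaves, " characters of 0/1", call. = FALSE)
    }
    events <- data.frame(
      event_index = as.integer(num(1L, "event_index")),
      couch_index = as.integer(num(2L, "couch_index")),
      couch_mm = num(3L, "couch_mm"),
      rotation_index = as.integer(num(4L, "rotation_index")),
      firing_index = as.integer(num(5L, "firing_index")),
      gantry_deg = num(6L, "gantry_deg"),
      mu = num(7L, "mu"),
      leaf_mask = mask,
      stringsAsFactors = FALSE
    )
  }
  beamlet_sequence(
    patient_id = meta[["patient_id"]],
    fraction = as.integer(meta[["fraction"]]),
    events = events,
    spec = spec,
    plan_mu = as.numeric(meta[["plan_mu"]])
  )
}

#' Write a beamlet sequence to a BLSQ file
#'
#' Emits the BLSQ v1 dialect (see [read_blsq()]). Numbers carry enough
#' precision to round-trip: couch positions and gantry angles with 3
#' decimals, MU with 6 decimals. `\n` line endings on every platform.
#'
#' @param seq A [beamlet_sequence()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_blsq <- function(seq, path) {
  stopifnot(inherits(seq, "beamlet_sequence"))
  spec <- seq$spec
  header <- c(
    "#BLSQ v1",
    sprintf("#patient_id=%s", seq$patient_id),
    sprintf("#fraction=%d", seq$fraction),
    sprintf("#plan_mu=%.6f", seq$plan_mu),
    sprintf("#n_leaves=%d", spec$n_leaves),
    sprintf("#fp_per_rotation=%d", spec$fp_per_rotation),
    sprintf("#gantry_rpm=%s", format_num(spec$gantry_rpm)),
    sprintf("#couch_step_mm=%s", format_num(spec$couch_step_mm)),
    sprintf("#nominal_dose_rate=%s", format_num(spec$nominal_dose_rate)),
    "event_index,couch_index,couch_mm,rotation_index,firing_index,gantry_deg,mu,leaf_mask"
  )
  ev <- seq$events
  rows <- if (nrow(ev)) {
    sprintf("%d,%d,%.3f,%d,%d,%.3f,%.6f,%s",
            ev$event_index, ev$couch_index, ev$couch_mm, ev$rotation_index,
            ev$firing_index, ev$gantry_deg, ev$mu, ev$leaf_mask)
  } else {
    character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, rows)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
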