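# On-disk formats: per-sensor recording CSVs (time_s, acc_x, acc_y, acc_z),
# per-subject JSON session manifests, the ground-truth score table, and the
# wide feature table. All readers validate strictly and all writer/reader
# pairs round-trip to text precision.

#' Construct and validate a session manifest
#'
#' The manifest ties a subject's session together: handedness, the worn
#' sensors with their data files, and the vocal-cue timestamps delimiting
#' each test condition.
#'
#' @param subject_id Subject identifier.
#' @param handedness `left` or `right`.
#' @param sensors Data frame with columns `placement`, `side`, `file`.
#' @param cues Data frame with columns `condition`, `start_s`, `stop_s`;
#'   conditions unique, intervals non-overlapping with `stop_s > start_s`.
#' @param fs Sampling frequency in Hz.
#' @return An object of class `session_manifest`.
#' @export
session_manifest <- function(subject_id, handedness, sensors, cues, fs) {
  if (!handedness %in% c("left", "right")) {
    stop("handedness must be left or right", call. = FALSE)
  }
  sensors <- as.data.frame(sensors, stringsAsFactors = FALSE)
  cues <- as.data.frame(cues, stringsAsFactors = FALSE)
  stopifnot(all(c("placement", "side", "file") %in% names(sensors)),
            all(c("condition", "start_s", "stop_s") %in% names(cues)),
            is.numeric(fs), fs > 0)
  .assert_placement(sensors$placement)
  .assert_condition(cues$condition)
  if (anyDuplicated(cues$condition)) {
    stop("cue conditions must be unique", call. = FALSE)
  }
  bad_side <- sensors$placement %in% CENTRAL_PLACEMENTS &
    sensors$side != "center"
  if (any(bad_side)) {
    stop("lumbar/sternum sensors must have side 'center'", call. = FALSE)
  }
  if (any(cues$stop_s <= cues$start_s)) {
    stop("every cue must have stop_s > start_s", call. = FALSE)
  }
  o <- order(cues$start_s)
  so <- cues[o, ]
  if (nrow(so) > 1 &&
      any(so$start_s[-1] < so$stop_s[-nrow(so)] - 1e-9)) {
    stop("cue intervals must not overlap", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 handedness = handedness, sensors = sensors,
                 cues = cues, fs = fs),
            class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> %s (%s-handed): %d sensors, %d cues @ %g Hz\n",
              x$subject_id, x$handedness, nrow(x$sensors), nrow(x$cues), x$fs))
  invisible(x)
}

#' Write / read a session manifest (JSON)
#'
#' @param manifest A [session_manifest()].
#' @param path File path.
#' @return `read_manifest()` returns a validated `session_manifest`;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "session_manifest"))
  jsonlite::write_json(
    list(subject_id = manifest$subject_id,
         handedness = manifest$handedness,
         fs = manifest$fs,
         sensors = manifest$sensors,
         cues = manifest$cues),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path)
  for (fld in c("subject_id", "handedness", "fs", "sensors", "cues")) {
    if (is.null(j[[fld]])) {
      stop("manifest ", path, " is missing field '", fld, "'", call. = FALSE)
    }
  }
  session_manifest(j$subject_id, j$handedness, j$sensors, j$cues, j$fs)
}

#' Write / read a raw recording CSV
#'
#' Recording files hold one sample per row with columns `time_s`, `acc_x`,
#' `acc_y`, `acc_z` (UTF-8, '.' decimal separator). The reader validates
#' column presence, finiteness (naming the first offending row), strictly
#' increasing time, and a constant sampling step within 1e-6 s.
#'
#' @param session An [imu_session()] or a device-frame [imu_recording()].
#' @param path File path.
#' @return `read_recording()` returns an [imu_session()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(session, path) {
  if (inherits(session, "imu_recording")) {
    t <- session$t0 + (seq_len(nrow(session$acc)) - 1) / session$fs
    acc <- session$acc
  } else if (inherits(session, "imu_session")) {
    t <- session$t
    acc <- session$acc
  } else {
    stop("session must be an imu_session or imu_recording", call. = FALSE)
  }
  utils::write.csv(
    data.frame(time_s = t, acc_x = acc[, 1], acc_y = acc[, 2],
               acc_z = acc[, 3]),
    path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such recording: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "acc_x", "acc_y", "acc_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[need])
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: non-finite value in column %s at data row %d",
                 path, need[bad[1, 2]], bad[1, 1]), call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop(path, ": time_s is not strictly increasing", call. = FALSE)
  }
  imu_session(df$time_s, as.matrix(df[c("acc_x", "acc_y", "acc_z")]))
}

#' Write / read the wide feature table (CSV)
#'
#' One row per (subject, condition, sensor): metadata columns
#' `subject_id`, `condition`, `placement`, `side`, `role`, the ground-truth
#' average velocity `av`, and the 42 feature columns in the canonical order
#' of [feature_names()].
#'
#' @param features Data frame as produced by [cohort_features()].
#' @param path File path.
#' @return `read_feature_table()` returns the validated data frame;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  validate_feature_table(features)
  cols <- c("subject_id", "condition", "placement", "side", "role", "av",
            feature_names())
  utils::write.csv(features[cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such feature table: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  validate_feature_table(df)
  df
}

#' Validate a feature table
#'
#' Checks that the metadata columns, the `av` column and all 42 feature
#' columns are present and finite.
#'
#' @param features Data frame.
#' @return The data frame, invisibly, or an error listing what is missing.
#' @export
validate_feature_table <- function(features) {
  stopifnot(is.data.frame(features))
  need <- c("subject_id", "condition", "placement", "side", "role", "av",
            feature_names())
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- as.matrix(features[c("av", feature_names())])
  if (nrow(features) > 0 && any(!is.finite(num))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  invisible(features)
}

#' Write a simulated cohort to disk
#'
#' Materializes the on-disk session layout: one CSV per sensor per subject
#' covering the whole session (noise-only lead-in, the four condition
#' segments, noise-only gaps and lead-out), one JSON manifest per subject,
#' and `scores.csv` with the ground-truth balance scores.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sway_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  fs <- cfg$fs
  utils::write.csv(cohort_scores(cohort), file.path(dir, "scores.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  sensors <- sensor_table_()
  for (si in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[si]]
    n_total <- round(s$session_end_s * fs)
    t <- (seq_len(n_total) - 1) / fs
    files <- character(nrow(sensors))
    with_seed_(cfg$seed %% 1000000L + 400000L + si, {
      for (k in seq_len(nrow(sensors))) {
        key <- paste(sensors$placement[k], sensors$side[k], sep = "_")
        nsd <- cfg$site_noise_sd[[sensors$placement[k]]]
        acc <- matrix(if (nsd > 0) rnorm(3 * n_total, sd = nsd) else 0,
                      n_total, 3)
        for (cond in CTSIB_CONDITIONS) {
          ce <- s$conditions[[cond]]
          i0 <- round(ce$cue[["start_s"]] * fs) + 1L
          seg <- ce$recordings[[key]]$acc
          acc[i0:(i0 + nrow(seg) - 1L), ] <- seg
        }
        files[k] <- sprintf("%s_%s_%s.csv", s$subject_id,
                            sensors$placement[k], sensors$side[k])
        write_recording(imu_session(t, acc, fs = fs),
                        file.path(dir, files[k]))
      }
    })
    cues <- data.frame(
      condition = CTSIB_CONDITIONS,
      start_s = vapply(CTSIB_CONDITIONS, function(cn)
        s$conditions[[cn]]$cue[["start_s"]], numeric(1)),
      stop_s = vapply(CTSIB_CONDITIONS, function(cn)
        s$conditions[[cn]]$cue[["stop_s"]], numeric(1)),
      stringsAsFactors = FALSE)
    m <- session_manifest(
      s$subject_id, s$handedness,
      sensors = data.frame(placement = sensors$placement,
                           side = sensors$side, file = files,
                           stringsAsFactors = FALSE),
      cues = cues, fs = fs)
    write_manifest(m, file.path(dir, paste0(s$subject_id, "_manifest.json")))
  }
  invisible(dir)
}
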