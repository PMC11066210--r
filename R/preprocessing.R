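# Session preprocessing: cue-based segmentation, edge trimming, dominance
# relabeling, and device-to-body axis harmonization.

#' Construct a whole-session raw recording
#'
#' A raw tri-axial accelerometer session as read from disk: a uniform time
#' base and device-frame X/Y/Z samples, before any segmentation.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   with a constant step.
#' @param acc Numeric matrix, `length(t)` rows x 3 columns (X, Y, Z).
#' @param fs Sampling frequency in Hz; if missing, inferred from `t`.
#' @return An object of class `imu_session`.
#' @export
imu_session <- function(t, acc, fs = NULL) {
  acc <- as.matrix(acc)
  stopifnot(is.numeric(t), nrow(acc) == length(t), ncol(acc) == 3)
  if (length(t) < 2) stop("a session needs >= 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing",
                         call. = FALSE)
  if (max(dt) - min(dt) > 1e-6) {
    stop("sampling step is not constant (tolerance 1e-6 s)", call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  colnames(acc) <- c("X", "Y", "Z")
  structure(list(t = t, acc = acc, fs = fs), class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  cat(sprintf("<imu_session> %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
              length(x$t), x$fs, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Split a session into per-condition segments using cue timestamps
#'
#' Each cue interval selects the samples with `start_s <= t < stop_s`
#' (half-open, so adjacent cues never share a boundary sample).
#'
#' @param session An [imu_session()] (or a [read_manifest()]-compatible
#'   manifest's sensor file read with [read_recording()]).
#' @param cues Data frame with columns `condition`, `start_s`, `stop_s`
#'   (e.g. the `cues` element of a [session_manifest()]).
#' @return Named list (one entry per cue condition) of `imu_session`
#'   segments.
#' @export
segment_by_cues <- function(session, cues) {
  stopifnot(inherits(session, "imu_session"), is.data.frame(cues))
  .assert_condition(cues$condition)
  tol <- 1e-9
  n <- length(session$t)
  span_lo <- session$t[1] - tol
  span_hi <- session$t[n] + 1 / session$fs + tol
  out <- list()
  for (i in seq_len(nrow(cues))) {
    a <- cues$start_s[i]; b <- cues$stop_s[i]
    if (a < span_lo || b > span_hi) {
      stop(sprintf("cue %s [%.3f, %.3f) lies outside the recording span",
                   cues$condition[i], a, b), call. = FALSE)
    }
    idx <- which(session$t >= a - tol & session$t < b - tol)
    if (length(idx) < 2) {
      stop("cue ", cues$condition[i], " selects fewer than 2 samples",
           call. = FALSE)
    }
    out[[cues$condition[i]]] <-
      imu_session(session$t[idx], session$acc[idx, , drop = FALSE],
                  fs = session$fs)
  }
  out
}

#' Trim transition edges from a segment
#'
#' Removes `round(trim_s * fs)` samples from each end of a segment, dropping
#' the instants where the subject may still be stepping on or off the
#' platform. Sample values are never altered, only selected.
#'
#' @param segment An [imu_session()] or [imu_recording()].
#' @param trim_s Seconds to trim from each end (default 0.5).
#' @return The trimmed object, same class as the input.
#' @export
trim_edges <- function(segment, trim_s = 0.5) {
  stopifnot(trim_s >= 0)
  fs <- segment$fs
  k <- round(trim_s * fs)
  if (k == 0) return(segment)
  n <- if (inherits(segment, "imu_session")) length(segment$t)
       else nrow(segment$acc)
  if (n <= 2 * k) {
    stop(sprintf("segment too short to trim: %d samples, trim removes 2 x %d",
                 n, k), call. = FALSE)
  }
  keep <- (k + 1):(n - k)
  if (inherits(segment, "imu_session")) {
    imu_session(segment$t[keep], segment$acc[keep, , drop = FALSE], fs = fs)
  } else if (inherits(segment, "imu_recording")) {
    segment$acc <- segment$acc[keep, , drop = FALSE]
    segment$t0 <- segment$t0 + k / fs
    segment
  } else {
    stop("segment must be an imu_session or imu_recording", call. = FALSE)
  }
}

#' Relabel a sensor side as dominant / non-dominant
#'
#' Limb dominance affects postural control, so bilateral sensors are
#' analyzed by dominance rather than by left/right: the side matching the
#' subject's handedness is `dominant`, the opposite side `nondominant`, and
#' midline sensors (lumbar, sternum) are `center`.
#'
#' @param placement Sensor placement.
#' @param side `left`, `right`, or `center`.
#' @param handedness Subject handedness, `left` or `right`.
#' @return `"dominant"`, `"nondominant"`, or `"center"`.
#' @examples
#' assign_dominance("ankle", "right", "right")
#' assign_dominance("wrist", "left", "right")
#' @export
assign_dominance <- function(placement, side, handedness) {
  .assert_placement(placement)
  if (!handedness %in% c("left", "right")) {
    stop("handedness must be left or right", call. = FALSE)
  }
  if (placement %in% CENTRAL_PLACEMENTS) {
    if (side != "center") {
      stop(placement, " sensors must have side 'center'", call. = FALSE)
    }
    return("center")
  }
  if (!side %in% c("left", "right")) {
    stop(placement, " sensors must have side left or right", call. = FALSE)
  }
  if (side == handedness) "dominant" else "nondominant"
}

#' Harmonize device axes into body axes
#'
#' Maps recorded X/Y/Z channels onto the anatomical medial-lateral (ML),
#' anterior-posterior (AP) and vertical (VT) axes. Worn as in this
#' protocol, every placement except the arm records ML on X and AP on Y;
#' arm sensors are rotated a quarter turn, so X records AP and Y records
#' ML. Z is vertical everywhere. A recording already in the body frame is
#' returned unchanged.
#'
#' @param recording An [imu_recording()] in the device frame.
#' @return The recording with `frame = "body"` and columns ML, AP, VT.
#' @export
harmonize_axes <- function(recording) {
  stopifnot(inherits(recording, "imu_recording"))
  if (recording$frame == "body") return(recording)
  acc <- recording$acc
  body <- if (recording$placement == "arm") {
    cbind(ML = acc[, "Y"], AP = acc[, "X"], VT = acc[, "Z"])
  } else {
    cbind(ML = acc[, "X"], AP = acc[, "Y"], VT = acc[, "Z"])
  }
  recording$acc <- body
  recording$frame <- "body"
  recording
}

#' Prepare one simulated recording for feature extraction
#'
#' Convenience wrapper applying the full preprocessing contract to a
#' device-frame segment: edge trimming, axis harmonization, and dominance
#' relabeling.
#'
#' @param recording A device-frame [imu_recording()] covering one condition.
#' @param handedness Subject handedness.
#' @param trim_s Seconds trimmed from each end (default 0.5).
#' @return A body-frame `imu_recording` with `role` set.
#' @export
preprocess_recording <- function(recording, handedness, trim_s = 0.5) {
  rec <- trim_edges(recording, trim_s = trim_s)
  rec <- harmonize_axes(rec)
  rec$role <- assign_dominance(rec$placement, rec$side, handedness)
  rec
}
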