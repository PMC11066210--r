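# Synthetic postural-sway cohort generator.
#
# COP sway is a discrete Ornstein-Uhlenbeck (mean-reverting Gaussian random
# walk) process per body axis; body-site acceleration is a gain-scaled second
# finite difference of the COP plus white noise. Both are deliberately minimal:
# they reproduce the statistical structure the downstream pipeline relies on
# (graded sway magnitude per condition, shared subject ability, proximal >
# distal coupling) without claiming biomechanical fidelity.

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a center-of-pressure sway trace
#'
#' One condition's COP trajectory as two independent mean-reverting Gaussian
#' random walks (discrete Ornstein-Uhlenbeck processes), one per body axis:
#' \deqn{x_{i+1} = x_i (1 - \theta \Delta t) + s \sqrt{\Delta t}\, \eta_i,}
#' with \eqn{\eta_i} standard normal, \eqn{\Delta t = 1/f_s} and sway scale
#' \eqn{s} in inches. The trace starts at the origin. Because the recursion
#' is linear in \eqn{s}, the whole trajectory — and therefore its path length
#' and average velocity — scales exactly proportionally with the sway scale,
#' which is what makes calibration against target velocities exact.
#'
#' Consumes the current R random number stream; seed with `set.seed()` (or
#' use [simulate_cohort()], which manages seeding).
#'
#' @param sway_scale Sway magnitude in inches (> 0).
#' @param duration_s Trace duration in seconds; `fs * duration_s` samples.
#' @param fs Sampling frequency in Hz.
#' @param theta Mean-reversion rate, 1/seconds.
#' @return A [cop_trace()].
#' @examples
#' set.seed(1)
#' tr <- simulate_cop(0.02, duration_s = 11, fs = 128)
#' average_velocity(tr)
#' @export
simulate_cop <- function(sway_scale, duration_s = 11, fs = 128, theta = 1.0) {
  if (!is.numeric(sway_scale) || length(sway_scale) != 1 || sway_scale <= 0) {
    stop("sway_scale must be a positive scalar", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  n <- round(fs * duration_s)
  if (n < 2) stop("need at least 2 samples (fs * duration_s >= 2)",
                  call. = FALSE)
  dt <- 1 / fs
  a <- 1 - theta * dt
  step_sd <- sway_scale * sqrt(dt)
  x <- c(0, stats::filter(rnorm(n - 1, sd = step_sd), a,
                          method = "recursive"))
  y <- c(0, stats::filter(rnorm(n - 1, sd = step_sd), a,
                          method = "recursive"))
  cop_trace(as.numeric(x), as.numeric(y), fs = fs)
}

#' Calibrate sway scales against target average velocities
#'
#' Finds, for each m-CTSIB condition, the sway scale whose simulated traces
#' have the configured mean average velocity (AV). The OU sway recursion is
#' linear in the scale, so AV is exactly proportional to it path-by-path;
#' the calibration therefore reduces to a one-point regression: simulate
#' `n_traces` unit-scale traces under a seed derived from `config$seed`,
#' measure their mean AV, and divide each target by it.
#'
#' @param config A [sim_config()].
#' @param n_traces Number of unit-scale traces used to estimate the
#'   scale-to-AV slope (default 500).
#' @return Named numeric vector: sway scale (inches) per condition.
#' @examples
#' sc <- calibrate_scales(sim_config(seed = 7), n_traces = 100)
#' sc[["ECFS"]] / sc[["EOSS"]]  # ratio of the AV targets
#' @export
calibrate_scales <- function(config, n_traces = 500) {
  stopifnot(inherits(config, "sim_config"))
  if (n_traces < 1) stop("n_traces must be >= 1", call. = FALSE)
  av_unit <- with_seed_(config$seed %% 1000000L + 77003L, {
    vapply(seq_len(n_traces), function(i) {
      average_velocity(simulate_cop(1.0, config$duration_s, config$fs,
                                    config$mean_reversion_theta))
    }, numeric(1))
  })
  slope <- mean(av_unit)
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failed: unit-scale mean AV is not positive",
         call. = FALSE)
  }
  config$condition_av_targets / slope
}

#' Construct an IMU accelerometer recording
#'
#' A tri-axial acceleration segment with placement metadata. Axes are either
#' in the device frame (`X`, `Y`, `Z`, as recorded) or the body frame
#' (`ML`, `AP`, `VT`) after [harmonize_axes()].
#'
#' @param acc Numeric matrix with 3 columns (samples x axes).
#' @param fs Sampling frequency in Hz.
#' @param placement One of `ankle`, `lumbar`, `sternum`, `wrist`, `arm`.
#' @param side `left`, `right`, or `center` (center only for lumbar/sternum).
#' @param frame `"device"` (columns X/Y/Z) or `"body"` (columns ML/AP/VT).
#' @param subject_id,condition,role Optional metadata carried through the
#'   pipeline.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(acc, fs, placement, side,
                          frame = c("device", "body"),
                          subject_id = NA_character_,
                          condition = NA_character_,
                          role = NA_character_,
                          t0 = 0) {
  frame <- match.arg(frame)
  .assert_placement(placement)
  if (!side %in% c("left", "right", "center")) {
    stop("side must be left, right or center", call. = FALSE)
  }
  if (placement %in% CENTRAL_PLACEMENTS && side != "center") {
    stop(placement, " sensors are midline: side must be 'center'",
         call. = FALSE)
  }
  if (placement %in% BILATERAL_PLACEMENTS && side == "center") {
    stop(placement, " sensors are bilateral: side must be left or right",
         call. = FALSE)
  }
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("acc must have 3 columns", call. = FALSE)
  if (any(!is.finite(acc))) stop("acc must be finite", call. = FALSE)
  colnames(acc) <- if (frame == "device") c("X", "Y", "Z")
                   else c("ML", "AP", "VT")
  structure(list(acc = acc, fs = fs, placement = placement, side = side,
                 frame = frame, subject_id = subject_id,
                 condition = condition, role = role, t0 = t0),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s/%s%s%s: %d samples @ %g Hz [%s frame]\n",
              x$placement, x$side,
              if (is.na(x$condition)) "" else paste0(" ", x$condition),
              if (is.na(x$role)) "" else paste0(" (", x$role, ")"),
              nrow(x$acc), x$fs, x$frame))
  invisible(x)
}

# Second central finite difference scaled by fs^2; endpoints repeat their
# nearest interior value so the output length matches the input.
second_diff_ <- function(x, fs) {
  n <- length(x)
  d <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  c(d[1], d, d[length(d)])
}

#' Synthesize a body-site accelerometer recording from a COP trace
#'
#' Couples limb acceleration to COP motion through a minimal lever-arm
#' abstraction: per axis, acceleration = site gain x second finite
#' difference of the COP coordinate x \eqn{f_s^2}, plus white Gaussian
#' noise. The effective gain carries a per-recording log-normal jitter
#' (CV from `config$site_gain_cv`) representing idiosyncratic secondary
#' movement, which is strongest at distal sites. The vertical axis carries
#' noise only.
#'
#' Device-frame axis conventions follow the worn-sensor orientation: for all
#' placements except the arm, X records ML and Y records AP motion; arm
#' sensors are rotated so X records AP and Y records ML. Z is vertical
#' everywhere. Acceleration is in arbitrary g-scaled units — only the
#' relative structure matters to the features.
#'
#' Consumes the current R random number stream.
#'
#' @param cop A [cop_trace()].
#' @param placement,side Sensor site (see [imu_recording()]).
#' @param config A [sim_config()] supplying gains and noise levels.
#' @param subject_id,condition Metadata carried into the recording.
#' @return An `imu_recording` in the device frame, same sample count as
#'   `cop`.
#' @export
cop_to_imu <- function(cop, placement, side, config,
                       subject_id = NA_character_,
                       condition = NA_character_) {
  stopifnot(inherits(cop, "cop_trace"), inherits(config, "sim_config"))
  .assert_placement(placement)
  n <- length(cop$x)
  gain <- config$site_gains[[placement]]
  cv <- config$site_gain_cv[[placement]]
  noise_sd <- config$site_noise_sd[[placement]]
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    gain <- gain * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  ml_sig <- gain * second_diff_(cop$x, cop$fs)
  ap_sig <- gain * second_diff_(cop$y, cop$fs)
  noise <- function() if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
  ml <- ml_sig + noise()
  ap <- ap_sig + noise()
  vt <- noise()
  acc <- if (placement == "arm") cbind(ap, ml, vt) else cbind(ml, ap, vt)
  imu_recording(acc, fs = cop$fs, placement = placement, side = side,
                frame = "device", subject_id = subject_id,
                condition = condition, t0 = cop$t[1])
}

# One sensor per row: the eight worn sites.
sensor_table_ <- function() {
  data.frame(
    placement = c("ankle", "ankle", "lumbar", "sternum",
                  "wrist", "wrist", "arm", "arm"),
    side = c("left", "right", "center", "center",
             "left", "right", "left", "right"),
    stringsAsFactors = FALSE)
}

#' Simulate a full balance-testing cohort
#'
#' Generates `config$n_subjects` subjects, each tested under the four
#' m-CTSIB conditions with eight worn sensors (two ankles, lumbar, sternum,
#' two wrists, two arms). Per-condition sway scales are calibrated against
#' `config$condition_av_targets` with [calibrate_scales()], then multiplied
#' by a subject-level log-normal ability factor (mean 1, CV
#' `config$condition_av_cv`) shared across conditions — this shared factor is
#' what induces the within-subject correlation of AV across conditions seen
#' in real cohorts. Condition durations are jittered around the nominal
#' 11 s (never below 9 s) and snapped to the sample grid; cue timestamps
#' (with lead-in and inter-condition gaps) are recorded so that session
#' segmentation can be exercised end to end.
#'
#' Ground-truth balance scores are computed from each COP trace with
#' [balance_score()]. The whole cohort is reproducible from `config`
#' (including its seed) alone.
#'
#' @param config A [sim_config()].
#' @return An object of class `sway_cohort`: list with `config`, `scales`
#'   (calibrated sway scale per condition) and `subjects`, each subject a
#'   list with `subject_id`, `handedness`, `ability` and per-condition
#'   entries holding `cop`, `score`, `cue` (start/stop seconds in the
#'   session) and eight device-frame `imu_recording`s.
#' @examples
#' co <- simulate_cohort(sim_config(n_subjects = 2, seed = 3))
#' co$subjects[[1]]$conditions$EOSS$score
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects < 2) {
    stop("n_subjects must be >= 2 (between-subject variation needs >= 2)",
         call. = FALSE)
  }
  scales <- calibrate_scales(config)
  sensors <- sensor_table_()
  fs <- config$fs

  with_seed_(config$seed, {
    sdlog <- sqrt(log(1 + config$condition_av_cv^2))
    abilities <- rlnorm(config$n_subjects, meanlog = -sdlog^2 / 2,
                        sdlog = sdlog)
    handed <- ifelse(runif(config$n_subjects) < config$left_handed_fraction,
                     "left", "right")

    subjects <- lapply(seq_len(config$n_subjects), function(si) {
      sid <- sprintf("S%02d", si)
      # session clock: lead-in, then the four conditions separated by gaps,
      # all boundaries snapped to the sample grid
      t_cursor <- round((2 + runif(1, 0, 0.3)) * fs) / fs
      conds <- list()
      for (cond in CTSIB_CONDITIONS) {
        n_samp <- max(round(9 * fs),
                      round((config$duration_s +
                             rnorm(1, sd = config$duration_jitter_sd)) * fs))
        dur <- n_samp / fs
        cop <- simulate_cop(scales[[cond]] * abilities[si],
                            duration_s = dur, fs = fs,
                            theta = config$mean_reversion_theta)
        cop$t <- cop$t + t_cursor
        recs <- lapply(seq_len(nrow(sensors)), function(k) {
          cop_to_imu(cop, sensors$placement[k], sensors$side[k], config,
                     subject_id = sid, condition = cond)
        })
        names(recs) <- paste(sensors$placement, sensors$side, sep = "_")
        conds[[cond]] <- list(
          cop = cop,
          score = balance_score(cop, cond),
          cue = c(start_s = t_cursor, stop_s = t_cursor + dur),
          recordings = recs)
        t_cursor <- t_cursor + dur +
          round((0.5 + runif(1, 0, 0.3)) * fs) / fs
      }
      list(subject_id = sid, handedness = handed[si],
           ability = abilities[si], conditions = conds,
           session_end_s = t_cursor + 2)
    })
    structure(list(config = config, scales = scales, subjects = subjects),
              class = "sway_cohort")
  })
}

#' @export
print.sway_cohort <- function(x, ...) {
  cat("<sway_cohort> ", length(x$subjects), " subjects x ",
      length(CTSIB_CONDITIONS), " conditions x 8 sensors @ ",
      x$config$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Ground-truth scores of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Data frame with columns `subject_id`, `condition`, `av_in_per_s`,
#'   `pl_in`.
#' @export
cohort_scores <- function(cohort) {
  stopifnot(inherits(cohort, "sway_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               condition = CTSIB_CONDITIONS,
               av_in_per_s = vapply(CTSIB_CONDITIONS, function(cn)
                 s$conditions[[cn]]$score$av, numeric(1)),
               pl_in = vapply(CTSIB_CONDITIONS, function(cn)
                 s$conditions[[cn]]$score$pl, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
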