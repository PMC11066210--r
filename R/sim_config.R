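#' Configuration for the synthetic postural-sway cohort generator
#'
#' Bundles every tunable of the simulator: cohort shape, sway-process
#' dynamics, the per-condition average-velocity (AV) targets the
#' center-of-pressure (COP) traces are calibrated against, and the
#' site-dependent coupling between COP motion and limb acceleration.
#'
#' The default AV targets (inches/second) are the published per-condition
#' cohort means for the four m-CTSIB conditions: 0.33 (EOSS), 0.63 (ECSS),
#' 0.70 (EOFS) and 1.94 (ECFS). Site gains default to a proximal-to-distal
#' attenuation (lumbar = ankle > sternum > wrist > arm) so that trunk and
#' ankle sensors carry the strongest sway signal, and per-recording gain
#' jitter grows distally: wrist and arm accelerations reflect idiosyncratic
#' secondary movement much more than the lumbar site does, which is what
#' limits how well distal sensors can predict the balance score.
#'
#' @param n_subjects Number of subjects in the cohort (default 34).
#' @param duration_s Nominal condition duration in seconds (default 11).
#' @param fs Sampling frequency in Hz (default 128). `fs * duration_s`
#'   must be a whole number of samples.
#' @param condition_av_targets Named numeric vector, target mean AV in
#'   inches/second for exactly the conditions `EOSS`, `ECSS`, `EOFS`, `ECFS`.
#' @param condition_av_cv Coefficient of variation of the log-normal
#'   subject-ability multiplier shared across conditions (default 0.5,
#'   matching the roughly 50% relative spread of the published
#'   per-condition AV standard deviations).
#' @param mean_reversion_theta Mean-reversion rate of the sway process,
#'   1/seconds (default 1).
#' @param site_gains Named numeric vector, dimensionless coupling gain per
#'   placement.
#' @param site_noise_sd Named numeric vector, additive white acceleration
#'   noise SD per placement (arbitrary g-scaled units); zero disables the
#'   noise, which is useful for noise-free checks.
#' @param site_gain_cv Named numeric vector, coefficient of variation of the
#'   per-recording log-normal gain jitter per placement.
#' @param left_handed_fraction Probability a subject is left-side dominant
#'   (default 3/34, the study's handedness split).
#' @param duration_jitter_sd SD in seconds of the per-condition duration
#'   jitter (default 1; conditions never drop below 9 s).
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [calibrate_scales()]
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 1)
#' cfg$condition_av_targets
#' @export
sim_config <- function(n_subjects = 34,
                       duration_s = 11,
                       fs = 128,
                       condition_av_targets = c(EOSS = 0.33, ECSS = 0.63,
                                                EOFS = 0.70, ECFS = 1.94),
                       condition_av_cv = 0.5,
                       mean_reversion_theta = 1.0,
                       site_gains = c(ankle = 0.95, lumbar = 1.0,
                                      sternum = 0.7, wrist = 0.35,
                                      arm = 0.3),
                       site_noise_sd = c(ankle = 3, lumbar = 3,
                                         sternum = 6, wrist = 12,
                                         arm = 12),
                       site_gain_cv = c(ankle = 0.08, lumbar = 0.06,
                                        sternum = 0.25, wrist = 0.6,
                                        arm = 0.7),
                       left_handed_fraction = 3 / 34,
                       duration_jitter_sd = 1.0,
                       seed = 1L) {
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1, n_subjects >= 1,
            is.numeric(duration_s), length(duration_s) == 1, duration_s > 0,
            is.numeric(fs), length(fs) == 1, fs > 0)
  n_samp <- fs * duration_s
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("fs * duration_s must be an integer sample count", call. = FALSE)
  }

  tgt <- condition_av_targets
  if (is.null(names(tgt)) || !setequal(names(tgt), CTSIB_CONDITIONS)) {
    stop("condition_av_targets must be named exactly ",
         paste(CTSIB_CONDITIONS, collapse = ", "), call. = FALSE)
  }
  tgt <- tgt[CTSIB_CONDITIONS]
  if (any(!is.finite(tgt)) || any(tgt <= 0)) {
    stop("condition_av_targets must be strictly positive", call. = FALSE)
  }

  for (nm in c("site_gains", "site_noise_sd", "site_gain_cv")) {
    v <- get(nm)
    if (is.null(names(v)) || !setequal(names(v), SENSOR_PLACEMENTS)) {
      stop(nm, " must be named exactly ",
           paste(SENSOR_PLACEMENTS, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(nm, " entries must be finite and non-negative", call. = FALSE)
    }
  }
  if (any(site_gains[SENSOR_PLACEMENTS] <= 0)) {
    stop("site_gains must be strictly positive", call. = FALSE)
  }

  stopifnot(is.numeric(condition_av_cv), condition_av_cv >= 0,
            is.numeric(mean_reversion_theta), mean_reversion_theta >= 0,
            is.numeric(duration_jitter_sd), duration_jitter_sd >= 0)
  if (left_handed_fraction < 0 || left_handed_fraction > 1) {
    stop("left_handed_fraction must lie in [0, 1]", call. = FALSE)
  }

  structure(
    list(n_subjects = as.integer(n_subjects),
         duration_s = duration_s,
         fs = fs,
         condition_av_targets = tgt,
         condition_av_cv = condition_av_cv,
         mean_reversion_theta = mean_reversion_theta,
         site_gains = site_gains[SENSOR_PLACEMENTS],
         site_noise_sd = site_noise_sd[SENSOR_PLACEMENTS],
         site_gain_cv = site_gain_cv[SENSOR_PLACEMENTS],
         left_handed_fraction = left_handed_fraction,
         duration_jitter_sd = duration_jitter_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  subjects:", x$n_subjects,
      "| fs:", x$fs, "Hz | nominal duration:", x$duration_s, "s\n")
  cat("  AV targets (in/s):",
      paste(sprintf("%s=%.2f", names(x$condition_av_targets),
                    x$condition_av_targets), collapse = " "), "\n")
  cat("  subject-ability CV:", x$condition_av_cv,
      "| theta:", x$mean_reversion_theta, "/s | seed:", x$seed, "\n")
  invisible(x)
}
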