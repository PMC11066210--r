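# Bridges between raw recordings and the wide feature table the models
# consume: one row per (subject, condition, sensor), 42 feature columns plus
# the ground-truth average velocity.

feature_row_ <- function(rec, av, opts) {
  fv <- extract_features(rec, opts)
  cbind(data.frame(subject_id = rec$subject_id, condition = rec$condition,
                   placement = rec$placement, side = rec$side,
                   role = rec$role, av = av, stringsAsFactors = FALSE),
        as.data.frame(as.list(fv)))
}

#' Feature table of an in-memory simulated cohort
#'
#' Runs the preprocessing contract (0.5 s edge trim, axis harmonization,
#' dominance relabeling) and the 42-feature extractor over every requested
#' sensor of every subject x condition, pairing each row with that
#' condition's ground-truth average velocity.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param placements Placements to extract (default all five).
#' @param roles Sensor roles to keep (default all: `dominant`,
#'   `nondominant`, `center`); restricting roles skips the corresponding
#'   extraction work entirely.
#' @param trim_s Seconds trimmed from each segment end (default 0.5).
#' @param opts A [feature_options()].
#' @return Data frame, one row per recording: `subject_id`, `condition`,
#'   `placement`, `side`, `role`, `av`, then the 42 feature columns.
#' @examples
#' co <- simulate_cohort(sim_config(n_subjects = 2, seed = 1))
#' ft <- cohort_features(co, placements = "lumbar")
#' dim(ft)
#' @export
cohort_features <- function(cohort, placements = SENSOR_PLACEMENTS,
                            roles = c("dominant", "nondominant", "center"),
                            trim_s = 0.5, opts = feature_options()) {
  stopifnot(inherits(cohort, "sway_cohort"))
  .assert_placement(placements)
  rows <- list()
  for (s in cohort$subjects) {
    for (cond in CTSIB_CONDITIONS) {
      ce <- s$conditions[[cond]]
      for (rec in ce$recordings) {
        if (!rec$placement %in% placements) next
        role <- assign_dominance(rec$placement, rec$side, s$handedness)
        if (!role %in% roles) next
        prepped <- preprocess_recording(rec, s$handedness, trim_s = trim_s)
        rows[[length(rows) + 1L]] <- feature_row_(prepped, ce$score$av, opts)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_feature_table(out)
  out
}

#' Feature table from an on-disk session directory
#'
#' Reads every `*_manifest.json` under `dir`, loads each sensor's session
#' CSV, segments it by the manifest cues, trims, harmonizes axes, relabels
#' dominance, extracts the 42 features, and joins the ground-truth average
#' velocity from `scores.csv`.
#'
#' @param dir Directory written by [write_cohort()] (or laid out the same
#'   way).
#' @inheritParams cohort_features
#' @return Data frame in the same layout as [cohort_features()].
#' @export
dir_features <- function(dir, placements = SENSOR_PLACEMENTS,
                         trim_s = 0.5, opts = feature_options()) {
  .assert_placement(placements)
  manifests <- list.files(dir, pattern = "_manifest\\.json$",
                          full.names = TRUE)
  if (length(manifests) == 0) {
    stop("no *_manifest.json files under ", dir, call. = FALSE)
  }
  scores_path <- file.path(dir, "scores.csv")
  if (!file.exists(scores_path)) {
    stop("missing scores.csv under ", dir, call. = FALSE)
  }
  scores <- utils::read.csv(scores_path, stringsAsFactors = FALSE)
  rows <- list()
  for (mp in manifests) {
    m <- read_manifest(mp)
    for (k in seq_len(nrow(m$sensors))) {
      placement <- m$sensors$placement[k]
      if (!placement %in% placements) next
      session <- read_recording(file.path(dir, m$sensors$file[k]))
      segs <- segment_by_cues(session, m$cues)
      for (cond in names(segs)) {
        rec <- imu_recording(segs[[cond]]$acc, fs = session$fs,
                             placement = placement,
                             side = m$sensors$side[k],
                             subject_id = m$subject_id, condition = cond,
                             t0 = segs[[cond]]$t[1])
        prepped <- preprocess_recording(rec, m$handedness, trim_s = trim_s)
        av <- scores$av_in_per_s[scores$subject_id == m$subject_id &
                                 scores$condition == cond]
        if (length(av) != 1) {
          stop("scores.csv has no unique AV for ", m$subject_id, " / ", cond,
               call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- feature_row_(prepped, av, opts)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_feature_table(out)
  out
}
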