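# Subject-wise cross-validated evaluation: leave-one-subject-out and
# subject-grouped k-fold splits, MAE / Pearson r / per-condition MAPE, and
# the end-to-end pipeline runner.

#' Mean absolute error
#'
#' @param truth,pred Equal-length numeric vectors.
#' @return `mean(|truth - pred|)`.
#' @export
mae <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  mean(abs(truth - pred))
}

#' Pearson correlation between truth and predictions
#'
#' Returns `NA` (with no error) when either vector is constant, where the
#' coefficient is undefined.
#'
#' @param truth,pred Equal-length numeric vectors.
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 1)
  if (sd(truth) == 0 || sd(pred) == 0) return(NA_real_)
  cor(truth, pred)
}

#' Mean absolute percentage error (as a fraction)
#'
#' `mean(|truth - pred| / truth)`; rows with zero truth are excluded with a
#' warning. Reported as a fraction (0.2 = 20%).
#'
#' @param truth,pred Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
mape <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  keep <- truth != 0
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with zero truth excluded from MAPE",
            call. = FALSE)
  }
  if (!any(keep)) stop("MAPE undefined: all truths are zero", call. = FALSE)
  mean(abs(truth[keep] - pred[keep]) / abs(truth[keep]))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; the test fold is all of that subject's rows.
#'
#' @param subjects Character vector, one entry per dataset row.
#' @return List of folds, each a list with `test_subjects` and
#'   `train_subjects`.
#' @export
loso_splits <- function(subjects) {
  ids <- unique(subjects)
  if (length(ids) < 2) stop("LOSO needs >= 2 subjects", call. = FALSE)
  lapply(ids, function(id) {
    list(test_subjects = id, train_subjects = setdiff(ids, id))
  })
}

#' Subject-grouped k-fold folds
#'
#' Subjects are shuffled under `seed` and split into `k` nearly equal
#' groups (sizes differ by at most one); all of a subject's rows share a
#' fold, so no subject ever appears in both train and test.
#'
#' @param subjects Character vector, one entry per dataset row.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of folds as in [loso_splits()].
#' @export
grouped_kfold <- function(subjects, k = 5, seed = 1L) {
  ids <- unique(subjects)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > length(ids)) {
    stop("k (", k, ") exceeds the subject count (", length(ids), ")",
         call. = FALSE)
  }
  shuffled <- with_seed_(seed, sample(ids))
  groups <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  lapply(groups, function(g) {
    list(test_subjects = g, train_subjects = setdiff(ids, g))
  })
}

# Rows of the feature table for the requested placement(s), with
# placement-prefixed feature columns when several placements are combined.
placement_dataset_ <- function(features, placements, role = NULL) {
  validate_feature_table(features)
  .assert_placement(placements)
  fn <- feature_names()
  parts <- lapply(placements, function(p) {
    r <- if (!is.null(role)) role
         else if (p %in% CENTRAL_PLACEMENTS) "center" else "dominant"
    rows <- features[features$placement == p & features$role == r, ,
                     drop = FALSE]
    if (nrow(rows) == 0) {
      stop("no rows for placement '", p, "' with role '", r, "'",
           call. = FALSE)
    }
    x <- rows[c("subject_id", "condition", "av", fn)]
    if (length(placements) > 1) {
      names(x)[match(fn, names(x))] <- paste(p, fn, sep = "_")
    }
    x
  })
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (i in 2:length(parts)) {
      out <- merge(out, parts[[i]][setdiff(names(parts[[i]]), "av")],
                   by = c("subject_id", "condition"))
    }
  }
  # completeness check: every subject must have every condition
  tab <- table(out$subject_id, out$condition)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("incomplete dataset: subject ", rownames(tab)[bad[1, 1]],
         " has ", tab[bad[1, 1], bad[1, 2]], " row(s) for condition ",
         colnames(tab)[bad[1, 2]], call. = FALSE)
  }
  out
}

#' Cross-validated evaluation of the AV-estimation pipeline
#'
#' Runs the full protocol over a feature table: per fold, a z-score
#' normalizer and (for MLR/SVR) the |r| > 0.7 feature selection are learned
#' from the training subjects only, hyperparameters are grid-searched on an
#' internal shuffled 80/20 split, the winner is refit on the whole training
#' fold, and the held-out subjects are predicted. Multiple placements are
#' combined by horizontal feature concatenation with placement-prefixed
#' names.
#'
#' @param features Feature table (see [cohort_features()]).
#' @param placements One placement, or several to combine.
#' @param kind Model kind: `"mlr"`, `"svr"` or `"gbt"`.
#' @param cv `"loso"` (leave-one-subject-out) or `"kfold"`
#'   (subject-grouped).
#' @param k Folds for `cv = "kfold"` (default 5).
#' @param role Sensor role to analyze for bilateral placements (default
#'   `dominant`; central placements always use `center`).
#' @param grid,threshold,prune,redundancy_threshold,val_fraction Passed to
#'   [train_model()].
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return An object of class `cv_result`: `predictions` (one row per
#'   subject x condition with `truth`, `pred`, `fold`), `metrics`
#'   (pooled test `r`, test MAE mean ± SD across folds, validation MAE
#'   mean ± SD, per-condition MAE and MAPE) and `folds` (selected features
#'   and winning hyperparameters per fold).
#' @examples
#' \donttest{
#' co <- simulate_cohort(sim_config(n_subjects = 6, seed = 2))
#' ft <- cohort_features(co, placements = "lumbar")
#' res <- evaluate_pipeline(ft, "lumbar", kind = "mlr", cv = "loso",
#'                          seed = 2)
#' res$metrics$test_r
#' }
#' @export
evaluate_pipeline <- function(features, placements, kind = c("mlr", "svr", "gbt"),
                              cv = c("loso", "kfold"), k = 5, role = NULL,
                              grid = NULL, threshold = 0.7, prune = FALSE,
                              redundancy_threshold = 0.9, val_fraction = 0.2,
                              seed = 1L) {
  kind <- match.arg(kind)
  cv <- match.arg(cv)
  data <- placement_dataset_(features, placements, role = role)
  feat_cols <- setdiff(names(data), c("subject_id", "condition", "av"))
  folds <- if (cv == "loso") loso_splits(data$subject_id)
           else grouped_kfold(data$subject_id, k = k, seed = seed)

  base_seed <- as.integer(seed) %% 1000000L
  pred_rows <- list()
  fold_info <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr <- data$subject_id %in% fold$train_subjects
    te <- data$subject_id %in% fold$test_subjects
    fold_seed <- base_seed * 1000L + fi
    model <- train_model(data[tr, feat_cols, drop = FALSE], data$av[tr],
                         kind = kind, grid = grid, threshold = threshold,
                         prune = prune,
                         redundancy_threshold = redundancy_threshold,
                         val_fraction = val_fraction, seed = fold_seed)
    pred <- predict(model, data[te, feat_cols, drop = FALSE])
    pred_rows[[fi]] <- data.frame(
      subject_id = data$subject_id[te], condition = data$condition[te],
      truth = data$av[te], pred = pred, fold = fi,
      stringsAsFactors = FALSE)
    fold_info[[fi]] <- list(fold = fi, selected = model$features,
                            hp = model$hp, val_mae = model$val_mae)
  }
  preds <- do.call(rbind, pred_rows)
  rownames(preds) <- NULL

  fold_mae <- vapply(pred_rows, function(p) mae(p$truth, p$pred), numeric(1))
  val_mae <- vapply(fold_info, function(f) f$val_mae, numeric(1))
  per_condition <- do.call(rbind, lapply(CTSIB_CONDITIONS, function(cn) {
    rows <- preds[preds$condition == cn, ]
    data.frame(condition = cn,
               mae = mae(rows$truth, rows$pred),
               mape = mape(rows$truth, rows$pred),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    cv = cv, placements = placements, kind = kind, seed = seed,
    predictions = preds,
    folds = fold_info,
    metrics = list(
      test_r = pearson_r(preds$truth, preds$pred),
      test_mae = mean(fold_mae),
      test_mae_sd = sd(fold_mae),
      val_mae = if (all(is.na(val_mae))) NA_real_ else
        mean(val_mae, na.rm = TRUE),
      val_mae_sd = if (all(is.na(val_mae))) NA_real_ else
        sd(val_mae[!is.na(val_mae)]),
      per_condition = per_condition)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cv_result> %s / %s / %s: pooled test r = %.3f, test MAE = %.3f +/- %.3f\n",
              paste(x$placements, collapse = "+"), toupper(x$kind),
              toupper(x$cv), m$test_r, m$test_mae,
              ifelse(is.na(m$test_mae_sd), 0, m$test_mae_sd)))
  print(m$per_condition, row.names = FALSE)
  invisible(x)
}

#' Feature-to-score correlation report for one placement
#'
#' Pearson correlation of each of the 42 (z-scored) features with the AV
#' balance score, flagging as significant the features whose |r| exceeds
#' the threshold.
#'
#' @param features Feature table.
#' @param placement One placement.
#' @param role Sensor role (defaults as in [evaluate_pipeline()]).
#' @param threshold Significance threshold on |r| (default 0.7).
#' @return Data frame with 42 rows: `feature`, `r`, `abs_r`, `significant`.
#' @export
feature_correlation_report <- function(features, placement, role = NULL,
                                       threshold = 0.7) {
  data <- placement_dataset_(features, placement, role = role)
  fn <- feature_names()
  x <- as.matrix(data[fn])
  x <- apply_normalizer(fit_normalizer(x), x)
  r <- vapply(fn, function(f) {
    if (sd(x[, f]) == 0) 0 else cor(x[, f], data$av)
  }, numeric(1))
  data.frame(feature = fn, r = unname(r), abs_r = unname(abs(r)),
             significant = unname(abs(r) > threshold),
             stringsAsFactors = FALSE)
}
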