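# Regression models for AV-score estimation: z-score normalization learned
# from training rows only, correlation-threshold feature selection, multiple
# linear regression solved directly by orthogonal (SVD) least squares, and
# SVR / gradient-boosted tree backends with the published hyperparameter
# grids. All randomness is seed-controlled; GBT runs single-threaded so fits
# are bit-reproducible.

as_feature_matrix_ <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("features must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    stop("feature columns must be named", call. = FALSE)
  }
  x
}

#' Fit / apply a z-score normalizer
#'
#' Learns per-feature mean and standard deviation from training rows only;
#' applying it to the training set gives column means 0 and SDs 1.
#' Zero-variance features pass through centered but unscaled (their SD is
#' treated as 1).
#'
#' @param train Numeric matrix or data frame of training features (>= 2
#'   rows, named columns).
#' @return `fit_normalizer()` returns an object of class `sway_normalizer`;
#'   `apply_normalizer()` returns the transformed matrix.
#' @export
fit_normalizer <- function(train) {
  x <- as_feature_matrix_(train)
  if (nrow(x) < 2) stop("normalizer needs >= 2 training rows", call. = FALSE)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  structure(list(mean = mu, sd = s, features = colnames(x)),
            class = "sway_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `sway_normalizer`.
#' @param features Matrix or data frame containing (at least) the training
#'   feature columns.
#' @export
apply_normalizer <- function(normalizer, features) {
  stopifnot(inherits(normalizer, "sway_normalizer"))
  x <- as_feature_matrix_(features)
  missing_cols <- setdiff(normalizer$features, colnames(x))
  if (length(missing_cols)) {
    stop("missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, normalizer$features, drop = FALSE]
  sweep(sweep(x, 2, normalizer$mean, "-"), 2, normalizer$sd, "/")
}

abs_cor_ <- function(x, y) {
  apply(x, 2, function(col) {
    if (sd(col) == 0 || sd(y) == 0) 0 else abs(cor(col, y))
  })
}

#' Correlation-threshold feature selection
#'
#' Selects, from the training rows only, the features whose absolute
#' Pearson correlation with the training AV scores exceeds `threshold`
#' (default 0.7). If no feature passes, the single highest-|r| feature is
#' kept (with a warning) so that downstream folds never abort.
#'
#' @param train Training feature matrix or data frame (>= 3 rows).
#' @param av Training AV scores.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return Character vector of selected feature names, in feature-table
#'   order.
#' @export
select_features <- function(train, av, threshold = 0.7) {
  x <- as_feature_matrix_(train)
  stopifnot(nrow(x) >= 3, length(av) == nrow(x))
  r <- abs_cor_(x, av)
  sel <- colnames(x)[r > threshold]
  if (length(sel) == 0) {
    warning("no feature exceeded |r| > ", threshold,
            "; falling back to the single best feature", call. = FALSE)
    sel <- colnames(x)[which.max(r)]
  }
  sel
}

#' Prune mutually redundant selected features
#'
#' Greedy pass in descending |r(feature, AV)|: a candidate is dropped when
#' its absolute correlation with an already-kept feature exceeds
#' `redundancy_threshold`. Off by default in the pipeline; exposed for
#' sensitivity analyses.
#'
#' @param selected Character vector of selected feature names.
#' @param train Training feature matrix (columns include `selected`).
#' @param av Training AV scores.
#' @param redundancy_threshold Pairwise |r| above which a feature is
#'   redundant (default 0.9).
#' @return Pruned feature names, in the original column order.
#' @export
prune_redundant <- function(selected, train, av, redundancy_threshold = 0.9) {
  x <- as_feature_matrix_(train)[, selected, drop = FALSE]
  if (length(selected) <= 1) return(selected)
  r <- abs_cor_(x, av)
  kept <- character(0)
  for (f in selected[order(-r)]) {
    redundant <- any(vapply(kept, function(g) {
      cc <- if (sd(x[, f]) == 0 || sd(x[, g]) == 0) 0 else abs(cor(x[, f], x[, g]))
      cc > redundancy_threshold
    }, logical(1)))
    if (!redundant) kept <- c(kept, f)
  }
  selected[selected %in% kept]
}

#' Multiple linear regression by orthogonal least squares
#'
#' Solves the least-squares problem for
#' \eqn{Y = \beta_0 + \beta_1 X_1 + \dots + \beta_n X_n + \epsilon}
#' directly through the singular value decomposition of the design matrix,
#' returning the minimum-norm solution (with a warning) when the design is
#' rank-deficient.
#'
#' @param train Training feature matrix or data frame (>= 2 rows).
#' @param av Training AV scores.
#' @return An object of class `mlr_fit`: `intercept`, named `coef`,
#'   `fitted`, `residual_sd`.
#' @export
fit_mlr <- function(train, av) {
  x <- as_feature_matrix_(train)
  stopifnot(length(av) == nrow(x))
  if (nrow(x) < 2) stop("MLR needs >= 2 rows", call. = FALSE)
  A <- cbind(`(Intercept)` = 1, x)
  sv <- svd(A)
  tol <- max(sv$d) * max(dim(A)) * .Machine$double.eps
  pos <- sv$d > tol
  if (sum(pos) < ncol(A)) {
    warning("rank-deficient design; returning the minimum-norm solution",
            call. = FALSE)
  }
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], av)) / sv$d[pos])
  beta <- drop(beta)
  names(beta) <- colnames(A)
  fitted <- drop(A %*% beta)
  structure(list(intercept = beta[["(Intercept)"]],
                 coef = beta[-1],
                 fitted = fitted,
                 residual_sd = sd(av - fitted)),
            class = "mlr_fit")
}

#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  x <- as_feature_matrix_(newdata)
  missing_cols <- setdiff(names(object$coef), colnames(x))
  if (length(missing_cols)) {
    stop("missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  drop(object$intercept +
         x[, names(object$coef), drop = FALSE] %*% object$coef)
}

#' Hyperparameter grids for SVR and GBT
#'
#' Discrete grids spanning the tuned ranges: SVR over linear and RBF
#' kernels with C in \{0.1, 1, 10\} and epsilon in
#' \{0.01, 0.05, 0.1, 0.2\}; GBT over 10-200 trees in steps of 20, maximum
#' depth 3-9 in steps of 2, and feature subsampling rate 0.1-0.5.
#'
#' @param kernel,C,epsilon SVR grid axes.
#' @param n_trees,max_depth,subsample_rate GBT grid axes.
#' @return Data frame with one row per grid point, ordered so that ties in
#'   validation error resolve toward the simpler model.
#' @export
svr_grid <- function(kernel = c("linear", "radial"),
                     C = c(0.1, 1, 10),
                     epsilon = c(0.01, 0.05, 0.1, 0.2)) {
  g <- expand.grid(kernel = kernel, C = C, epsilon = epsilon,
                   stringsAsFactors = FALSE)
  g[order(g$C, -g$epsilon, g$kernel != "linear"), , drop = FALSE]
}

#' @rdname svr_grid
#' @export
gbt_grid <- function(n_trees = seq(10, 200, by = 20),
                     max_depth = seq(3, 9, by = 2),
                     subsample_rate = seq(0.1, 0.5, by = 0.1)) {
  g <- expand.grid(n_trees = n_trees, max_depth = max_depth,
                   subsample_rate = subsample_rate)
  g[order(g$n_trees, g$max_depth, g$subsample_rate), , drop = FALSE]
}

default_grid_ <- function(kind) {
  switch(kind, svr = svr_grid(), gbt = gbt_grid(),
         mlr = data.frame(row.names = 1))
}

validate_hp_ <- function(kind, hp) {
  if (kind == "svr") {
    stopifnot(hp$kernel %in% c("linear", "radial"))
    if (hp$C < 0.1 || hp$C > 10 || hp$epsilon < 0.01 || hp$epsilon > 0.2) {
      stop("SVR hyperparameters out of range: C in [0.1, 10], ",
           "epsilon in [0.01, 0.2]", call. = FALSE)
    }
  } else if (kind == "gbt") {
    if (hp$n_trees < 10 || hp$n_trees > 200 ||
        hp$max_depth < 3 || hp$max_depth > 10 ||
        hp$subsample_rate < 0.1 || hp$subsample_rate > 0.5) {
      stop("GBT hyperparameters out of range: n_trees in [10, 200], ",
           "max_depth in [3, 10], subsample_rate in [0.1, 0.5]",
           call. = FALSE)
    }
  }
  invisible(hp)
}

#' Fit a support vector regression model
#'
#' Epsilon-insensitive SVR (`Y = <w, phi(X)> + b`) on pre-normalized
#' features, delegated to the libsvm backend.
#'
#' @param train Training feature matrix (already normalized).
#' @param av Training AV scores.
#' @param hp One-row data frame or list with `kernel`, `C`, `epsilon`.
#' @return A fitted `e1071::svm` object.
#' @export
fit_svr <- function(train, av, hp) {
  validate_hp_("svr", hp)
  x <- as_feature_matrix_(train)
  e1071::svm(x = x, y = av, type = "eps-regression",
             kernel = as.character(hp$kernel), cost = hp$C,
             epsilon = hp$epsilon, scale = FALSE)
}

#' Fit a gradient-boosted tree regression model
#'
#' Additive tree ensemble (`Y = sum_k f_k(X)`) via the xgboost backend,
#' squared-error objective, single-threaded and explicitly seeded so fits
#' are reproducible.
#'
#' @param train Training feature matrix.
#' @param av Training AV scores.
#' @param hp One-row data frame or list with `n_trees`, `max_depth`,
#'   `subsample_rate` (feature subsampling per tree).
#' @param seed Integer seed for the backend's column subsampling.
#' @return An `xgb.Booster` wrapped with its feature names.
#' @export
fit_gbt <- function(train, av, hp, seed = 1L) {
  validate_hp_("gbt", hp)
  x <- as_feature_matrix_(train)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(av), nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = as.integer(hp$max_depth),
                  colsample_bytree = hp$subsample_rate,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = as.integer(hp$n_trees), verbose = 0)
  structure(list(booster = booster, features = colnames(x)),
            class = "gbt_fit")
}

#' @export
predict.gbt_fit <- function(object, newdata, ...) {
  x <- as_feature_matrix_(newdata)[, object$features, drop = FALSE]
  predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

fit_backend_ <- function(kind, x, av, hp, seed) {
  switch(kind,
         mlr = fit_mlr(x, av),
         svr = fit_svr(x, av, hp),
         gbt = fit_gbt(x, av, hp, seed = seed))
}

predict_backend_ <- function(kind, fit, x) {
  switch(kind,
         mlr = predict(fit, x),
         svr = as.numeric(predict(fit, as_feature_matrix_(x))),
         gbt = predict(fit, x))
}

#' Grid-search hyperparameters on a single shuffled 80/20 split
#'
#' Shuffles the training rows once under `seed`, holds out
#' `val_fraction` of them for validation, fits every grid point on the
#' remaining rows, and returns the point minimizing validation MAE. The
#' grid rows are pre-ordered from simple to complex (see [svr_grid()] /
#' [gbt_grid()]), so exact ties resolve toward the simpler model.
#'
#' @param train Training feature matrix (already normalized and selected).
#' @param av Training AV scores.
#' @param kind `"svr"` or `"gbt"` (MLR has no hyperparameters).
#' @param grid Grid data frame; defaults to the published grid for `kind`.
#' @param val_fraction Fraction of rows held out for validation
#'   (default 0.2).
#' @param seed Integer seed controlling the shuffle (and GBT subsampling).
#' @return List with `hp` (winning one-row grid), `val_mae`, and
#'   `val_mae_all` (per grid point).
#' @export
grid_search <- function(train, av, kind = c("svr", "gbt"), grid = NULL,
                        val_fraction = 0.2, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid_(kind)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  x <- as_feature_matrix_(train)
  n <- nrow(x)
  n_val <- max(2, round(val_fraction * n))
  if (n - n_val < 2) stop("too few rows for an 80/20 split", call. = FALSE)
  idx <- with_seed_(seed, sample.int(n))
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  val_mae <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- grid[i, , drop = FALSE]
    fit <- fit_backend_(kind, x[tr, , drop = FALSE], av[tr], hp, seed = seed)
    mae(av[val], predict_backend_(kind, fit, x[val, , drop = FALSE]))
  }, numeric(1))
  best <- which.min(val_mae)
  list(hp = grid[best, , drop = FALSE], val_mae = val_mae[best],
       val_mae_all = val_mae)
}

#' Train one AV-estimation model on a training fold
#'
#' The full per-fold procedure: learn a z-score normalizer from the
#' training rows, select features by the |r| > `threshold` rule (MLR and
#' SVR only; GBT keeps all features and relies on its built-in selection),
#' grid-search hyperparameters on an internal 80/20 split, then refit on
#' the complete training fold with the winning hyperparameters.
#'
#' @param train Training feature matrix or data frame (named columns).
#' @param av Training AV scores (inches/second).
#' @param kind `"mlr"`, `"svr"` or `"gbt"`.
#' @param grid Hyperparameter grid (defaults to the published grid).
#' @param threshold Feature-selection |r| threshold (default 0.7).
#' @param prune If `TRUE`, additionally prune selected features that are
#'   mutually correlated above `redundancy_threshold`.
#' @param redundancy_threshold Pairwise |r| pruning threshold (default 0.9).
#' @param val_fraction Validation fraction for the grid search.
#' @param seed Integer seed.
#' @return An object of class `sway_model` holding the normalizer, the
#'   selected feature names, the fitted backend, the winning
#'   hyperparameters and the validation MAE.
#' @export
train_model <- function(train, av, kind = c("mlr", "svr", "gbt"),
                        grid = NULL, threshold = 0.7, prune = FALSE,
                        redundancy_threshold = 0.9, val_fraction = 0.2,
                        seed = 1L) {
  kind <- match.arg(kind)
  x <- as_feature_matrix_(train)
  stopifnot(length(av) == nrow(x))
  norm <- fit_normalizer(x)
  xn <- apply_normalizer(norm, x)
  if (kind %in% c("mlr", "svr")) {
    sel <- select_features(xn, av, threshold = threshold)
    if (prune) sel <- prune_redundant(sel, xn, av, redundancy_threshold)
  } else {
    sel <- colnames(xn)
  }
  xs <- xn[, sel, drop = FALSE]
  if (kind == "mlr") {
    hp <- NULL
    val_mae <- NA_real_
  } else {
    gs <- grid_search(xs, av, kind, grid = grid,
                      val_fraction = val_fraction, seed = seed)
    hp <- gs$hp
    val_mae <- gs$val_mae
  }
  fit <- fit_backend_(kind, xs, av, hp, seed = seed)
  structure(list(kind = kind, normalizer = norm, features = sel,
                 fit = fit, hp = hp, val_mae = val_mae, seed = seed),
            class = "sway_model")
}

#' Predict AV scores with a trained model
#'
#' Applies, in order, the training-fold normalizer, the training-fold
#' feature selection, and the fitted backend. Errors name any missing
#' feature column.
#'
#' @param object A [train_model()] result.
#' @param newdata Feature matrix or data frame containing the training
#'   feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted AV (inches/second).
#' @export
predict.sway_model <- function(object, newdata, ...) {
  xn <- apply_normalizer(object$normalizer, newdata)
  xs <- xn[, object$features, drop = FALSE]
  out <- predict_backend_(object$kind, object$fit, xs)
  stopifnot(all(is.finite(out)))
  out
}

#' @export
print.sway_model <- function(x, ...) {
  cat(sprintf("<sway_model> %s, %d feature(s)%s\n", toupper(x$kind),
              length(x$features),
              if (is.null(x$hp)) "" else paste0(
                "; hp: ", paste(names(x$hp), unlist(x$hp), sep = "=",
                                collapse = " "))))
  invisible(x)
}
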