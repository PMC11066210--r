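test_that("normalizer learns training statistics and guards constants", {
  tr <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "f1"))
  nz <- fit_normalizer(tr)
  expect_equal(nz$mean[["f1"]], 1)
  expect_equal(nz$sd[["f1"]], sqrt(2))
  expect_equal(apply_normalizer(nz, matrix(1, 1, 1,
                                           dimnames = list(NULL, "f1")))[1],
               0)
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  xn <- apply_normalizer(fit_normalizer(x), x)
  expect_true(all(abs(colMeans(xn)) < 1e-12))
  expect_true(all(abs(apply(xn, 2, sd) - 1) < 1e-12))
  # constant column: centered only, stays constant (sd treated as 1)
  x[, "c"] <- 7
  xc <- apply_normalizer(fit_normalizer(x), x)
  expect_true(all(xc[, "c"] == 0))
  expect_error(fit_normalizer(x[1, , drop = FALSE]), ">= 2")
})

test_that("correlation-threshold selection keeps |r| > 0.7 features only", {
  set.seed(2)
  av <- rnorm(100)
  x <- cbind(pos = av, neg = -av, noise = rnorm(100))
  sel <- select_features(x, av, threshold = 0.7)
  expect_identical(sel, c("pos", "neg"))
  # a pure-noise feature survives essentially never at n = 100
  hits <- 0
  for (i in 1:500) {
    x2 <- cbind(sig = av + rnorm(100, sd = 0.1), noise = rnorm(100))
    if ("noise" %in% select_features(x2, av)) hits <- hits + 1
  }
  expect_lte(hits, 5)  # excluded in >= 99% of repetitions
  # empty selection falls back to the single best feature, with a warning
  xn <- cbind(n1 = rnorm(100), n2 = rnorm(100))
  expect_warning(sel2 <- select_features(xn, av), "falling back")
  expect_length(sel2, 1)
})

test_that("redundancy pruning keeps one representative per correlated block", {
  set.seed(3)
  av <- rnorm(200)
  dup <- av + rnorm(200, sd = 0.05)
  x <- cbind(f1 = dup, f2 = dup, f3 = rnorm(200))
  expect_identical(prune_redundant(c("f1", "f2"), x, av), "f1")
  orth <- cbind(a = rnorm(200), b = rnorm(200))
  expect_identical(prune_redundant(c("a", "b"), orth, av), c("a", "b"))
  # three mutually redundant features: the one closest to av survives
  base <- rnorm(200)
  x3 <- cbind(best = base + rnorm(200, sd = 0.01),
              mid = base + rnorm(200, sd = 0.02),
              worst = base + rnorm(200, sd = 0.03))
  expect_identical(prune_redundant(c("best", "mid", "worst"), x3, base),
                   "best")
})

test_that("MLR recovers exact linear models and satisfies least-squares identities", {
  set.seed(4)
  x <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "x1"))
  fit <- fit_mlr(x, 2 * x[, 1] + 3)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$coef[["x1"]], 2, tolerance = 1e-10)
  # constant response
  fitc <- fit_mlr(x, rep(5, 10))
  expect_equal(fitc$intercept, 5, tolerance = 1e-10)
  expect_lt(abs(fitc$coef[["x1"]]), 1e-10)
  # 50 x 5 noiseless recovery + residual orthogonality under noise
  X <- matrix(rnorm(250), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  beta <- c(1.5, -2, 0.3, 0, 4)
  fit5 <- fit_mlr(X, drop(X %*% beta) + 7)
  expect_equal(unname(fit5$coef), beta, tolerance = 1e-8)
  yn <- drop(X %*% beta) + rnorm(50)
  fitn <- fit_mlr(X, yn)
  resid <- yn - predict(fitn, X)
  expect_true(all(abs(crossprod(cbind(1, X), resid)) < 1e-8))
  # rank deficiency: minimum-norm solution with a warning
  Xd <- cbind(X, f6 = X[, 1])
  expect_warning(fit_mlr(Xd, yn), "rank-deficient")
})

test_that("MLR agrees with a normal-equations oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(20:60, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n)
    fit <- fit_mlr(X, y)
    A <- cbind(1, X)
    beta_oracle <- solve(crossprod(A), crossprod(A, y))
    expect_equal(unname(c(fit$intercept, fit$coef)),
                 unname(drop(beta_oracle)), tolerance = 1e-8)
  }
})

test_that("SVR fits noiseless linear data tightly and validates ranges", {
  set.seed(6)
  X <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(1, -2)) + 0.5
  fit <- fit_svr(X[1:60, ], y[1:60],
                 list(kernel = "linear", C = 10, epsilon = 0.01))
  pred <- predict(fit, X[61:80, ])
  expect_lt(mae(y[61:80], as.numeric(pred)), 0.02)
  expect_error(fit_svr(X, y, list(kernel = "linear", C = 100,
                                  epsilon = 0.01)), "out of range")
})

test_that("GBT fits beat the intercept baseline and are seed-deterministic", {
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- drop(X %*% c(2, 1, 0, 0))
  hp <- list(n_trees = 10, max_depth = 3, subsample_rate = 0.5)
  fit <- fit_gbt(X, y, hp, seed = 9)
  expect_lt(mae(y, predict(fit, X)), mae(y, rep(mean(y), 50)))
  fit2 <- fit_gbt(X, y, hp, seed = 9)
  expect_identical(predict(fit, X), predict(fit2, X))
  expect_error(fit_gbt(X, y, list(n_trees = 500, max_depth = 3,
                                  subsample_rate = 0.5)), "out of range")
})

test_that("grid search picks the generating complexity and is deterministic", {
  set.seed(8)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 2, -1))
  single <- svr_grid(kernel = "linear", C = 1, epsilon = 0.1)
  gs <- grid_search(X, y, "svr", grid = single, seed = 1)
  expect_identical(nrow(gs$hp), 1L)
  expect_equal(gs$hp$C, 1)
  # a flexible fit vs a gross under-fit on noiseless linear data
  duo <- svr_grid(kernel = "linear", C = c(0.1, 10),
                  epsilon = c(0.2, 0.01))
  gs2 <- grid_search(X, y, "svr", grid = duo, seed = 1)
  expect_equal(gs2$hp$C, 10)
  expect_equal(gs2$hp$epsilon, 0.01)
  gs3 <- grid_search(X, y, "svr", grid = duo, seed = 1)
  expect_identical(gs2$hp, gs3$hp)
  expect_error(grid_search(X, y, "svr", grid = svr_grid()[0, ]), "empty")
})

test_that("trained models apply normalizer, selection and backend in order", {
  set.seed(9)
  n <- 60
  f1 <- rnorm(n)
  av <- 3 * f1 + 1
  X <- cbind(f1 = f1, f2 = f1 + rnorm(n, sd = 0.05), f3 = rnorm(n))
  m <- train_model(X, av, kind = "mlr")
  expect_true(all(m$features %in% c("f1", "f2")))
  expect_false("f3" %in% m$features)
  # fitted values reproduce on the training rows
  expect_equal(predict(m, X), predict(m$fit,
               apply_normalizer(m$normalizer, X)[, m$features, drop = FALSE]),
               tolerance = 1e-12)
  expect_lt(mae(av, predict(m, X)), 1e-8)
  # missing columns are named
  expect_error(predict(m, X[, c("f1", "f3")]), "f2")
  # constant response predicts the constant
  mc <- suppressWarnings(train_model(cbind(f1 = f1), rep(2.5, n),
                                     kind = "mlr"))
  expect_equal(unname(predict(mc, cbind(f1 = rnorm(5)))), rep(2.5, 5),
               tolerance = 1e-8)
})

test_that("fold training depends on training rows only", {
  ft <- shared_lumbar_features()
  res <- evaluate_pipeline(ft, "lumbar", kind = "mlr", cv = "loso", seed = 3)
  # corrupt the held-out subject of fold 1; its fold must train identically
  test_subj <- res$predictions$subject_id[res$predictions$fold == 1][1]
  ft2 <- ft
  corrupt <- ft2$subject_id == test_subj
  ft2$av[corrupt] <- ft2$av[corrupt] * 10 + 5
  ft2[corrupt, feature_names()] <- ft2[corrupt, feature_names()] * 2
  res2 <- evaluate_pipeline(ft2, "lumbar", kind = "mlr", cv = "loso",
                            seed = 3)
  expect_identical(res2$folds[[1]]$selected, res$folds[[1]]$selected)
  # and the fold-1 model itself is bit-identical: train it directly from the
  # two tables' training rows and compare coefficients
  feat <- feature_names()
  tr1 <- ft[ft$subject_id != test_subj, ]
  tr2 <- ft2[ft2$subject_id != test_subj, ]
  m1 <- train_model(as.matrix(tr1[feat]), tr1$av, kind = "mlr", seed = 1)
  m2 <- train_model(as.matrix(tr2[feat]), tr2$av, kind = "mlr", seed = 1)
  expect_identical(m1$features, m2$features)
  expect_identical(m1$fit$coef, m2$fit$coef)
})
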