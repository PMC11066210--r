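test_that("moment statistics match closed forms and guard constants", {
  s <- stat_features(c(1, 2, 3, 4, 5))
  expect_equal(s[["sd"]], sqrt(2.5), tolerance = 1e-12)
  expect_equal(s[["skewness"]], 0, tolerance = 1e-12)
  expect_identical(stat_features(rep(3, 4)), c(sd = 0, skewness = 0,
                                               kurtosis = 0))
  set.seed(8)
  g <- stat_features(rnorm(1e5))
  expect_lt(abs(g[["kurtosis"]]), 0.1)
  expect_lt(abs(g[["skewness"]]), 0.05)
})

test_that("Hoyer sparsity spans its closed-form extremes", {
  expect_equal(sparsity(c(0, 0, 1, 0)), 1.0)
  expect_equal(sparsity(c(1, 1, 1, 1)), 0.0)
  expect_equal(sparsity(c(-1, 1, -1, 1)), 0.0)  # constant magnitude
  expect_equal(sparsity(c(1, 1, 0, 0)), 2 - sqrt(2), tolerance = 1e-12)
  expect_equal(sparsity(c(0, 0, 0, 0)), 0.0)
})

test_that("histogram entropy hits its bounds", {
  expect_equal(shannon_entropy(rep(2.5, 100)), 0)
  # exactly equal counts in all 16 bins
  x <- rep((0:15) + 0.5, each = 5) / 16
  expect_equal(shannon_entropy(x, 16), 4.0, tolerance = 1e-12)
  set.seed(12)
  expect_lt(abs(shannon_entropy(runif(1e4), 16) - 4), 0.05)
  # affine invariance: bins track the range
  set.seed(13); z <- rnorm(500)
  expect_equal(shannon_entropy(3 * z + 10), shannon_entropy(z),
               tolerance = 1e-12)
})

test_that("sample entropy equals the naive pair-counting oracle", {
  expect_equal(sample_entropy(rep(1, 32)), 0)
  alt <- rep(c(1, 2), 32)
  expect_equal(sample_entropy(alt), naive_sampen(alt), tolerance = 1e-12)
  set.seed(14)
  w <- rnorm(512)
  expect_equal(sample_entropy(w), naive_sampen(w), tolerance = 1e-12)
  expect_gt(sample_entropy(w), 0.5)
  for (i in 1:10) {
    x <- rnorm(sample(20:128, 1))
    expect_equal(sample_entropy(x), naive_sampen(x), tolerance = 1e-12)
  }
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
})

test_that("spectral features recover known tones", {
  t <- (0:255) / 128
  pure <- sin(2 * pi * 8 * t)
  sf <- spectral_features(pure, 128)
  expect_equal(sf[["main_freq"]], 8)
  expect_equal(sf[["main_freq_power"]], 0.5, tolerance = 1e-9)  # A^2/2
  expect_lt(sf[["spectral_entropy"]], 1e-6)
  two <- 2 * sin(2 * pi * 4 * t) + sin(2 * pi * 10 * t)
  sf2 <- spectral_features(two, 128)
  expect_equal(sf2[["main_freq"]], 4)
  expect_equal(sf2[["secondary_freq"]], 10)
  expect_gte(sf2[["main_freq_power"]], sf2[["secondary_freq_power"]])
  expect_identical(unname(spectral_features(rep(1, 64), 128)), rep(0, 5))
})

test_that("difference sum and average jerk follow hand arithmetic", {
  expect_equal(difference_sum(c(0, 1, 2, 3)), 3)
  expect_equal(difference_sum(c(0, 2, 1)), 3)
  expect_equal(difference_sum(rep(5, 10)), 0)
  expect_equal(difference_sum(c(0, 1) + 100), 1)  # shift-invariant
  expect_equal(average_jerk(rep(2, 50), 128), 0)
  expect_equal(average_jerk(seq(0, 10, by = 1), 128), 128)
  expect_equal(average_jerk(seq(0, 5, by = 0.5), 128), 64)
})

test_that("cross correlation is bounded, symmetric and guarded", {
  set.seed(15)
  x <- rnorm(100)
  expect_equal(cross_correlation(x, x), 1.0)
  expect_equal(cross_correlation(x, -x), -1.0)
  expect_equal(cross_correlation(x, 2 * x + 5), 1.0)
  y <- rnorm(100)
  expect_equal(cross_correlation(x, y), cross_correlation(y, x))
  expect_equal(cross_correlation(x, rep(1, 100)), 0)
  expect_lt(abs(cross_correlation(rnorm(1e4), rnorm(1e4))), 0.05)
})

test_that("extract_features yields 42 named finite values in fixed order", {
  rec <- noise_recording(n = 256)
  fv <- extract_features(rec)
  expect_length(fv, 42)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  zero <- imu_recording(matrix(0, 64, 3), 128, "lumbar", "center",
                        frame = "body")
  fz <- extract_features(zero)
  expect_length(fz, 42)
  expect_true(all(fz == 0))
  raw <- imu_recording(matrix(rnorm(192), 64, 3), 128, "lumbar", "center")
  expect_error(extract_features(raw), "body-frame")
})

test_that("swapping ML and AP axes swaps the per-axis blocks coherently", {
  rec <- noise_recording(n = 256, seed = 20)
  swapped <- rec
  swapped$acc <- rec$acc[, c(2, 1, 3)]
  colnames(swapped$acc) <- c("ML", "AP", "VT")
  f1 <- extract_features(rec)
  f2 <- extract_features(swapped)
  for (feat in c("sd", "sample_entropy", "main_freq", "average_jerk")) {
    expect_equal(f2[[paste0("ML_", feat)]], f1[[paste0("AP_", feat)]])
    expect_equal(f2[[paste0("AP_", feat)]], f1[[paste0("ML_", feat)]])
    expect_equal(f2[[paste0("VT_", feat)]], f1[[paste0("VT_", feat)]])
  }
  expect_equal(f2[["xcorr_MLAP"]], f1[["xcorr_MLAP"]])
  expect_equal(f2[["xcorr_MLVT"]], f1[["xcorr_APVT"]])
  expect_equal(f2[["xcorr_APVT"]], f1[["xcorr_MLVT"]])
})

test_that("features transform correctly under affine maps of the signal", {
  set.seed(16)
  for (i in 1:5) {
    x <- rnorm(200) + sin(2 * pi * 5 * (0:199) / 128)
    a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
    y <- a * x + b
    expect_equal(stat_features(y)[["skewness"]],
                 stat_features(x)[["skewness"]], tolerance = 1e-9)
    expect_equal(stat_features(y)[["kurtosis"]],
                 stat_features(x)[["kurtosis"]], tolerance = 1e-9)
    expect_equal(shannon_entropy(y), shannon_entropy(x), tolerance = 1e-9)
    expect_equal(sample_entropy(y), sample_entropy(x), tolerance = 1e-9)
    expect_equal(spectral_features(y, 128)[["main_freq"]],
                 spectral_features(x, 128)[["main_freq"]])
    expect_equal(stat_features(y)[["sd"]], a * stat_features(x)[["sd"]],
                 tolerance = 1e-9)
    expect_equal(difference_sum(y), a * difference_sum(x), tolerance = 1e-9)
    expect_equal(average_jerk(y, 128), a * average_jerk(x, 128),
                 tolerance = 1e-9)
  }
})

test_that("lumbar ML/AP features track av more strongly than VT features", {
  ft <- shared_lumbar_features()
  rpt <- feature_correlation_report(ft, "lumbar")
  ml <- rpt$abs_r[startsWith(rpt$feature, "ML_")]
  vt <- rpt$abs_r[startsWith(rpt$feature, "VT_")]
  expect_gt(mean(ml), mean(vt))
})
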