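# Shared fixtures and independent oracles.

# Naive O(N^2) sample-entropy oracle: direct pair counting over explicit
# template matrices, independent of the package's C++ kernel.
naive_sampen <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  nt <- n - m
  count_pairs <- function(len) {
    tem <- sapply(seq_len(nt), function(i) x[i:(i + len - 1)])
    tem <- matrix(tem, nrow = len)
    cnt <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(tem[, i] - tem[, j])) <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (B == 0 || A == 0) return(log(n - m))
  -log(A / B)
}

# A valid body-frame recording built from white noise.
noise_recording <- function(n = 256, fs = 128, seed = 1) {
  set.seed(seed)
  imu_recording(matrix(rnorm(3 * n), n, 3), fs = fs, placement = "lumbar",
                side = "center", frame = "body", role = "center")
}

# Small cohort + lumbar feature table, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(sim_config(n_subjects = 8,
                                                      seed = 11))
  }
  .fixture_env$cohort
}

shared_lumbar_features <- function() {
  if (is.null(.fixture_env$lumbar)) {
    .fixture_env$lumbar <- cohort_features(shared_cohort(),
                                           placements = "lumbar")
  }
  .fixture_env$lumbar
}

# A synthetic feature table with controllable av (all 42 columns present).
synthetic_feature_table <- function(n_subjects = 8, seed = 1) {
  set.seed(seed)
  fn <- feature_names()
  grid <- expand.grid(condition = CTSIB_CONDITIONS,
                      subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  x <- matrix(rnorm(n * length(fn)), n, length(fn),
              dimnames = list(NULL, fn))
  cbind(data.frame(subject_id = grid$subject_id,
                   condition = grid$condition,
                   placement = "lumbar", side = "center", role = "center",
                   av = rnorm(n, 1, 0.3), stringsAsFactors = FALSE),
        as.data.frame(x))
}
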