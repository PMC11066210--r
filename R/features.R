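# The 42-feature extractor: 13 features per body axis (ML, AP, VT) plus the
# three zero-lag cross-axis correlations. Each per-axis feature family has
# many published variants; the definitions here are the most standard reading
# of each name and all tunables are exposed through feature_options().

#' Options for the feature extractor
#'
#' @param shannon_bins Number of equal-width histogram bins for Shannon
#'   entropy (default 16).
#' @param sampen_m Sample-entropy template length (default 2).
#' @param sampen_r_frac Sample-entropy tolerance as a fraction of the
#'   signal's sample standard deviation (default 0.2).
#' @return A list of class `feature_options`.
#' @export
feature_options <- function(shannon_bins = 16, sampen_m = 2,
                            sampen_r_frac = 0.2) {
  stopifnot(shannon_bins >= 2, sampen_m >= 1, sampen_r_frac >= 0)
  structure(list(shannon_bins = shannon_bins, sampen_m = sampen_m,
                 sampen_r_frac = sampen_r_frac),
            class = "feature_options")
}

AXIS_FEATURES <- c("sd", "skewness", "kurtosis", "sparsity",
                   "shannon_entropy", "sample_entropy", "spectral_entropy",
                   "main_freq_power", "secondary_freq_power",
                   "main_freq", "secondary_freq",
                   "difference_sum", "average_jerk")

#' Canonical names of the 42 features, in extraction order
#'
#' Thirteen per-axis features for each of ML, AP and VT (named
#' `<axis>_<feature>`), followed by the three cross-axis correlations
#' `xcorr_MLAP`, `xcorr_MLVT`, `xcorr_APVT`.
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(c("ML", "AP", "VT"), AXIS_FEATURES, paste, sep = "_"))),
    "xcorr_MLAP", "xcorr_MLVT", "xcorr_APVT")
}

#' Moment statistics of a signal
#'
#' Sample standard deviation (n - 1 denominator), skewness (standardized
#' third central moment) and excess kurtosis (Gaussian signals score 0).
#' A constant signal returns all zeros.
#'
#' @param x Numeric vector, length >= 4.
#' @return Named numeric vector `sd`, `skewness`, `kurtosis`.
#' @export
stat_features <- function(x) {
  stopifnot(length(x) >= 4)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(c(sd = 0, skewness = 0, kurtosis = 0))
  c(sd = sd(x),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

#' Hoyer sparsity of a signal
#'
#' \eqn{(\sqrt{N} - \|x\|_1/\|x\|_2) / (\sqrt{N} - 1)}: 0 for
#' constant-magnitude vectors, 1 for one-hot vectors. An all-zero vector
#' scores 0.
#'
#' @param x Numeric vector, length >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
sparsity <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) return(0)
  (sqrt(n) - sum(abs(x)) / l2) / (sqrt(n) - 1)
}

#' Histogram Shannon entropy of a signal
#'
#' Entropy (bits) of the empirical distribution over `n_bins` equal-width
#' bins spanning `[min(x), max(x)]`. Affine-invariant because the bins track
#' the signal's range; a constant signal occupies a single bin and scores 0.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (default 16).
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(x, n_bins = 16) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(0)
  idx <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1)
  p <- tabulate(idx + 1L, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sample entropy of a signal
#'
#' Standard SampEn: with template length `m` and tolerance
#' `r = r_frac * sd(x)`, count template pairs within Chebyshev distance `r`
#' at lengths `m` (`B`) and `m + 1` (`A`), self-matches excluded, and return
#' `-log(A / B)`. Lower values mean a more regular signal. When no pairs
#' match at either length the value is capped at `log(N - m)` so feature
#' vectors stay finite.
#'
#' @param x Numeric vector, length >= `m + 2`.
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  if (n < m + 2) stop("sample entropy needs length >= m + 2", call. = FALSE)
  r <- r_frac * sd(x)
  ab <- sampen_counts(as.numeric(x), as.integer(m), r)
  if (ab[2] == 0 || ab[1] == 0) return(log(n - m))
  -log(ab[1] / ab[2])
}

#' Spectral features of a signal
#'
#' One-sided rectangular-window periodogram with the DC bin excluded.
#' Returns the spectral (frequency-domain) entropy in bits of the
#' power-normalized spectrum, the frequency and power of the dominant bin,
#' and of the strongest bin not adjacent to the dominant one (adjacency is
#' excluded so spectral leakage around one peak is not reported twice).
#' Powers are scaled so a pure sinusoid of amplitude A at an exact bin
#' frequency has main power A^2/2. A constant signal returns all zeros.
#'
#' @param x Numeric vector, length >= 8.
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector `spectral_entropy`, `main_freq_power`,
#'   `secondary_freq_power`, `main_freq`, `secondary_freq`.
#' @export
spectral_features <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 8)
  zero <- c(spectral_entropy = 0, main_freq_power = 0,
            secondary_freq_power = 0, main_freq = 0, secondary_freq = 0)
  xc <- x - mean(x)
  if (all(xc == 0)) return(zero)
  kmax <- floor(n / 2)
  P <- (2 / n^2) * Mod(fft(xc)[2:(kmax + 1)])^2
  tot <- sum(P)
  if (tot <= 0) return(zero)
  p <- P / tot
  pp <- p[p > 0]
  ent <- -sum(pp * log2(pp))
  freqs <- seq_len(kmax) * fs / n
  k1 <- which.max(P)
  eligible <- which(abs(seq_len(kmax) - k1) > 1)
  if (length(eligible) == 0) {
    k2p <- 0; k2f <- 0
  } else {
    k2 <- eligible[which.max(P[eligible])]
    k2p <- P[k2]; k2f <- freqs[k2]
  }
  c(spectral_entropy = ent, main_freq_power = P[k1],
    secondary_freq_power = k2p, main_freq = freqs[k1], secondary_freq = k2f)
}

#' Difference sum (total variation) of a signal
#'
#' \eqn{\sum_i |x_{i+1} - x_i|}; zero iff the signal is constant, and
#' invariant to adding a constant.
#'
#' @param x Numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
difference_sum <- function(x) {
  stopifnot(length(x) >= 2)
  sum(abs(diff(x)))
}

#' Average jerk of an acceleration signal
#'
#' Mean absolute first difference scaled to per-second units:
#' `mean(|diff(x)|) * fs`. Summarizes movement smoothness; zero for
#' constant acceleration.
#'
#' @param x Numeric acceleration vector, length >= 2.
#' @param fs Sampling frequency in Hz.
#' @return Non-negative scalar.
#' @export
average_jerk <- function(x, fs) {
  stopifnot(length(x) >= 2, fs > 0)
  mean(abs(diff(x))) * fs
}

#' Zero-lag cross-axis correlation
#'
#' Pearson correlation of two equal-length signals; 0 (by guard) when
#' either signal is constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Scalar in `[-1, 1]`.
#' @export
cross_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

axis_features_ <- function(x, fs, opts) {
  sf <- spectral_features(x, fs)
  c(stat_features(x),
    sparsity = sparsity(x),
    shannon_entropy = shannon_entropy(x, opts$shannon_bins),
    sample_entropy = sample_entropy(x, opts$sampen_m, opts$sampen_r_frac),
    sf[c("spectral_entropy", "main_freq_power", "secondary_freq_power",
         "main_freq", "secondary_freq")],
    difference_sum = difference_sum(x),
    average_jerk = average_jerk(x, fs))
}

#' Extract the 42-feature vector from one recording
#'
#' Computes, on the full (unwindowed) body-frame segment, 13 features per
#' axis — standard deviation, skewness, excess kurtosis, Hoyer sparsity,
#' histogram Shannon entropy, sample entropy, spectral entropy, power and
#' frequency of the main and secondary spectral peaks, difference sum, and
#' average jerk — plus the three zero-lag cross-axis Pearson correlations.
#' Degenerate inputs (e.g. an all-zero axis) produce guard values of 0, so
#' the output is always 42 finite numbers in a fixed order.
#'
#' @param recording A body-frame [imu_recording()] (see [harmonize_axes()]),
#'   at least 8 samples long.
#' @param opts A [feature_options()].
#' @return Named numeric vector of length 42, names as in [feature_names()].
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_subjects = 2, seed = 1)
#' cop <- simulate_cop(0.02, duration_s = 2, fs = 128)
#' rec <- harmonize_axes(cop_to_imu(cop, "lumbar", "center", cfg))
#' length(extract_features(rec))
#' @export
extract_features <- function(recording, opts = feature_options()) {
  stopifnot(inherits(recording, "imu_recording"),
            inherits(opts, "feature_options"))
  if (recording$frame != "body") {
    stop("extract_features needs a body-frame recording; ",
         "run harmonize_axes() first", call. = FALSE)
  }
  if (nrow(recording$acc) < 8) {
    stop("recording too short for feature extraction (< 8 samples)",
         call. = FALSE)
  }
  ml <- recording$acc[, "ML"]
  ap <- recording$acc[, "AP"]
  vt <- recording$acc[, "VT"]
  fs <- recording$fs
  out <- c(axis_features_(ml, fs, opts),
           axis_features_(ap, fs, opts),
           axis_features_(vt, fs, opts),
           cross_correlation(ml, ap),
           cross_correlation(ml, vt),
           cross_correlation(ap, vt))
  names(out) <- feature_names()
  stopifnot(all(is.finite(out)))
  out
}
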