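#' Construct a center-of-pressure trace
#'
#' A COP trace is the 2-D trajectory of the center of pressure on a force
#' platform, sampled uniformly: `x` is medial-lateral (ML) displacement and
#' `y` anterior-posterior (AP) displacement, both in inches.
#'
#' @param x,y Numeric vectors of equal length (>= 2), ML and AP
#'   displacement in inches.
#' @param fs Sampling frequency in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `cop_trace` with fields `t`, `x`, `y`, `fs`.
#' @examples
#' tr <- cop_trace(x = c(0, 3), y = c(0, 4), fs = 1)
#' path_length(tr)
#' @export
cop_trace <- function(x, y, fs, t0 = 0) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2, is.numeric(fs), fs > 0)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("COP coordinates must be finite", call. = FALSE)
  }
  structure(list(t = t0 + (seq_along(x) - 1) / fs,
                 x = as.numeric(x), y = as.numeric(y), fs = fs),
            class = "cop_trace")
}

#' @export
print.cop_trace <- function(x, ...) {
  cat("<cop_trace> ", length(x$x), " samples @ ", x$fs, " Hz (",
      sprintf("%.2f", x$t[length(x$t)] - x$t[1]), " s)\n", sep = "")
  invisible(x)
}

#' COP path length
#'
#' Total distance traveled by the center of pressure: the discrete Euclidean
#' arc length of the trace, \eqn{\sum_i \sqrt{\Delta x_i^2 + \Delta y_i^2}},
#' in inches. No smoothing is applied.
#'
#' @param cop A [cop_trace()].
#' @return Path length in inches (scalar >= 0).
#' @export
path_length <- function(cop) {
  stopifnot(inherits(cop, "cop_trace"))
  if (length(cop$x) < 2) stop("path length needs >= 2 samples", call. = FALSE)
  sum(sqrt(diff(cop$x)^2 + diff(cop$y)^2))
}

#' COP average velocity
#'
#' Path length divided by elapsed time (last minus first timestamp), in
#' inches/second. Elapsed time comes from the timestamps, not from the
#' sample count, so irregular traces fail upstream validation rather than
#' silently changing the score.
#'
#' @param cop A [cop_trace()].
#' @return Average velocity in inches/second (scalar >= 0).
#' @export
average_velocity <- function(cop) {
  stopifnot(inherits(cop, "cop_trace"))
  elapsed <- cop$t[length(cop$t)] - cop$t[1]
  if (elapsed <= 0) stop("elapsed time must be positive", call. = FALSE)
  path_length(cop) / elapsed
}

#' Ground-truth balance score for one condition
#'
#' Computes the platform-equivalent scores from a COP trace: path length
#' (PL, inches) and average velocity (AV, inches/second). By construction
#' `av * duration_s == pl`.
#'
#' @param cop A [cop_trace()].
#' @param condition One of `EOSS`, `ECSS`, `EOFS`, `ECFS`.
#' @return An object of class `balance_score`: list with `condition`, `pl`,
#'   `av`, `duration_s`.
#' @export
balance_score <- function(cop, condition) {
  .assert_condition(condition)
  pl <- path_length(cop)
  duration <- cop$t[length(cop$t)] - cop$t[1]
  if (duration <= 0) stop("elapsed time must be positive", call. = FALSE)
  structure(list(condition = condition, pl = pl, av = pl / duration,
                 duration_s = duration),
            class = "balance_score")
}

#' @export
print.balance_score <- function(x, ...) {
  cat(sprintf("<balance_score> %s: PL %.3f in, AV %.3f in/s over %.2f s\n",
              x$condition, x$pl, x$av, x$duration_s))
  invisible(x)
}
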