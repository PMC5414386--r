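#' Fit the linear trend of a trajectory
#'
#' Ordinary least squares of the scores on the occasion index 1..T. The
#' residual scale `sigma` is the root mean squared residual with
#' denominator T (not T - 2): the band is a descriptive envelope around
#' the observed spread, not an inferential standard error.
#'
#' @param traj An `emotion_trajectory` or a numeric score vector.
#' @return A `trend_fit`: list with `intercept`, `slope`, `fitted`,
#'   `residuals`, `mean_sq_residual`, `sigma`, `occasions`, `scores`.
#' @export
#' @examples
#' fit_trend(c(2, 1, 1, 2, 3, 2, 2, 1))$sigma
fit_trend <- function(traj) {
  scores <- if (inherits(traj, "emotion_trajectory")) traj$scores else as.numeric(traj)
  n <- length(scores)
  if (n < 3L) stop("at least 3 points are needed to fit a trend", call. = FALSE)
  x <- seq_len(n)
  xc <- x - mean(x)
  slope <- sum(xc * scores) / sum(xc^2)
  intercept <- mean(scores) - slope * mean(x)
  fitted <- intercept + slope * x
  res <- scores - fitted
  msr <- mean(res^2)
  structure(
    list(
      intercept = intercept, slope = slope, fitted = fitted,
      residuals = res, mean_sq_residual = msr, sigma = sqrt(msr),
      occasions = x, scores = scores
    ),
    class = "trend_fit"
  )
}

#' Control band around a fitted trend
#'
#' Upper and lower control limits at `multiplier` residual standard
#' deviations above and below the trend line. The default multiplier of
#' 1.65 corresponds to roughly the central 90% of a normal residual
#' distribution; points strictly outside the band are "exceptional". The
#' band is not clipped to the 1..5 score range.
#'
#' @param fit A `trend_fit`.
#' @param multiplier Positive band half-width in residual SD units.
#' @return A `control_band`: list with `ucl`, `lcl`, `fitted`, `sigma`,
#'   `multiplier`.
#' @export
control_limits <- function(fit, multiplier = 1.65) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    stop("multiplier must be a positive number", call. = FALSE)
  }
  half <- multiplier * fit$sigma
  structure(
    list(
      ucl = fit$fitted + half, lcl = fit$fitted - half,
      fitted = fit$fitted, sigma = fit$sigma, multiplier = multiplier
    ),
    class = "control_band"
  )
}

#' Flag exceptional points of a trajectory
#'
#' An occasion is exceptional when its score falls strictly outside the
#' control band: above the UCL (`polarity = "high"`) or below the LCL
#' (`polarity = "low"`). Strict inequality means a perfectly linear
#' trajectory (zero-width band) flags nothing.
#'
#' @param traj An `emotion_trajectory` or numeric score vector.
#' @param multiplier Band half-width in residual SD units.
#' @return A tibble with one row per exceptional point, ordered by
#'   occasion: `participant`, `emotion`, `valence`, `occasion`,
#'   `polarity`, `score`, `fitted`, `ucl`, `lcl`, `sigma`. Zero rows when
#'   no point leaves the band.
#' @export
#' @examples
#' find_exceptional_points(c(2, 1, 1, 2, 3, 2, 2, 1))
find_exceptional_points <- function(traj, multiplier = 1.65) {
  if (!inherits(traj, "emotion_trajectory")) traj <- emotion_trajectory(traj)
  fit <- fit_trend(traj)
  band <- control_limits(fit, multiplier)
  high <- traj$scores > band$ucl
  low <- traj$scores < band$lcl
  k <- which(high | low)
  tibble::tibble(
    participant = rep(traj$participant, length(k)),
    emotion = rep(traj$emotion, length(k)),
    valence = rep(traj$valence, length(k)),
    occasion = as.integer(k),
    polarity = c("low", "high")[high[k] + 1L],
    score = traj$scores[k],
    fitted = band$fitted[k],
    ucl = band$ucl[k],
    lcl = band$lcl[k],
    sigma = rep(fit$sigma, length(k))
  )
}
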