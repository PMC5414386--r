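#' OLS slope of a segment
#'
#' Slope of the scores at a subset of occasions against the original
#' occasion indices (the abscissa is never re-indexed, so segment slopes
#' are in score units per occasion of the full series).
#'
#' @param scores Numeric scores of the segment.
#' @param occasions The original occasion indices of those scores.
#' @return The OLS slope, or `NA_real_` when fewer than 2 points are
#'   available or the occasions are all identical (undefined slope).
#' @export
segment_slope <- function(scores, occasions = seq_along(scores)) {
  stopifnot(length(scores) == length(occasions))
  if (length(scores) < 2L) return(NA_real_)
  xc <- occasions - mean(occasions)
  sxx <- sum(xc^2)
  if (sxx == 0) return(NA_real_)
  sum(xc * scores) / sxx
}

# index sets of the two segments around candidate point k
segment_indices <- function(n, k, segment_rule = c("include", "exclude")) {
  segment_rule <- match.arg(segment_rule)
  if (segment_rule == "exclude") {
    list(before = seq_len(k - 1L), after = if (k < n) seq.int(k + 1L, n) else integer(0))
  } else {
    list(before = seq_len(k), after = seq.int(k, n))
  }
}

#' Testable occasion range for the slope-change test
#'
#' Both segments need at least two points. With the default rule (the
#' candidate point shared by both segments) occasions `2..T-1` are
#' testable; with the point excluded from both segments, `3..T-2`.
#'
#' @param n Series length T.
#' @param segment_rule `"include"` (default) or `"exclude"`.
#' @return Integer vector of testable occasions (may be empty).
#' @export
testable_occasions <- function(n, segment_rule = c("include", "exclude")) {
  segment_rule <- match.arg(segment_rule)
  if (segment_rule == "exclude") {
    if (n < 5L) integer(0) else seq.int(3L, n - 2L)
  } else {
    if (n < 3L) integer(0) else seq.int(2L, n - 1L)
  }
}

# linear contrast c such that |sum(c * scores)| = |slope_after - slope_before|
slope_contrast <- function(n, k, segment_rule = "include") {
  seg <- segment_indices(n, k, segment_rule)
  w <- function(idx) {
    out <- numeric(n)
    xc <- idx - mean(idx)
    out[idx] <- xc / sum(xc^2)
    out
  }
  w(seg$after) - w(seg$before)
}

#' Absolute slope change at a candidate point
#'
#' The statistic of the turning-point test: the absolute difference
#' between the OLS slopes of the segments after and before occasion `k`.
#' By default the candidate point anchors both segments (it is the last
#' point of the before-segment and the first of the after-segment), so the
#' out-of-band excursion itself contributes to the slope change; with
#' `segment_rule = "exclude"` it belongs to neither segment.
#'
#' @param traj An `emotion_trajectory` or numeric score vector.
#' @param k Candidate occasion index.
#' @param segment_rule Whether the candidate point anchors both segments
#'   (`"include"`, default) or belongs to neither (`"exclude"`).
#' @return `|slope_after - slope_before|`, or `NA_real_` when `k` is not
#'   testable.
#' @export
#' @examples
#' slope_change_statistic(c(1, 2, 3, 5, 3, 2, 1, 0), k = 4)
slope_change_statistic <- function(traj, k, segment_rule = c("include", "exclude")) {
  segment_rule <- match.arg(segment_rule)
  scores <- if (inherits(traj, "emotion_trajectory")) traj$scores else as.numeric(traj)
  n <- length(scores)
  if (!k %in% testable_occasions(n, segment_rule)) return(NA_real_)
  seg <- segment_indices(n, k, segment_rule)
  abs(segment_slope(scores[seg$after], seg$after) -
        segment_slope(scores[seg$before], seg$before))
}

# tolerance for counting permuted statistics tied with the observed one
.tie_tol <- 1e-9

#' Monte Carlo permutation test of a slope change
#'
#' Reshuffles the full score vector uniformly over orderings, recomputes
#' the absolute slope change at the same occasion `k`, and counts the
#' permutations whose statistic is at least the observed one (ties count
#' as extreme). The p-value is that count divided by `n_permutations`, so
#' it can be exactly 0 at finite n; `n_extreme` is reported alongside.
#'
#' @param traj An `emotion_trajectory` or numeric score vector.
#' @param k Candidate occasion index (must be testable).
#' @param n_permutations Number of random reorderings (default 10000).
#' @param seed Optional integer seed; the same seed reproduces the result
#'   bit-exactly.
#' @param segment_rule Segment membership of the candidate point.
#' @return A `permutation_result`: list with `observed`, `n_permutations`,
#'   `n_extreme`, `p`, `seed`.
#' @export
permutation_pvalue <- function(traj, k, n_permutations = 10000, seed = NULL,
                               segment_rule = c("include", "exclude")) {
  segment_rule <- match.arg(segment_rule)
  scores <- if (inherits(traj, "emotion_trajectory")) traj$scores else as.numeric(traj)
  n <- length(scores)
  if (!k %in% testable_occasions(n, segment_rule)) {
    stop("occasion ", k, " is not testable for a series of length ", n, call. = FALSE)
  }
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop("n_permutations must be at least 1", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  if (!is.null(seed)) set.seed(seed)

  cvec <- slope_contrast(n, k, segment_rule)
  observed <- abs(sum(cvec * scores))

  idx <- vapply(seq_len(n_permutations), function(i) sample.int(n), integer(n))
  perm_stats <- abs(.colSums(matrix(scores[idx], nrow = n) * cvec, n, n_permutations))
  n_extreme <- sum(perm_stats >= observed - .tie_tol)

  structure(
    list(
      observed = observed, n_permutations = n_permutations,
      n_extreme = n_extreme, p = n_extreme / n_permutations,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(
    "<permutation_result> observed = ", format(x$observed),
    ", p = ", format(x$p), " (", x$n_extreme, "/", x$n_permutations, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Detect turning points of one trajectory
#'
#' Two-stage procedure: occasions falling strictly outside the
#' `multiplier`-sigma control band are exceptional points; each testable
#' exceptional point (both segments with at least 2 occasions) is promoted
#' to a turning point when the permutation p-value of its slope change is
#' below `alpha`. High exceptional points become pre-decrease turning
#' points (intensity was rising, then falls); low ones become pre-increase
#' turning points. Edge exceptional points are reported with
#' `testable = FALSE` and are never promoted. Each point is tested at
#' `alpha` with no multiplicity correction.
#'
#' @param traj An `emotion_trajectory` or numeric score vector.
#' @param multiplier Band half-width in residual SD units.
#' @param alpha Promotion threshold on the permutation p-value.
#' @param n_permutations Permutations per tested point.
#' @param seed Optional integer seed governing all permutations of this
#'   call.
#' @param segment_rule Segment membership of the candidate point.
#' @return A tibble with one row per exceptional point: the columns of
#'   [find_exceptional_points()] plus `testable`, `slope_before`,
#'   `slope_after`, `statistic`, `n_extreme`, `p`, `turning_point`
#'   (logical) and `type` (`"pre-decrease"`, `"pre-increase"`, or NA).
#' @export
detect_turning_points <- function(traj, multiplier = 1.65, alpha = 0.05,
                                  n_permutations = 10000, seed = NULL,
                                  segment_rule = c("include", "exclude")) {
  segment_rule <- match.arg(segment_rule)
  if (!inherits(traj, "emotion_trajectory")) traj <- emotion_trajectory(traj)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  eps <- find_exceptional_points(traj, multiplier)
  n <- length(traj$scores)
  ok <- testable_occasions(n, segment_rule)

  m <- nrow(eps)
  out <- dplyr::mutate(
    eps,
    testable = .data$occasion %in% ok,
    slope_before = NA_real_, slope_after = NA_real_,
    statistic = NA_real_, n_extreme = NA_integer_, p = NA_real_,
    turning_point = FALSE, type = NA_character_
  )
  if (m == 0L) return(out)

  for (i in seq_len(m)) {
    if (!out$testable[i]) next
    k <- out$occasion[i]
    seg <- segment_indices(n, k, segment_rule)
    out$slope_before[i] <- segment_slope(traj$scores[seg$before], seg$before)
    out$slope_after[i] <- segment_slope(traj$scores[seg$after], seg$after)
    pr <- permutation_pvalue(traj, k, n_permutations = n_permutations,
                             seed = NULL, segment_rule = segment_rule)
    out$statistic[i] <- pr$observed
    out$n_extreme[i] <- pr$n_extreme
    out$p[i] <- pr$p
    if (pr$p < alpha) {
      out$turning_point[i] <- TRUE
      out$type[i] <- if (out$polarity[i] == "high") "pre-decrease" else "pre-increase"
    }
  }
  out
}

#' Detect turning points across a whole cohort
#'
#' Runs [detect_turning_points()] on every (participant, emotion)
#' trajectory of the dataset, in the fixed participant-by-emotion order,
#' under a single seed so the full detection table is reproducible.
#'
#' @param dataset A `ratings_dataset`.
#' @inheritParams detect_turning_points
#' @return A tibble binding the per-trajectory detection tables; zero rows
#'   if no trajectory has an exceptional point.
#' @export
detect_cohort <- function(dataset, multiplier = 1.65, alpha = 0.05,
                          n_permutations = 10000, seed = NULL,
                          segment_rule = c("include", "exclude")) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  segment_rule <- match.arg(segment_rule)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(trajectories(dataset), function(tr) {
    detect_turning_points(
      tr, multiplier = multiplier, alpha = alpha,
      n_permutations = n_permutations, seed = NULL, segment_rule = segment_rule
    )
  })
  dplyr::bind_rows(res)
}
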