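#' Partition (participant, occasion) cells by turning-point occurrence
#'
#' The "with" group contains the cells at which a participant has at least
#' one turning point matching the filter (cells, not whole occasions: the
#' default `grouping = "cell"` keeps a cell participant-specific, so other
#' participants at the same occasion stay in the "without" group;
#' `grouping = "occasion"` instead flags the whole occasion column for all
#' participants). A cell with turning points in several emotions appears
#' once.
#'
#' @param turning_points Cohort detection table from [detect_cohort()]
#'   (or any tibble with `participant`, `occasion`, `valence`, `type`,
#'   `turning_point` columns).
#' @param dataset The `ratings_dataset` the detection ran on.
#' @param type_filter Which turning points define the "with" group.
#' @param grouping `"cell"` (default) or `"occasion"`.
#' @return A `cell_partition`: list with logical matrix `mask`
#'   (participants x occasions, TRUE = with-group), `filter`, `grouping`,
#'   `n_with`, `n_without`.
#' @export
group_cells <- function(turning_points, dataset,
                        type_filter = c("all", "pre-decrease-positive",
                                        "pre-increase-positive",
                                        "pre-decrease-negative",
                                        "pre-increase-negative"),
                        grouping = c("cell", "occasion")) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  type_filter <- match.arg(type_filter)
  grouping <- match.arg(grouping)

  tp <- turning_points
  if (nrow(tp) > 0) tp <- tp[tp$turning_point %in% TRUE, , drop = FALSE]
  if (type_filter != "all" && nrow(tp) > 0) {
    parts <- strsplit(type_filter, "-(?=[^-]+$)", perl = TRUE)[[1]]
    tp <- tp[tp$type == parts[1] & tp$valence == parts[2], , drop = FALSE]
  }

  p <- dataset$participants
  mask <- matrix(
    FALSE, nrow = length(p), ncol = dataset$n_occasions,
    dimnames = list(p, seq_len(dataset$n_occasions))
  )
  if (nrow(tp) > 0) {
    if (grouping == "cell") {
      mask[cbind(match(tp$participant, p), tp$occasion)] <- TRUE
    } else {
      mask[, unique(tp$occasion)] <- TRUE
    }
  }
  structure(
    list(
      mask = mask, filter = type_filter, grouping = grouping,
      n_with = sum(mask), n_without = sum(!mask)
    ),
    class = "cell_partition"
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Complexity difference between cell groups
#'
#' Means and population SDs (denominator n, descriptive) of the
#' per-occasion complexity scores in the with- and without-groups, and
#' their difference. An empty with-group makes the association untestable:
#' the result is returned with `testable = FALSE` and NA statistics.
#'
#' @param dataset A `ratings_dataset`.
#' @param partition A `cell_partition` from [group_cells()].
#' @return An `association_result`: list with `filter`, `grouping`,
#'   `n_with`, `n_without`, `mean_with`, `sd_with`, `mean_without`,
#'   `sd_without`, `difference`, `testable`, and (until
#'   [association_pvalue()] fills them) NA permutation fields.
#' @export
complexity_difference <- function(dataset, partition) {
  stopifnot(inherits(dataset, "ratings_dataset"), inherits(partition, "cell_partition"))
  C <- complexity_matrix(dataset)
  stopifnot(identical(dim(C), dim(partition$mask)))
  testable <- partition$n_with > 0 && partition$n_without > 0
  w <- C[partition$mask]
  wo <- C[!partition$mask]
  structure(
    list(
      filter = partition$filter, grouping = partition$grouping,
      n_with = partition$n_with, n_without = partition$n_without,
      mean_with = if (testable) mean(w) else NA_real_,
      sd_with = if (testable) pop_sd(w) else NA_real_,
      mean_without = if (testable) mean(wo) else NA_real_,
      sd_without = if (testable) pop_sd(wo) else NA_real_,
      difference = if (testable) mean(w) - mean(wo) else NA_real_,
      testable = testable,
      p = NA_real_, n_extreme = NA_integer_, n_permutations = NA_integer_,
      seed = NA_integer_, reshuffle = NA_character_
    ),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(
    "<association_result> filter = ", x$filter,
    ", difference = ", format(x$difference),
    if (!is.na(x$p)) paste0(", one-sided p = ", format(x$p)) else "",
    if (!x$testable) " (untestable: empty group)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' One-sided permutation test of the complexity difference
#'
#' Tests whether complexity is higher at turning-point cells than
#' elsewhere. Each permutation reshuffles every participant's complexity
#' values across that participant's occasions (the default
#' `reshuffle = "within"`, preserving between-person complexity levels;
#' `"global"` reshuffles all cells jointly), recomputes the group
#' difference for the fixed partition, and counts permutations whose
#' difference is at least the observed one (ties count). One-sided
#' p = count / n_permutations.
#'
#' @param dataset A `ratings_dataset`.
#' @param partition A `cell_partition`.
#' @param n_permutations Number of reshufflings (default 10000).
#' @param seed Optional integer seed.
#' @param reshuffle `"within"` (default) or `"global"`.
#' @return The `association_result` of [complexity_difference()] with the
#'   permutation fields filled in; untestable partitions are returned
#'   unchanged with `testable = FALSE`.
#' @export
association_pvalue <- function(dataset, partition, n_permutations = 10000,
                               seed = NULL, reshuffle = c("within", "global")) {
  reshuffle <- match.arg(reshuffle)
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop("n_permutations must be at least 1", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  res <- complexity_difference(dataset, partition)
  if (!res$testable) return(res)
  if (!is.null(seed)) set.seed(seed)

  C <- complexity_matrix(dataset)
  mask <- partition$mask
  n_w <- res$n_with
  n_wo <- res$n_without
  total <- sum(C)
  T_n <- ncol(C)

  if (reshuffle == "within") {
    # sum over with-cells after shuffling each participant's row; rows with
    # no with-cell contribute nothing to the with-sum under any shuffle
    sum_with <- numeric(n_permutations)
    for (i in seq_len(nrow(C))) {
      mi <- mask[i, ]
      if (!any(mi)) next
      idx <- vapply(seq_len(n_permutations), function(j) sample.int(T_n), integer(T_n))
      sum_with <- sum_with +
        .colSums(matrix(C[i, ][idx], nrow = T_n) * mi, T_n, n_permutations)
    }
  } else {
    vals <- as.vector(C)
    mv <- as.vector(mask)
    nn <- length(vals)
    idx <- vapply(seq_len(n_permutations), function(j) sample.int(nn), integer(nn))
    sum_with <- .colSums(matrix(vals[idx], nrow = nn) * mv, nn, n_permutations)
  }
  perm_diff <- sum_with / n_w - (total - sum_with) / n_wo
  res$n_extreme <- sum(perm_diff >= res$difference - .tie_tol)
  res$n_permutations <- n_permutations
  res$p <- res$n_extreme / n_permutations
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  res$reshuffle <- reshuffle
  res
}

#' Association results for every turning-point type
#'
#' Runs the complexity association for the overall turning-point set and
#' for each of the four type-by-valence subsets, returning one row per
#' filter.
#'
#' @inheritParams association_pvalue
#' @param turning_points Cohort detection table from [detect_cohort()].
#' @param grouping Passed to [group_cells()].
#' @return A tibble with one row per filter: group sizes, means, SDs,
#'   difference, one-sided `p`, `n_extreme`, `testable`.
#' @export
association_table <- function(dataset, turning_points, n_permutations = 10000,
                              seed = NULL, grouping = c("cell", "occasion"),
                              reshuffle = c("within", "global")) {
  grouping <- match.arg(grouping)
  reshuffle <- match.arg(reshuffle)
  if (!is.null(seed)) set.seed(seed)
  filters <- c("all", "pre-decrease-positive", "pre-increase-positive",
               "pre-decrease-negative", "pre-increase-negative")
  rows <- lapply(filters, function(f) {
    part <- group_cells(turning_points, dataset, type_filter = f, grouping = grouping)
    r <- association_pvalue(dataset, part, n_permutations = n_permutations,
                            seed = NULL, reshuffle = reshuffle)
    tibble::tibble(
      filter = f, n_with = r$n_with, n_without = r$n_without,
      mean_with = r$mean_with, sd_with = r$sd_with,
      mean_without = r$mean_without, sd_without = r$sd_without,
      difference = r$difference, p = r$p, n_extreme = r$n_extreme,
      n_permutations = r$n_permutations, testable = r$testable
    )
  })
  dplyr::bind_rows(rows)
}
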