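#' Count table of exceptional or turning points by valence
#'
#' Tallies points by category (polarity `"high"`/`"low"` for exceptional
#' points, type `"pre-decrease"`/`"pre-increase"` for turning points)
#' within positive- and negative-emotion trajectories. Percentages are
#' reported within each valence's points and against all points, rounded
#' to the nearest integer for display; the raw counts are kept.
#'
#' @param points A detection tibble with `valence` and the category
#'   column. For `by = "type"` only rows with `turning_point == TRUE` are
#'   counted.
#' @param by `"polarity"` (exceptional points) or `"type"` (turning
#'   points).
#' @return A tibble with columns `category`, `valence`, `n`,
#'   `pct_within_valence`, `pct_of_all_points` (the last two rounded).
#' @export
summarize_counts <- function(points, by = c("polarity", "type")) {
  by <- match.arg(by)
  cats <- if (by == "polarity") c("high", "low") else c("pre-decrease", "pre-increase")
  pts <- points
  if (by == "type" && nrow(pts) > 0) pts <- pts[pts$turning_point %in% TRUE, , drop = FALSE]

  grid <- expand.grid(
    category = cats, valence = c("positive", "negative"),
    stringsAsFactors = FALSE
  )
  n <- unname(mapply(function(cat, val) {
    if (nrow(pts) == 0) 0L else sum(pts[[by]] == cat & pts$valence == val)
  }, grid$category, grid$valence))
  total <- sum(n)
  by_val <- as.vector(tapply(n, grid$valence, sum)[grid$valence])
  tibble::tibble(
    category = grid$category,
    valence = grid$valence,
    n = as.integer(n),
    pct_within_valence = ifelse(by_val > 0, round(100 * n / by_val), NA_real_),
    pct_of_all_points = if (total > 0) round(100 * n / total) else rep(NA_real_, length(n))
  )
}

#' Per-occasion complexity summary
#'
#' Cohort mean and range of the per-occasion complexity scores (the mean
#' of the two items) at every measurement point.
#'
#' @param dataset A `ratings_dataset`.
#' @return A tibble with `occasion`, `mean`, `min`, `max`.
#' @export
complexity_occasion_summary <- function(dataset) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  C <- complexity_matrix(dataset)
  tibble::tibble(
    occasion = seq_len(ncol(C)),
    mean = colMeans(C),
    min = apply(C, 2, min),
    max = apply(C, 2, max)
  )
}

#' Participant-by-occasion turning-point matrix
#'
#' @param turning_points Cohort detection table.
#' @param dataset The `ratings_dataset` the detection ran on.
#' @return An integer matrix (participants x occasions) counting turning
#'   points per cell.
#' @export
turning_point_matrix <- function(turning_points, dataset) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  p <- dataset$participants
  m <- matrix(
    0L, nrow = length(p), ncol = dataset$n_occasions,
    dimnames = list(p, seq_len(dataset$n_occasions))
  )
  tp <- turning_points[turning_points$turning_point %in% TRUE, , drop = FALSE]
  if (nrow(tp) > 0) {
    for (i in seq_len(nrow(tp))) {
      r <- match(tp$participant[i], p)
      m[r, tp$occasion[i]] <- m[r, tp$occasion[i]] + 1L
    }
  }
  m
}

#' Run the full turning-point pipeline
#'
#' Detects exceptional and turning points on every trajectory, builds the
#' standard summary tables (point counts by valence, per-occasion
#' complexity, complexity association overall and by turning-point type,
#' the participant-by-occasion turning-point matrix) and a machine-
#' readable manifest of the run. With `output_dir` set, the tables are
#' written as CSV and the manifest as YAML.
#'
#' @param dataset A `ratings_dataset`.
#' @param multiplier Control-band half-width in residual SD units.
#' @param alpha Promotion threshold for the slope-change test.
#' @param n_permutations Permutations per test.
#' @param seed Integer seed governing the whole run; identical inputs and
#'   seed reproduce the bundle bit-exactly.
#' @param grouping,reshuffle Association options, see [group_cells()] and
#'   [association_pvalue()].
#' @param segment_rule Segment membership of candidate points.
#' @param output_dir Optional directory for CSV/YAML output.
#' @return A list of class `turning_point_report`: `exceptional_points`,
#'   `turning_points` (rows promoted), `detection` (full table),
#'   `table_exceptional`, `table_turning`, `complexity_by_occasion`,
#'   `association`, `tp_matrix`, `manifest`.
#' @export
run_pipeline <- function(dataset, multiplier = 1.65, alpha = 0.05,
                         n_permutations = 10000, seed = NULL,
                         grouping = c("cell", "occasion"),
                         reshuffle = c("within", "global"),
                         segment_rule = c("include", "exclude"),
                         output_dir = NULL) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  grouping <- match.arg(grouping)
  reshuffle <- match.arg(reshuffle)
  segment_rule <- match.arg(segment_rule)
  if (!is.null(seed)) set.seed(seed)

  detection <- detect_cohort(
    dataset, multiplier = multiplier, alpha = alpha,
    n_permutations = n_permutations, seed = NULL, segment_rule = segment_rule
  )
  turning <- detection[detection$turning_point %in% TRUE, , drop = FALSE]

  assoc <- association_table(
    dataset, detection, n_permutations = n_permutations, seed = NULL,
    grouping = grouping, reshuffle = reshuffle
  )

  manifest <- list(
    package = "emoturn",
    version = as.character(utils::packageVersion("emoturn")),
    multiplier = multiplier, alpha = alpha, n_permutations = n_permutations,
    seed = if (is.null(seed)) NA else seed,
    grouping = grouping, reshuffle = reshuffle, segment_rule = segment_rule,
    n_participants = length(dataset$participants),
    n_emotions = length(dataset$emotions),
    n_occasions = dataset$n_occasions,
    n_trajectories = unname(n_trajectories(dataset)[["total"]]),
    n_exceptional_points = nrow(detection),
    n_turning_points = nrow(turning)
  )

  report <- structure(
    list(
      exceptional_points = detection[, c("participant", "emotion", "valence",
                                         "occasion", "polarity", "score",
                                         "fitted", "ucl", "lcl", "sigma")],
      turning_points = turning,
      detection = detection,
      table_exceptional = summarize_counts(detection, by = "polarity"),
      table_turning = summarize_counts(detection, by = "type"),
      complexity_by_occasion = complexity_occasion_summary(dataset),
      association = assoc,
      tp_matrix = turning_point_matrix(detection, dataset),
      manifest = manifest
    ),
    class = "turning_point_report"
  )

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.turning_point_report <- function(x, ...) {
  cat(
    "<turning_point_report> ", x$manifest$n_trajectories, " trajectories: ",
    x$manifest$n_exceptional_points, " exceptional points, ",
    x$manifest$n_turning_points, " turning points\n",
    sep = ""
  )
  invisible(x)
}

#' Write a report bundle to disk
#'
#' @param report A `turning_point_report`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "turning_point_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE, quote = FALSE)
  }
  out(report$exceptional_points, "exceptional_points.csv")
  out(report$detection, "detection.csv")
  out(report$table_exceptional, "table_exceptional.csv")
  out(report$table_turning, "table_turning.csv")
  out(report$complexity_by_occasion, "complexity_by_occasion.csv")
  out(report$association, "association.csv")
  mat <- as.data.frame(report$tp_matrix)
  mat <- cbind(participant = rownames(report$tp_matrix), mat)
  out(mat, "turning_point_matrix.csv")
  yaml::write_yaml(report$manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}
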