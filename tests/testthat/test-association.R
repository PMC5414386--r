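# a detection-like tibble with just the columns group_cells needs
tp_rows <- function(participant, occasion, valence, type) {
  tibble::tibble(
    participant = participant, occasion = as.integer(occasion),
    valence = valence, type = type, turning_point = TRUE
  )
}

test_that("cell partitions follow the filter and use set semantics", {
  ds <- tiny_cohort(n_participants = 3)
  tp <- tp_rows("P1", 4, "negative", "pre-decrease")
  part <- group_cells(tp, ds)
  expect_identical(part$n_with, 1L)
  expect_true(part$mask["P1", 4])
  expect_identical(part$n_with + part$n_without, 24L)

  pdneg <- group_cells(tp, ds, type_filter = "pre-decrease-negative")
  expect_identical(pdneg$n_with, 1L)
  pipos <- group_cells(tp, ds, type_filter = "pre-increase-positive")
  expect_identical(pipos$n_with, 0L)

  # two turning points in different emotions at the same cell count once
  tp2 <- rbind(tp, tp_rows("P1", 4, "positive", "pre-increase"))
  expect_identical(group_cells(tp2, ds)$n_with, 1L)

  # occasion-wide grouping flags the whole column
  occ <- group_cells(tp, ds, grouping = "occasion")
  expect_identical(occ$n_with, 3L)
  expect_true(all(occ$mask[, 4]))

  # partition is complete and disjoint for every filter
  for (f in c("all", "pre-decrease-positive", "pre-increase-positive",
              "pre-decrease-negative", "pre-increase-negative")) {
    p <- group_cells(tp2, ds, type_filter = f)
    expect_identical(p$n_with + p$n_without, length(p$mask))
  }
})

test_that("group means, SDs and differences match a brute-force recomputation", {
  set.seed(51)
  g <- generate_cohort(synthetic_spec(n_participants = 5), seed = 52)
  ds <- g$dataset
  tp <- tp_rows(c("P01", "P03"), c(4, 6), c("negative", "positive"),
                c("pre-decrease", "pre-increase"))
  part <- group_cells(tp, ds)
  res <- complexity_difference(ds, part)

  # brute force over all cells
  vals_with <- c()
  vals_without <- c()
  for (p in ds$participants) {
    cs <- complexity_series(ds, p)
    for (t in cs$occasions) {
      v <- cs$values[t]
      if ((p == "P01" && t == 4) || (p == "P03" && t == 6)) {
        vals_with <- c(vals_with, v)
      } else {
        vals_without <- c(vals_without, v)
      }
    }
  }
  expect_equal(res$mean_with, mean(vals_with), tolerance = 1e-12)
  expect_equal(res$mean_without, mean(vals_without), tolerance = 1e-12)
  expect_equal(res$difference, mean(vals_with) - mean(vals_without), tolerance = 1e-12)
  expect_equal(res$sd_with, sqrt(mean((vals_with - mean(vals_with))^2)), tolerance = 1e-12)
  expect_equal(res$sd_without, sqrt(mean((vals_without - mean(vals_without))^2)),
               tolerance = 1e-12)

  # identical complexity everywhere: difference 0
  flat <- tiny_cohort(n_participants = 3, conceptual = 2L, performative = 4L)
  part2 <- group_cells(tp_rows("P1", 4, "negative", "pre-decrease"), flat)
  expect_identical(complexity_difference(flat, part2)$difference, 0)

  # empty with-group is signalled, not an error
  none <- group_cells(tp[0, ], ds)
  r0 <- complexity_difference(ds, none)
  expect_false(r0$testable)
  expect_identical(r0$difference, NA_real_)
  expect_false(association_pvalue(ds, none, n_permutations = 10)$testable)
})

test_that("within-participant reshuffling gives exact p on a 2 x 4 toy and p = 1 degenerately", {
  # 2 participants x 4 occasions; complexity items chosen so per-cell values
  # differ within participants
  ratings <- expand.grid(participant = c("A", "B"), emotion = "interest",
                         occasion = 1:4, stringsAsFactors = FALSE)
  ratings$score <- 3L
  complexity <- expand.grid(occasion = 1:4, participant = c("A", "B"),
                            stringsAsFactors = FALSE)[, 2:1]
  complexity$conceptual <- c(1L, 2L, 3L, 4L, 2L, 2L, 4L, 5L)
  complexity$performative <- c(2L, 2L, 4L, 4L, 1L, 3L, 4L, 4L)
  ds <- ratings_dataset(ratings, complexity, c(interest = "positive"))

  mask <- matrix(FALSE, 2, 4, dimnames = list(c("A", "B"), 1:4))
  mask["A", 3] <- TRUE
  mask["B", 4] <- TRUE
  part <- structure(
    list(mask = mask, filter = "all", grouping = "cell",
         n_with = 2L, n_without = 6L),
    class = "cell_partition"
  )

  # exact p by enumerating all (4!)^2 = 576 joint within-row reshufflings
  C <- rbind(A = (complexity$conceptual[1:4] + complexity$performative[1:4]) / 2,
             B = (complexity$conceptual[5:8] + complexity$performative[5:8]) / 2)
  obs <- mean(C[mask]) - mean(C[!mask])
  perms <- all_permutations(4)
  count <- 0L
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(perms))) {
      Cp <- rbind(C[1, perms[i, ]], C[2, perms[j, ]])
      d <- mean(Cp[mask]) - mean(Cp[!mask])
      if (d >= obs - 1e-9) count <- count + 1L
    }
  }
  exact <- count / nrow(perms)^2

  res <- association_pvalue(ds, part, n_permutations = 10000, seed = 61)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lte(abs(res$p - exact), max(3 * se, 1e-12))

  # complexity constant within every participant: difference 0, p = 1
  flat <- tiny_cohort(n_participants = 2, conceptual = 3L, performative = 2L)
  m2 <- matrix(FALSE, 2, 8, dimnames = list(c("P1", "P2"), 1:8))
  m2["P1", 4] <- TRUE
  part2 <- structure(
    list(mask = m2, filter = "all", grouping = "cell",
         n_with = 1L, n_without = 15L),
    class = "cell_partition"
  )
  r2 <- association_pvalue(flat, part2, n_permutations = 300, seed = 62)
  expect_identical(r2$difference, 0)
  expect_identical(r2$p, 1)
})

test_that("the test is one-sided: a negative bump drives p toward 1", {
  spec_up <- synthetic_spec(n_participants = 8, complexity_bump = 1.5,
                            p_inject = 0.5)
  g <- generate_cohort(spec_up, seed = 71)
  tp <- g$truth$trajectories[g$truth$trajectories$injected, ]
  tp$turning_point <- TRUE
  part <- group_cells(tp, g$dataset)
  up <- association_pvalue(g$dataset, part, n_permutations = 1000, seed = 72)

  # same partition, complexity recoded so bumped cells are LOW instead
  ds_neg <- g$dataset
  ds_neg$complexity$conceptual <- 6L - ds_neg$complexity$conceptual
  ds_neg$complexity$performative <- 6L - ds_neg$complexity$performative
  down <- association_pvalue(ds_neg, part, n_permutations = 1000, seed = 72)
  expect_lt(up$p, 0.05)
  expect_gt(down$p, 0.5)
})

test_that("association_table covers all five filters and flags empty ones", {
  g <- generate_cohort(synthetic_spec(n_participants = 6, p_inject = 0.3), seed = 81)
  det <- detect_cohort(g$dataset, n_permutations = 300, seed = 82)
  tab <- association_table(g$dataset, det, n_permutations = 300, seed = 83)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$filter[1], "all")
  expect_true(all(tab$n_with + tab$n_without == 48L))
  expect_true(all(is.na(tab$p) == !tab$testable))
})
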