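test_that("segment slopes agree with closed-form values and the OLS oracle", {
  expect_equal(segment_slope(c(1, 2, 3), 1:3), 1)
  expect_equal(segment_slope(c(4, 4, 4), 6:8), 0)
  expect_identical(segment_slope(c(2), 4), NA_real_)
  set.seed(41)
  for (i in 1:25) {
    occ <- sort(sample(1:8, 4))
    y <- runif(4, 1, 5)
    expect_equal(segment_slope(y, occ), oracle_slope(y, occ), tolerance = 1e-10)
  }
})

test_that("the slope-change statistic matches hand-computable segments", {
  # tent with the peak excluded: before = exact line slope +1 on occasions
  # 1-3, after = exact line slope -1 on occasions 5-8
  tent <- c(1, 2, 3, 5, 3, 2, 1, 0)
  expect_equal(slope_change_statistic(tent, 4, segment_rule = "exclude"), 2)
  # with the peak anchoring both segments the slopes steepen symmetrically
  expect_equal(
    slope_change_statistic(tent, 4, segment_rule = "include"),
    abs(oracle_slope(tent[4:8], 4:8) - oracle_slope(tent[1:4], 1:4)),
    tolerance = 1e-10
  )
  # exactly linear series: zero statistic at every interior point
  lin <- seq(1, 4.5, by = 0.5)
  for (k in testable_occasions(8)) {
    expect_equal(slope_change_statistic(lin, k), 0, tolerance = 1e-10)
  }
  # shift invariance
  set.seed(42)
  y <- sample(1:5, 8, replace = TRUE)
  for (k in 3:6) {
    expect_equal(slope_change_statistic(y, k),
                 slope_change_statistic(y + 2, k), tolerance = 1e-10)
  }
  # untestable occasions yield NA
  expect_identical(slope_change_statistic(y, 1), NA_real_)
  expect_identical(slope_change_statistic(y, 8), NA_real_)
  expect_identical(slope_change_statistic(y, 2, segment_rule = "exclude"), NA_real_)
})

test_that("the linear contrast reproduces the two-segment statistic", {
  set.seed(43)
  for (rule in c("include", "exclude")) {
    for (i in 1:20) {
      n <- sample(6:9, 1)
      y <- runif(n, 1, 5)
      for (k in testable_occasions(n, rule)) {
        cvec <- emoturn:::slope_contrast(n, k, rule)
        expect_equal(abs(sum(cvec * y)), slope_change_statistic(y, k, segment_rule = rule),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("permutation p-values are deterministic under a seed and degenerate cases behave", {
  y <- c(2, 4, 1, 5, 3, 2, 4, 1)
  a <- permutation_pvalue(y, 4, n_permutations = 500, seed = 7)
  b <- permutation_pvalue(y, 4, n_permutations = 500, seed = 7)
  expect_identical(a$n_extreme, b$n_extreme)
  expect_identical(a$p, b$p)
  expect_equal(a$p, a$n_extreme / a$n_permutations, tolerance = 1e-15)

  # exactly linear series: observed statistic 0, every permutation ties or
  # exceeds, p = 1
  lin <- seq(1, 4.5, by = 0.5)
  pr <- permutation_pvalue(lin, 4, n_permutations = 200, seed = 1)
  expect_equal(pr$observed, 0, tolerance = 1e-10)
  expect_identical(pr$p, 1)

  expect_error(permutation_pvalue(y, 1, n_permutations = 10), "not testable")
  expect_error(permutation_pvalue(y, 4, n_permutations = 0), "at least 1")
})

test_that("Monte Carlo p-values agree with exhaustive enumeration", {
  set.seed(45)
  cases <- list(
    list(y = c(1, 3, 2, 5, 1, 2), k = 3),
    list(y = c(2, 2, 5, 1, 3, 4), k = 4),
    list(y = c(5, 1, 4, 2, 3, 1, 2), k = 4)
  )
  for (cs in cases) {
    for (rule in c("include", "exclude")) {
      if (!cs$k %in% testable_occasions(length(cs$y), rule)) next
      exact <- oracle_exact_pvalue(cs$y, cs$k, rule)
      mc <- permutation_pvalue(cs$y, cs$k, n_permutations = 10000,
                               seed = 99, segment_rule = rule)
      se <- sqrt(exact * (1 - exact) / 10000)
      expect_lte(abs(mc$p - exact), max(3 * se, 1e-12))
    }
  }
})

test_that("score reflection swaps polarity and type but preserves p-values", {
  ys <- list(
    c(1, 2, 3, 5, 3, 2, 1, 1),
    c(4, 3, 3, 1, 3, 4, 4, 5),
    c(2, 2, 3, 2, 5, 3, 2, 2)
  )
  for (y in ys) {
    d1 <- detect_turning_points(y, n_permutations = 400, seed = 13)
    d2 <- detect_turning_points(6 - y, n_permutations = 400, seed = 13)
    expect_identical(d1$occasion, d2$occasion)
    expect_identical(d1$polarity, rev(c("high", "low"))[match(d2$polarity, c("high", "low"))])
    expect_equal(d1$statistic, d2$statistic, tolerance = 1e-9)
    expect_identical(d1$n_extreme, d2$n_extreme)
    expect_identical(d1$turning_point, d2$turning_point)
    both <- d1$turning_point
    if (any(both)) {
      swap <- c(`pre-decrease` = "pre-increase", `pre-increase` = "pre-decrease")
      expect_identical(d1$type[both], unname(swap[d2$type[both]]))
    }
  }
})

test_that("detection handles flat, reversal, and edge-point trajectories", {
  # constant trajectory: no exceptional points at all
  expect_identical(nrow(detect_turning_points(rep(3, 8), n_permutations = 100)), 0L)

  # strong clean reversal: the spike is promoted as a pre-decrease point
  d <- detect_turning_points(c(1, 2, 3, 5, 3, 2, 1, 1),
                             n_permutations = 5000, seed = 3)
  hit <- d[d$occasion == 4, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$polarity, "high")
  expect_true(hit$turning_point)
  expect_identical(hit$type, "pre-decrease")
  # promoted p agrees with full enumeration at alpha 0.05 on the 6-point core
  expect_lt(hit$p, 0.05)

  # an exceptional point at an edge occasion is reported untestable
  edge <- c(5, 3, 3, 3, 3, 3, 3, 3)
  de <- detect_turning_points(edge, n_permutations = 100, seed = 5)
  expect_identical(de$occasion, 1L)
  expect_false(de$testable)
  expect_false(de$turning_point)
  expect_identical(de$p, NA_real_)
})

test_that("cohort detection is reproducible and covers every trajectory", {
  g <- generate_cohort(synthetic_spec(n_participants = 3), seed = 8)
  d1 <- detect_cohort(g$dataset, n_permutations = 300, seed = 77)
  d2 <- detect_cohort(g$dataset, n_permutations = 300, seed = 77)
  expect_identical(d1, d2)
  expect_true(all(paste(d1$participant, d1$emotion) %in%
                    paste(g$truth$trajectories$participant, g$truth$trajectories$emotion)))
  expect_true(all(d1$valence %in% c("positive", "negative")))
})
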