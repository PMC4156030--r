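test_that("Mann-Kendall trend matches its printed anchor cases", {
  expect_equal(mann_kendall_tau(10:1), -1)
  expect_equal(mann_kendall_tau(1:3), 1)
  expect_equal(mann_kendall_tau(c(2, 2, 2)), 0)
  expect_equal(mann_kendall_tau(7), 0)
  expect_equal(mann_kendall_tau(numeric(0)), 0)
  # skip-adjacent: of the pairs of [1,3,2] only (x1, x3) remains
  expect_equal(mann_kendall_tau(c(1, 3, 2), skip_adjacent = TRUE), 1)
  expect_equal(mann_kendall_tau(c(1, 2), skip_adjacent = TRUE), 0)
})

test_that("Mann-Kendall agrees with exhaustive enumeration on all short sequences", {
  for (n in 2:6) {
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))
    for (i in seq_len(nrow(grid))) {
      x <- grid[i, ]
      expect_equal(mann_kendall_tau(x), oracle_tau(x))
      expect_equal(mann_kendall_tau(x, TRUE), oracle_tau(x, TRUE))
    }
  }
  # independent cross-check on tie-free sequences: Kendall correlation with
  # the index equals the all-pairs trend statistic
  set.seed(1)
  for (i in 1:20) {
    x <- sample(100, 8)
    expect_equal(mann_kendall_tau(x),
                 unname(cor(x, seq_along(x), method = "kendall")))
  }
})

test_that("hourglass score matches its anchor profiles", {
  w <- c(100, 80, 60, 40, 60, 80, 100, 120, 130, 140)
  hs <- hourglass_score(w, exclude_first = FALSE)
  expect_equal(hs$H, 1)
  expect_equal(hs$waist, 4L)
  expect_equal(hs$tau_X, -1)
  expect_equal(hs$tau_Y, 1)
  expect_equal(hs$H_robust, 1)

  # strictly increasing: singleton X (tau 0), increasing Y -> H = 0.5
  inc <- hourglass_score(seq(10, 100, by = 10), exclude_first = FALSE)
  expect_equal(inc$H, 0.5)
  expect_equal(inc$waist, 1L)

  # flat: waist tie-broken to floor(L/2), both trends 0
  flat <- hourglass_score(rep(7, 10), exclude_first = FALSE)
  expect_equal(flat$H, 0)
  expect_equal(flat$waist, 5L)

  # equidistant tie resolves to the earlier stage
  tie <- hourglass_score(c(9, 9, 1, 9, 1, 9, 9, 9), exclude_first = FALSE)
  expect_equal(tie$waist, 3L)
})

test_that("hourglass score respects exclusion of the first stage", {
  # first stage is the global minimum but is not considered
  w <- c(5, 100, 80, 60, 80, 100, 120, 140, 150, 160)
  hs <- hourglass_score(w, exclude_first = TRUE)
  expect_equal(hs$waist, 4L)
  expect_equal(hs$H, 1)
  expect_error(hourglass_score(c(3, 2, 1)), "at least 3")
})

test_that("hourglass score is bounded, scale-invariant, and robust variant uses fewer pairs", {
  set.seed(8)
  for (i in 1:50) {
    w <- sample(1:50, sample(4:12, 1), replace = TRUE)
    hs <- hourglass_score(w, exclude_first = FALSE)
    expect_true(hs$H >= -1 && hs$H <= 1)
    expect_true(hs$H_robust >= -1 && hs$H_robust <= 1)
    hs2 <- hourglass_score(w * 3, exclude_first = FALSE)
    expect_equal(hs2$waist, hs$waist)
    expect_equal(hs2$H, hs$H)
  }
  # skip-adjacent drops exactly the n-1 adjacent pairs of an n-sequence
  x <- c(4, 1, 3, 2, 5)
  expect_equal(choose(5, 2) - (5 - 1), 6)
  expect_equal(mann_kendall_tau(x, TRUE), oracle_tau(x, TRUE))
})

test_that("stage lethality is the flagged fraction of DL/RW events", {
  ev <- tibble::tibble(
    generation = c(1, 1, 2, 3, 3, 4, 5),
    individual = 1,
    kind = c("RW", "RW", "RW", "RW", "DP", "DL", "RW"),
    stage = c(3, 3, 3, 3, 3, 2, 5),
    gene_instance = 1:7,
    caused_df = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  out <- lethality_by_stage(ev, L = 5)
  expect_equal(out$lethality[3], 0.25)   # 1 of 4 RW at stage 3; DP ignored
  expect_equal(out$lethality[2], 1)
  expect_equal(out$lethality[5], 0)
  expect_true(is.na(out$lethality[1]))
  expect_true(all(out$n_lethal <= out$n_events))
  empty <- lethality_by_stage(ev[0, ], L = 3)
  expect_true(all(is.na(empty$lethality)))
  # cutting off at an earlier generation drops later events
  out2 <- lethality_by_stage(ev, L = 5, upto_generation = 3)
  expect_equal(out2$n_events[3], 4L)
  expect_equal(out2$n_events[5], 0L)
})

test_that("gene age and per-stage medians follow the definitions", {
  expect_equal(gene_age(0L, 100L), 100L)
  expect_equal(gene_age(100L, 100L), 0L)
  expect_error(gene_age(101L, 100L), "later than")

  pop <- init_population(fixture_dgen("cascade6"), N = 1)
  pop$generation <- 10L
  pop$individuals[[1]]$t0[[2]] <- c(8L, 2L)  # ages 2 and 8 -> median 5
  ages <- age_by_stage(pop)
  expect_equal(ages$median_age[2], 5)
  expect_equal(ages$median_age[1], 10)
  # at generation 0 everything has age 0
  pop0 <- init_population(fixture_dgen("cascade6"), N = 3)
  expect_true(all(age_by_stage(pop0)$median_age == 0))
})

test_that("prevalence counts individuals carrying a label", {
  pop <- init_population(fixture_dgen("cascade6"), N = 10)
  expect_equal(prevalence(pop, 3L), 1)
  # remove label 3 from one individual
  pop$individuals[[1]] <- apply_deletion(pop$individuals[[1]], 3L)$dgen
  expect_equal(prevalence(pop, 3L), 0.9)
  expect_equal(prevalence(pop, 999L), 0)
  # a duplicated label still counts once per individual
  pop$individuals[[2]] <- apply_duplication(pop$individuals[[2]], 4L)$dgen
  expect_equal(prevalence(pop, 4L), 1)
  by_stage <- prevalence_by_stage(pop)
  expect_equal(nrow(by_stage), 4L)
  expect_true(all(by_stage$mean_prevalence <= 1))
  avp <- age_vs_prevalence(pop)
  expect_true(all(avp$prevalence > 0 & avp$prevalence <= 1))
  expect_true(all(avp$age == pop$generation))
})
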