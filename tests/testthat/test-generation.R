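test_that("zero event probabilities leave the population at a fixed point", {
  set.seed(10)
  prof <- specificity_profile("linear", 4)
  pop <- init_population(build_dgen(4, 5, prof), N = 4)
  params <- evolution_params(prof, P_DL = 0, P_DP = 0, P_RW = 0, z = 4)
  pop2 <- step_generation(pop, params)
  expect_equal(pop2$generation, 1L)
  expect_identical(lapply(pop2$individuals, dgen_widths),
                   lapply(pop$individuals, dgen_widths))
  expect_identical(pop2$individuals[[1]]$adj, pop$individuals[[1]]$adj)
  expect_equal(nrow(pop_events(pop2)), 0L)
})

test_that("population size stays N and failed individuals are replaced by survivors", {
  set.seed(21)
  pop <- init_population(fixture_dgen("cascade6"), N = 6)
  prof <- const_profile(4, 0.5)
  params <- evolution_params(prof, P_DL = 0.4, P_RW = 0, z = Inf,
                             policy = df_policy("strict"))
  pop2 <- step_generation(pop, params)
  expect_length(pop2$individuals, 6L)
  ev <- pop_events(pop2)
  expect_true(nrow(ev) > 0)
  expect_true(all(ev$kind == "DL"))
  # an individual flagged caused_df must now carry a survivor's network:
  # with strict DF and gamma0 = 2, every retained network has w(L) >= 2
  for (d in pop2$individuals) expect_gte(dgen_widths(d)[4], 2L)
  # caused_df marks exactly the events of failed individuals
  wl <- vapply(seq_len(6), function(i) {
    ind_ev <- ev[ev$individual == i, ]
    if (!nrow(ind_ev)) NA else all(ind_ev$caused_df) || !any(ind_ev$caused_df)
  }, logical(1))
  expect_true(all(wl, na.rm = TRUE))
})

test_that("a full-population failure retains the previous generation with a warning", {
  set.seed(2)
  pop <- init_population(fixture_dgen("chain3"), N = 3)
  prof <- const_profile(3, 0.5)
  params <- evolution_params(prof, P_DL = 1, P_RW = 0, z = Inf)
  expect_warning(pop2 <- step_generation(pop, params), "all 3 individuals")
  expect_identical(lapply(pop2$individuals, dgen_widths),
                   lapply(pop$individuals, dgen_widths))
})

test_that("model presets constrain event kinds and runs are seed-deterministic", {
  cfg <- sim_config(model = 1, N = 5, L = 5, gamma0 = 8, P_RW = 5e-3,
                    generations = 300, metric_interval = 100, seed = 5)
  sim_a <- run_simulation(cfg)
  sim_b <- run_simulation(cfg)
  expect_identical(sim_a$trajectory, sim_b$trajectory)
  expect_identical(sim_events(sim_a), sim_events(sim_b))
  ev <- sim_events(sim_a)
  expect_true(nrow(ev) > 0)
  expect_true(all(ev$kind == "RW"))  # models 1-2 forbid DP and DL
  expect_equal(cfg$P_DL, 0)
  expect_equal(cfg$P_DP_init, 0)
  expect_equal(sim_config(model = 3)$P_DL, 0)
})

test_that("stage-1 width never decreases without deletions", {
  cfg <- sim_config(model = 2, N = 6, L = 6, gamma0 = 10, P_RW = 5e-3,
                    generations = 500, metric_interval = 100, seed = 9)
  sim <- run_simulation(cfg)
  expect_true(all(sim$trajectory$w1 == 10L))
  # rewiring at the last stage cannot trigger RF below it: a stage-L RW
  # that is its individual'\''s only event that generation is never lethal
  ev <- sim_events(sim)
  solo <- ev |>
    dplyr::group_by(.data$generation, .data$individual) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  expect_gt(nrow(solo[solo$stage == 6, ]), 0)
  expect_true(all(!solo$caused_df[solo$stage == 6]))
})

test_that("the duplication controller moves P_DP toward the band and clamps", {
  expect_equal(duplication_controller(1e-4, 750, 700, 800), 1e-4)
  expect_equal(duplication_controller(1e-4, 600, 700, 800), 1.2e-4)
  expect_equal(duplication_controller(1.2e-4, 900, 700, 800), 1e-4)
  # repeated low-size checks increase monotonically up to the clamp
  p <- 1e-4
  trace <- numeric(60)
  for (i in 1:60) {
    p <- duplication_controller(p, 0, 700, 800)
    trace[i] <- p
  }
  expect_true(all(diff(trace) >= 0))
  expect_equal(max(trace), 0.01)
})

test_that("instance ids stay unique across individuals within a run", {
  cfg <- sim_config(model = 3, N = 4, L = 4, gamma0 = 6, P_RW = 2e-3,
                    P_DP_init = 2e-3, generations = 400,
                    metric_interval = 200, seed = 13)
  sim <- run_simulation(cfg)
  pop <- sim$population
  # ids are unique within every individual, and an id always denotes a
  # gene at the same stage wherever it occurs (labels may diverge after
  # per-individual rewiring)
  for (d in pop$individuals) {
    expect_equal(anyDuplicated(unlist(d$ids)), 0L)
  }
  all_genes <- dplyr::bind_rows(lapply(pop$individuals, dgen_genes))
  per_id <- dplyr::summarise(dplyr::group_by(all_genes, instance_id),
                             n_stages = dplyr::n_distinct(stage))
  expect_true(all(per_id$n_stages == 1))
})
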