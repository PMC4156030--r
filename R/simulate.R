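#' Simulation configuration
#'
#' Builds a validated configuration for [run_simulation()]. Four model
#' presets of increasing complexity are provided:
#'
#' * Model 1 — constant specificity (`s(l) = 0.5`), rewiring only;
#' * Model 2 — linearly increasing specificity (`s(l) = l/L`), rewiring
#'   only;
#' * Model 3 — Model 2 plus gene duplication, with `P_DP` adjusted
#'   dynamically so the population-mean DGEN size stays inside
#'   `size_band * L * gamma0` (70--80% by default);
#' * Model 4 — Model 3 plus gene deletion at a fixed `P_DL` (1e-6 by
#'   default).
#'
#' The specificity profile may be overridden (e.g. a sigmoid profile to
#' move the waist); presets only fill unset values, except that models 1-2
#' force `P_DL = P_DP = 0` and model 3 forces `P_DL = 0`.
#'
#' @param model Preset 1, 2, 3 or 4.
#' @param N Population size.
#' @param L Number of developmental stages.
#' @param gamma0 Initial genes per stage.
#' @param z Regulatory-failure parameter.
#' @param P_RW Per-gene rewiring probability per generation.
#' @param P_DL Per-gene deletion probability (presets 1-3 force 0).
#' @param P_DP_init Initial per-gene duplication probability (presets 1-2
#'   force 0; starting point of the dynamic controller in presets 3-4).
#' @param specificity List with `kind` and, as needed, `value` or
#'   `gamma_mid`; defaults to the preset's profile.
#' @param size_band Two fractions of `L * gamma0` bounding the target mean
#'   DGEN size for the duplication controller.
#' @param df List with `mode` and optional `gamma_tol`, `ramp_width`; see
#'   [df_policy()].
#' @param generations Number of generations to simulate.
#' @param metric_interval Checkpoint cadence (generations) for recording
#'   widths and hourglass scores.
#' @param controller_interval,controller_factor Cadence and multiplicative
#'   step of the duplication controller.
#' @param seed Integer seed; a run is fully reproducible given its seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(model = 2, N = 20, L = 10, gamma0 = 100, z = 4,
                       P_RW = 1e-4, P_DL = NULL, P_DP_init = NULL,
                       specificity = NULL, size_band = c(0.7, 0.8),
                       df = list(mode = "strict"), generations = 1000,
                       metric_interval = 1000, controller_interval = 100,
                       controller_factor = 1.2, seed = 1) {
  if (!model %in% 1:4) stop("`model` must be 1, 2, 3 or 4", call. = FALSE)
  if (is.null(specificity)) {
    specificity <- if (model == 1) list(kind = "constant", value = 0.5)
                   else list(kind = "linear")
  }
  if (model %in% 1:2) {
    P_DL <- 0; P_DP_init <- 0
  } else {
    if (model == 3) P_DL <- 0
    if (is.null(P_DL)) P_DL <- 1e-6
    if (is.null(P_DP_init)) P_DP_init <- 1e-5
  }
  stopifnot(length(size_band) == 2, size_band[1] <= size_band[2],
            generations >= 1, metric_interval >= 1,
            controller_interval >= 1, controller_factor > 1)
  cfg <- list(model = model, N = as.integer(N), L = as.integer(L),
              gamma0 = as.integer(gamma0), z = z, P_RW = P_RW, P_DL = P_DL,
              P_DP_init = P_DP_init, specificity = specificity,
              size_band = size_band, df = df,
              generations = as.integer(generations),
              metric_interval = as.integer(metric_interval),
              controller_interval = as.integer(controller_interval),
              controller_factor = controller_factor,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

config_profile <- function(cfg) {
  sp <- cfg$specificity
  specificity_profile(sp$kind, L = cfg$L,
                      value = if (is.null(sp$value)) 0.5 else sp$value,
                      gamma_mid = sp$gamma_mid)
}

config_policy <- function(cfg) {
  df <- cfg$df
  df_policy(mode = if (is.null(df$mode)) "strict" else df$mode,
            gamma_tol = if (is.null(df$gamma_tol)) 0L else df$gamma_tol,
            ramp_width = if (is.null(df$ramp_width)) 1L else df$ramp_width)
}

#' Dynamic duplication-probability controller
#'
#' Keeps the population-mean DGEN size inside a target band by adjusting
#' the duplication probability multiplicatively: `P_DP` is multiplied by
#' `factor` when the mean size falls below the band, divided by `factor`
#' when it exceeds it, and left unchanged inside the band; the result is
#' clamped to `[0, clamp_max]`.
#'
#' While the population approaches the band from above (e.g. the initial
#' decay from the full founder size), repeated divisions would drive
#' `P_DP` to numerical zero and make the later recovery take thousands of
#' checks; [run_simulation()] therefore applies a small floor
#' (`clamp_min = 1e-7`) so the controller stays responsive. The exported
#' function defaults to `clamp_min = 0`.
#'
#' @param P_DP Current duplication probability.
#' @param mean_size Population-mean total gene count.
#' @param lo,hi Absolute size-band bounds (genes).
#' @param factor Multiplicative adjustment step (> 1).
#' @param clamp_max Upper clamp for `P_DP`.
#' @param clamp_min Lower clamp for `P_DP`.
#' @return The updated duplication probability.
#' @export
duplication_controller <- function(P_DP, mean_size, lo, hi, factor = 1.2,
                                   clamp_max = 0.01, clamp_min = 0) {
  stopifnot(factor > 1, lo <= hi)
  if (mean_size < lo) P_DP <- P_DP * factor
  else if (mean_size > hi) P_DP <- P_DP / factor
  min(max(P_DP, clamp_min), clamp_max)
}

#' Run an evolutionary DGEN simulation
#'
#' Builds the founder DGEN from the configured specificity profile, clones
#' it into `N` identical individuals, and advances the population for the
#' configured number of generations (see [step_generation()]). At every
#' `metric_interval` generations (and at the final one) the per-individual
#' stage widths, hourglass scores and waist locations are recorded. In
#' presets 3 and 4 the duplication probability is adjusted by
#' [duplication_controller()] every `controller_interval` generations.
#'
#' @param config A [sim_config()], a list of `sim_config()` arguments, or
#'   the path to a YAML configuration file (see [read_run_config()]).
#' @param progress Emit a message every 10,000 generations.
#' @return An object of class `dgen_sim` with components:
#' \describe{
#'   \item{trajectory}{tibble, one row per (checkpoint, individual):
#'     `generation`, `individual`, `w1..wL`, `size`, `H`, `H_robust`,
#'     `waist`.}
#'   \item{controller}{tibble of controller checkpoints (`generation`,
#'     `P_DP`, `mean_size`).}
#'   \item{population}{the final `population` (with full event log).}
#'   \item{config}{the configuration used.}
#' }
#' @export
run_simulation <- function(config, progress = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  profile <- config_profile(cfg)
  policy <- config_policy(cfg)
  founder <- build_dgen(cfg$L, cfg$gamma0, profile)
  pop <- init_population(founder, cfg$N)
  params <- evolution_params(profile, P_DL = cfg$P_DL, P_DP = cfg$P_DP_init,
                             P_RW = cfg$P_RW, z = cfg$z, policy = policy)
  controller_on <- cfg$model %in% c(3, 4)
  band <- cfg$size_band * cfg$L * cfg$gamma0

  checkpoints <- unique(c(seq(cfg$metric_interval, cfg$generations,
                              by = cfg$metric_interval), cfg$generations))
  traj <- vector("list", length(checkpoints))
  ti <- 0L
  ctrl <- list(generation = integer(0), P_DP = numeric(0),
               mean_size = numeric(0))

  for (gen in seq_len(cfg$generations)) {
    pop <- step_generation(pop, params)
    if (controller_on && gen %% cfg$controller_interval == 0L) {
      mean_size <- mean(vapply(pop$individuals,
                               function(d) sum(lengths(d$ids)), numeric(1)))
      params$P_DP <- duplication_controller(params$P_DP, mean_size,
                                            band[1], band[2],
                                            cfg$controller_factor,
                                            clamp_min = 1e-7)
      ctrl$generation <- c(ctrl$generation, gen)
      ctrl$P_DP <- c(ctrl$P_DP, params$P_DP)
      ctrl$mean_size <- c(ctrl$mean_size, mean_size)
    }
    if (gen %in% checkpoints) {
      ti <- ti + 1L
      wmat <- t(vapply(pop$individuals, function(d) lengths(d$ids),
                       integer(cfg$L)))
      colnames(wmat) <- paste0("w", seq_len(cfg$L))
      hs <- pop_hourglass(pop, exclude_first = TRUE)
      traj[[ti]] <- dplyr::bind_cols(
        tibble::tibble(generation = gen, individual = seq_len(cfg$N)),
        tibble::as_tibble(wmat),
        tibble::tibble(size = rowSums(wmat)),
        hs[, c("H", "H_robust", "waist")]
      )
    }
    if (progress && gen %% 10000L == 0L) {
      message(sprintf("generation %d / %d (P_DP = %.3g)", gen,
                      cfg$generations, params$P_DP))
    }
  }

  structure(
    list(trajectory = dplyr::bind_rows(traj[seq_len(ti)]),
         controller = tibble::as_tibble(ctrl),
         population = pop,
         config = cfg),
    class = "dgen_sim"
  )
}

#' @export
print.dgen_sim <- function(x, ...) {
  final <- dplyr::filter(x$trajectory,
                         .data$generation == max(.data$generation))
  cat(sprintf("<dgen_sim> model %d, N = %d, L = %d, gamma0 = %d, %d generations (seed %d)\n",
              x$config$model, x$config$N, x$config$L, x$config$gamma0,
              x$config$generations, x$config$seed))
  cat(sprintf("final generation: median H = %.3f, median size = %.0f, %d events logged\n",
              stats::median(final$H), stats::median(final$size),
              x$population$log$n))
  invisible(x)
}

#' Final-generation summaries of a simulation
#'
#' Convenience accessors: `sim_final()` returns the final-checkpoint rows
#' of the trajectory; `sim_events()` the full event log;
#' `sim_lethality()` the per-stage lethality estimate over the whole run;
#' `sim_age_by_stage()` the per-stage median gene age at the final
#' generation.
#'
#' @param x A `dgen_sim`.
#' @return A tibble.
#' @export
sim_final <- function(x) {
  stopifnot(inherits(x, "dgen_sim"))
  dplyr::filter(x$trajectory, .data$generation == max(.data$generation))
}

#' @rdname sim_final
#' @export
sim_events <- function(x) {
  stopifnot(inherits(x, "dgen_sim"))
  pop_events(x$population)
}

#' @rdname sim_final
#' @export
sim_lethality <- function(x) {
  stopifnot(inherits(x, "dgen_sim"))
  lethality_by_stage(sim_events(x), x$config$L)
}

#' @rdname sim_final
#' @export
sim_age_by_stage <- function(x) {
  stopifnot(inherits(x, "dgen_sim"))
  age_by_stage(x$population)
}
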