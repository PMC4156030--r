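#' Read a simulation configuration from YAML
#'
#' Accepts the keys of [sim_config()] (`model`, `N`, `L`, `gamma0`,
#' `specificity`, `z`, `P_RW`, `P_DL`, `P_DP_init`, `size_band`, `df`,
#' `generations`, `metric_interval`, `controller_interval`,
#' `controller_factor`, `seed`); unknown keys are rejected so typos fail
#' loudly rather than silently falling back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N` key as a boolean; restore the schema key
  names(raw)[names(raw) == "FALSE"] <- "N"
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$size_band)) raw$size_band <- as.numeric(raw$size_band)
  do.call(sim_config, raw)
}

run_id_of <- function(cfg) {
  sprintf("model%d_N%d_L%d_G%d_seed%d", cfg$model, cfg$N, cfg$L,
          cfg$gamma0, cfg$seed)
}

# TSV with a run-id header comment; floats at 6 significant digits
write_report_tsv <- function(df, path, run_id) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# run_id: %s", run_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}

#' Write the standard output files of a simulation run
#'
#' Writes, under `dir`: `trajectory.tsv` (one row per checkpoint and
#' individual with widths, size, H, robust H and waist),
#' `stage_summary.tsv` (per-stage lethality and median gene age at the
#' final generation), `events.tsv` (the event log) and `summary.json`
#' (provenance block: config echo, seed, package version, plus
#' final-generation medians). Every TSV carries a `# run_id:` header
#' comment and floating-point values are printed at 6 significant digits.
#'
#' @param sim A `dgen_sim` from [run_simulation()].
#' @param dir Output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "dgen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rid <- run_id_of(sim$config)
  paths <- c(
    trajectory = file.path(dir, "trajectory.tsv"),
    stage_summary = file.path(dir, "stage_summary.tsv"),
    events = file.path(dir, "events.tsv"),
    summary = file.path(dir, "summary.json")
  )
  write_report_tsv(sim$trajectory, paths["trajectory"], rid)
  stage_summary <- dplyr::left_join(sim_lethality(sim),
                                    sim_age_by_stage(sim), by = "stage")
  write_report_tsv(stage_summary, paths["stage_summary"], rid)
  write_report_tsv(sim_events(sim), paths["events"], rid)
  final <- sim_final(sim)
  summary <- list(
    run_id = rid,
    version = as.character(utils::packageVersion("devhourglass")),
    seed = sim$config$seed,
    config = unclass(sim$config),
    final_generation = max(sim$trajectory$generation),
    median_H = signif(stats::median(final$H), 6),
    median_H_robust = signif(stats::median(final$H_robust), 6),
    median_size = signif(stats::median(final$size), 6),
    n_events = sim$population$log$n
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
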