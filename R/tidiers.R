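#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' Returns the checkpoint trajectory either in the wide form stored on the
#' object (one row per checkpoint and individual, `w1..wL` columns) or in
#' a long form with one row per (checkpoint, individual, stage).
#'
#' @param x A `dgen_sim`.
#' @param long Pivot widths to long form.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dgen_sim <- function(x, long = FALSE, ...) {
  tr <- x$trajectory
  if (!long) return(tr)
  tr |>
    tidyr::pivot_longer(dplyr::starts_with("w"),
                        names_to = "stage", values_to = "width",
                        names_prefix = "w", names_transform = as.integer) |>
    dplyr::select("generation", "individual", "stage", "width", "H",
                  "H_robust", "waist")
}

#' One-row summary of a simulation
#'
#' @param x A `dgen_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the configuration headline and the
#'   final-generation population medians of H, robust H, waist and DGEN
#'   size.
#' @export
glance.dgen_sim <- function(x, ...) {
  final <- sim_final(x)
  tibble::tibble(
    model = x$config$model,
    N = x$config$N,
    L = x$config$L,
    gamma0 = x$config$gamma0,
    generations = x$config$generations,
    seed = x$config$seed,
    median_H = stats::median(final$H),
    median_H_robust = stats::median(final$H_robust),
    median_waist = stats::median(final$waist),
    median_size = stats::median(final$size),
    n_events = x$population$log$n
  )
}
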