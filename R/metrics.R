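#' Normalized Mann-Kendall trend statistic
#'
#' The normalized univariate Mann-Kendall statistic of a sequence is the
#' sum of `sign(x_j - x_i)` over ordered pairs `i < j`, divided by the
#' number of pairs considered: -1 for a strictly decreasing sequence, +1
#' for strictly increasing, near 0 for a random one. Tied pairs contribute
#' 0 to the numerator but still count in the denominator. With
#' `skip_adjacent = TRUE` only pairs at least two positions apart
#' (`j >= i + 2`) are compared, which makes the statistic insensitive to
#' single-step fluctuations; this variant backs the robust hourglass
#' score. Sequences with fewer than one eligible pair return 0.
#'
#' @param x Numeric sequence.
#' @param skip_adjacent Drop comparisons of adjacent elements.
#' @return A value in `[-1, 1]`.
#' @examples
#' mann_kendall_tau(10:1)  # -1
#' mann_kendall_tau(1:3)   # +1
#' @export
mann_kendall_tau <- function(x, skip_adjacent = FALSE) {
  n <- length(x)
  gap <- if (skip_adjacent) 2L else 1L
  if (n < 1L + gap) return(0)
  s <- 0L
  np <- 0L
  for (i in seq_len(n - gap)) {
    j <- (i + gap):n
    s <- s + sum(sign(x[j] - x[i]))
    np <- np + length(j)
  }
  s / np
}

#' Hourglass score of a stage-width profile
#'
#' Given per-stage widths `w(1..L)` (gene counts), locates the waist `b`
#' as the minimum-width stage (ties broken toward `floor(L / 2)`; two
#' equidistant stages resolve to the earlier one), splits the profile into
#' `X = w(1..b)` and `Y = w(b..L)`, and scores
#' `H = (tau_Y - tau_X) / 2` with [mann_kendall_tau()]. `H = 1` for a
#' decreasing-then-increasing (hourglass) profile, about 0.5 for a
#' monotonically increasing one (the pre-waist segment is then a
#' singleton, whose trend is defined as 0), and 0 for a flat profile. The
#' robust variant `H_robust` computes both trends with
#' `skip_adjacent = TRUE`.
#'
#' With `exclude_first = TRUE` (the convention for simulated DGENs, whose
#' first-stage width can never decrease when deletions are off) stage 1 is
#' dropped before locating the waist and scoring; reported stage indices
#' still refer to the original numbering.
#'
#' @param widths Numeric vector of at least 3 per-stage widths.
#' @param exclude_first Drop the first stage before scoring.
#' @return A one-row tibble of class `hourglass_report` with columns `H`,
#'   `H_robust`, `waist`, `tau_X`, `tau_Y`.
#' @examples
#' hourglass_score(c(100, 80, 60, 40, 60, 80, 100, 120, 130, 140),
#'                 exclude_first = FALSE)
#' @export
hourglass_score <- function(widths, exclude_first = TRUE) {
  if (!is.numeric(widths)) stop("`widths` must be numeric", call. = FALSE)
  L <- length(widths)
  stages <- if (exclude_first) 2:L else seq_len(L)
  if (length(stages) < 3L) {
    stop("at least 3 considered stages are required", call. = FALSE)
  }
  w <- widths[stages]
  cand <- stages[w == min(w)]
  target <- floor(L / 2)
  b <- cand[order(abs(cand - target), cand)][1]
  X <- widths[stages[stages <= b]]
  Y <- widths[stages[stages >= b]]
  out <- tibble::tibble(
    H = (mann_kendall_tau(Y) - mann_kendall_tau(X)) / 2,
    H_robust = (mann_kendall_tau(Y, TRUE) - mann_kendall_tau(X, TRUE)) / 2,
    waist = b,
    tau_X = mann_kendall_tau(X),
    tau_Y = mann_kendall_tau(Y)
  )
  class(out) <- c("hourglass_report", class(out))
  out
}

#' Per-individual stage widths of a population
#'
#' @param pop A `population`.
#' @return Tibble with columns `individual`, `stage`, `width`.
#' @export
pop_widths <- function(pop) {
  stopifnot(inherits(pop, "population"))
  tibble::tibble(
    individual = rep(seq_len(pop$N), each = pop$L),
    stage = rep(seq_len(pop$L), pop$N),
    width = unlist(lapply(pop$individuals, function(d) lengths(d$ids)))
  )
}

#' Hourglass scores across a population
#'
#' Scores every individual's width profile with [hourglass_score()].
#'
#' @param pop A `population`.
#' @param exclude_first Passed to [hourglass_score()].
#' @return Tibble with one row per individual: `individual`, `H`,
#'   `H_robust`, `waist`, `tau_X`, `tau_Y`.
#' @export
pop_hourglass <- function(pop, exclude_first = TRUE) {
  stopifnot(inherits(pop, "population"))
  dplyr::bind_rows(lapply(seq_len(pop$N), function(i) {
    rep <- hourglass_score(lengths(pop$individuals[[i]]$ids), exclude_first)
    dplyr::bind_cols(tibble::tibble(individual = i), tibble::as_tibble(rep))
  }))
}

#' Stage lethality from an event log
#'
#' The lethality of stage `l` is estimated as the fraction of DL and RW
#' events that occurred at stage `l` and led to a developmental failure of
#' their individual, over all DL/RW events at that stage up to
#' `upto_generation`. Duplication events are never counted. Stages without
#' any eligible event report `NA`.
#'
#' @param events Event tibble as returned by [pop_events()].
#' @param L Number of stages.
#' @param upto_generation Only events at or before this generation count.
#' @return Tibble with columns `stage`, `n_events`, `n_lethal`,
#'   `lethality`.
#' @export
lethality_by_stage <- function(events, L, upto_generation = Inf) {
  stopifnot(is.data.frame(events))
  ev <- dplyr::filter(events, .data$kind %in% c("DL", "RW"),
                      .data$generation <= upto_generation)
  counts <- ev |>
    dplyr::group_by(stage = .data$stage) |>
    dplyr::summarise(n_events = dplyr::n(),
                     n_lethal = sum(.data$caused_df), .groups = "drop")
  out <- tibble::tibble(stage = seq_len(L)) |>
    dplyr::left_join(counts, by = "stage") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      n_lethal = dplyr::coalesce(.data$n_lethal, 0L),
      lethality = ifelse(.data$n_events > 0, .data$n_lethal / .data$n_events,
                         NA_real_)
    )
  out
}

#' Evolutionary age of genes
#'
#' A gene's age at generation `i` is `A(g) = i - t0(g)`, the number of
#' generations since it was last rewired (`t0 = 0` for genes never
#' rewired). Duplicates inherit their parent's `t0` and therefore its age.
#'
#' @param t0 Generation(s) of most recent rewiring (vectorised).
#' @param generation Current generation, `>= max(t0)`.
#' @return Nonnegative integer ages.
#' @export
gene_age <- function(t0, generation) {
  if (any(t0 > generation)) {
    stop("`t0` later than the current generation", call. = FALSE)
  }
  generation - t0
}

#' Median gene age per stage
#'
#' Pools the genes of all individuals and reports, for each stage, the
#' median age (midpoint convention for even counts, as in
#' [stats::median()]).
#'
#' @param pop A `population`.
#' @param generation Generation at which ages are taken (defaults to the
#'   population's current generation).
#' @return Tibble with columns `stage`, `n_genes`, `median_age`.
#' @export
age_by_stage <- function(pop, generation = pop$generation) {
  stopifnot(inherits(pop, "population"))
  t0_by_stage <- lapply(seq_len(pop$L), function(l) {
    unlist(lapply(pop$individuals, function(d) d$t0[[l]]))
  })
  tibble::tibble(
    stage = seq_len(pop$L),
    n_genes = lengths(t0_by_stage),
    median_age = vapply(t0_by_stage, function(v) {
      if (!length(v)) return(NA_real_)
      stats::median(gene_age(v, generation))
    }, numeric(1))
  )
}

# one row per functional label: stage, t0, number of individuals carrying it
label_table <- function(pop) {
  parts <- lapply(seq_len(pop$N), function(i) {
    d <- pop$individuals[[i]]
    lab <- unlist(d$labels)
    keep <- !duplicated(lab)   # count each label once per individual
    data.frame(label = lab[keep],
               stage = rep(seq_len(pop$L), lengths(d$labels))[keep],
               t0 = unlist(d$t0)[keep])
  })
  all <- do.call(rbind, parts)
  agg <- all |>
    dplyr::group_by(label = .data$label) |>
    dplyr::summarise(stage = .data$stage[1], t0 = .data$t0[1],
                     n_individuals = dplyr::n(), .groups = "drop")
  agg
}

#' Gene prevalence
#'
#' The prevalence of a functional gene label is the fraction of the
#' population's individuals whose DGEN carries at least one gene with that
#' label. Unknown labels have prevalence 0.
#'
#' @param pop A `population`.
#' @param label Integer label(s) to query.
#' @return Numeric vector of prevalences in `[0, 1]`, one per queried
#'   label.
#' @export
prevalence <- function(pop, label) {
  stopifnot(inherits(pop, "population"))
  tab <- label_table(pop)
  n <- tab$n_individuals[match(label, tab$label)]
  n[is.na(n)] <- 0L
  n / pop$N
}

#' Per-stage prevalence summary
#'
#' Aggregates label prevalences over the labels present at each stage.
#'
#' @param pop A `population`.
#' @return Tibble with columns `stage`, `n_labels`, `mean_prevalence`,
#'   `median_prevalence`.
#' @export
prevalence_by_stage <- function(pop) {
  stopifnot(inherits(pop, "population"))
  label_table(pop) |>
    dplyr::mutate(prevalence = .data$n_individuals / pop$N) |>
    dplyr::group_by(stage = .data$stage) |>
    dplyr::summarise(n_labels = dplyr::n(),
                     mean_prevalence = mean(.data$prevalence),
                     median_prevalence = stats::median(.data$prevalence),
                     .groups = "drop")
}

#' Gene age versus prevalence
#'
#' Pairs every functional label with its prevalence and age (all copies of
#' a label share `t0`, so age is well defined per label). The decile
#' summary supports checking that older genes tend to be more prevalent.
#'
#' @param pop A `population`.
#' @param generation Generation at which ages are taken.
#' @return Tibble with columns `label`, `stage`, `prevalence`, `age`.
#' @export
age_vs_prevalence <- function(pop, generation = pop$generation) {
  stopifnot(inherits(pop, "population"))
  label_table(pop) |>
    dplyr::transmute(label = .data$label, stage = .data$stage,
                     prevalence = .data$n_individuals / pop$N,
                     age = gene_age(.data$t0, generation))
}

#' @rdname age_vs_prevalence
#' @param records Output of `age_vs_prevalence()`.
#' @param n_bins Number of prevalence bins. Bins are quantile-based with
#'   tied prevalence values kept together (prevalence takes only `N + 1`
#'   distinct values, with heavy ties at fixation, so equal-count binning
#'   would split ties arbitrarily); fewer than `n_bins` bins are returned
#'   when quantile breaks coincide.
#' @return `age_prevalence_deciles()`: tibble with `decile`,
#'   `mean_prevalence`, `mean_age`, `n_labels`, ordered by increasing
#'   prevalence.
#' @export
age_prevalence_deciles <- function(records, n_bins = 10) {
  stopifnot(is.data.frame(records))
  breaks <- unique(stats::quantile(records$prevalence,
                                   seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) breaks <- c(0, breaks)
  records |>
    dplyr::mutate(decile = cut(.data$prevalence, breaks,
                               include.lowest = TRUE, labels = FALSE)) |>
    dplyr::group_by(decile = .data$decile) |>
    dplyr::summarise(mean_prevalence = mean(.data$prevalence),
                     mean_age = mean(.data$age),
                     n_labels = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$decile)
}
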