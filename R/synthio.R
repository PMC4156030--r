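#' Design a synthetic expression dataset with planted hourglass structure
#'
#' Describes a genes-by-stages expression matrix in which a chosen set of
#' genes makes one large expression step at an assigned stage-pair
#' (planted transitioning genes) while all other stage-to-stage changes
#' are bounded noise. The planted per-pair counts (`widths`) decrease to a
#' minimum at the `waist` pair and increase after it, and the planted step
#' magnitudes exceed `delta_band[2]` while background changes stay below
#' `delta_band[1]`, so every threshold `c` inside `delta_band` separates
#' planted from background transitions. `age_profile` gives each pair's
#' target mean phylostratum rank, minimal at the waist (old genes at the
#' waist).
#'
#' @param L Number of stages (at least 4).
#' @param n_genes Total genes (at least `sum(widths) + 10`).
#' @param waist Planted waist as a stage-pair index `l` in `2..L`.
#' @param widths Planted transitioning counts for pairs `2..L`; minimum
#'   must sit exactly at `waist`.
#' @param delta_band `(c_lo, c_hi)`: thresholds in this open band recover
#'   the planted membership (normalized scale).
#' @param noise_sd Standard deviation of the truncated-normal background
#'   noise; must satisfy `c_lo > 6 * noise_sd`.
#' @param age_profile Target mean rank per pair `2..L`, minimal at the
#'   waist.
#' @param seed Integer seed for the generator.
#' @return A list of class `synth_design`.
#' @export
synth_design <- function(L = 6, n_genes = 400, waist = 4,
                         widths = c(50, 30, 10, 30, 50),
                         delta_band = c(1e-4, 4e-4), noise_sd = 1e-5,
                         age_profile = c(5, 4, 2, 4, 5), seed = 42) {
  stopifnot(L >= 4, length(widths) == L - 1, length(age_profile) == L - 1,
            waist >= 2, waist <= L, n_genes >= sum(widths) + 10,
            length(delta_band) == 2, delta_band[1] > 0,
            delta_band[1] < delta_band[2], noise_sd >= 0)
  if (delta_band[1] <= 6 * noise_sd || delta_band[2] <= 8 * noise_sd) {
    stop("infeasible design: delta_band[1] must exceed 6 * noise_sd",
         call. = FALSE)
  }
  pairs <- 2:L
  if (pairs[which.min(widths)] != waist || sum(widths == min(widths)) != 1) {
    stop("`widths` must attain a unique minimum at `waist`", call. = FALSE)
  }
  if (pairs[which.min(age_profile)] != waist) {
    stop("`age_profile` must be minimal at `waist`", call. = FALSE)
  }
  structure(list(L = as.integer(L), n_genes = as.integer(n_genes),
                 waist = as.integer(waist), widths = as.integer(widths),
                 delta_band = delta_band, noise_sd = noise_sd,
                 age_profile = age_profile, seed = as.integer(seed)),
            class = "synth_design")
}

#' Generate a synthetic expression matrix
#'
#' Builds the matrix on the normalized scale (every stage column sums to
#' 1): each gene has a flat baseline, planted genes add a single
#' persistent step of magnitude in `(c_hi, 2 c_hi)` (signs alternating
#' within each pair) at their assigned pair, column sums are rebalanced
#' by spreading the tiny residual over background genes, and
#' column-centred truncated-normal noise is added. Columns are then scaled
#' by stage-specific totals so the returned matrix is on an absolute scale
#' whose normalization reproduces the design. The construction is checked:
#' every planted normalized `|delta|` exceeds `c_hi` and every background
#' `|delta|` stays below `c_lo`.
#'
#' @param design A [synth_design()].
#' @return A list with `expression` (tibble: `gene_id` + stage columns,
#'   absolute scale), `membership` (tibble `gene_id`, `pair`: the planted
#'   ground truth) and `design`.
#' @export
synth_expression <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  set.seed(design$seed)
  L <- design$L
  n <- design$n_genes
  pairs <- 2:L
  c_lo <- design$delta_band[1]
  c_hi <- design$delta_band[2]

  base <- stats::runif(n, 0.5, 1.5)
  base <- base / sum(base)
  M <- matrix(base, nrow = n, ncol = L)

  # steps clear c_hi even after the bounded noise is added; signs alternate
  # within each pair so the column-sum residual stays at most one step
  planted <- sample.int(n, sum(design$widths))
  pair_of <- rep(pairs, design$widths)
  step <- stats::runif(length(planted), c_hi + 7 * design$noise_sd, 2 * c_hi)
  sgn <- unlist(lapply(design$widths, function(k) {
    rep_len(c(1, -1), k)
  }))
  stopifnot(all(base[planted][sgn < 0] > step[sgn < 0] + 6 * design$noise_sd))
  for (k in seq_along(planted)) {
    p <- pair_of[k]
    M[planted[k], p:L] <- M[planted[k], p:L] + sgn[k] * step[k]
  }

  background <- setdiff(seq_len(n), planted)
  resid <- 1 - colSums(M)
  M[background, ] <- M[background, ] +
    matrix(resid / length(background), nrow = length(background), ncol = L,
           byrow = TRUE)

  if (design$noise_sd > 0) {
    noise <- matrix(stats::rnorm(n * L, 0, design$noise_sd), nrow = n)
    noise <- pmin(pmax(noise, -3 * design$noise_sd), 3 * design$noise_sd)
    noise <- sweep(noise, 2, colMeans(noise))
    M <- M + noise
  }
  stopifnot(all(M > 0), max(abs(colSums(M) - 1)) < 1e-10)

  # verify the separation the design promises
  d <- M[, -1, drop = FALSE] - M[, -L, drop = FALSE]
  planted_delta <- abs(d[cbind(planted, pair_of - 1L)])
  bg_mask <- abs(d) > 0
  bg_mask[cbind(planted, pair_of - 1L)] <- FALSE
  stopifnot(all(planted_delta > c_hi), max(abs(d)[bg_mask], 0) < c_lo)

  gene_id <- sprintf("g%04d", seq_len(n))
  scales <- stats::runif(L, 0.8, 1.2) * 1e4
  abs_m <- sweep(M, 2, scales, "*")
  colnames(abs_m) <- paste0("stage", seq_len(L))
  membership <- tibble::tibble(gene_id = gene_id[planted],
                               pair = as.integer(pair_of))
  membership <- dplyr::arrange(membership, .data$pair, .data$gene_id)
  list(
    expression = dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                                  tibble::as_tibble(abs_m)),
    membership = membership,
    design = design
  )
}

#' Generate a gene-age table matching an age profile
#'
#' Planted transitioning genes receive integer ranks whose mean
#' approximates their pair's `age_profile` value (randomized rounding);
#' all other genes draw ranks uniformly over `rank_range`. With the
#' default profile the expression-weighted mean rank (TAI) per pair is
#' minimized at the design waist.
#'
#' @param gene_ids All gene ids of the expression matrix.
#' @param membership Planted membership tibble (`gene_id`, `pair`).
#' @param age_profile Target mean rank per pair `2..L` (named by pair or
#'   positional in pair order).
#' @param rank_range Integer range of phylostratum ranks.
#' @param seed Integer seed.
#' @return An age tibble (`gene_id`, `rank`) as accepted by
#'   [tai_per_stage_pair()].
#' @export
synth_ages <- function(gene_ids, membership, age_profile,
                       rank_range = c(1, 6), seed = 43) {
  stopifnot(is.data.frame(membership),
            all(c("gene_id", "pair") %in% names(membership)))
  set.seed(seed)
  pairs <- sort(unique(membership$pair))
  stopifnot(length(age_profile) == length(pairs))
  target <- stats::setNames(age_profile, pairs)
  rank <- sample(rank_range[1]:rank_range[2], length(gene_ids),
                 replace = TRUE)
  names(rank) <- gene_ids
  mu <- target[as.character(membership$pair)]
  lo <- floor(mu)
  rank[membership$gene_id] <- as.integer(
    lo + (stats::runif(length(mu)) < (mu - lo))
  )
  tibble::tibble(gene_id = gene_ids, rank = as.integer(rank[gene_ids]))
}

#' Hand-built micro-DGEN fixtures
#'
#' Deterministic small networks for cascade and viability unit tests:
#'
#' * `"chain3"`: 3 stages of 1 gene each, edges 1 -> 2 -> 3;
#' * `"diamond"`: two stage-1 genes both regulating one stage-2 gene
#'   (losing one of them gives `r = 0.5`), which regulates one stage-3
#'   gene;
#' * `"cascade6"`: a 4-stage, 8-gene network where deleting the first
#'   stage-1 gene under forced removal (`z = Inf`) cascades through 6
#'   gene removals.
#'
#' @param name Fixture name.
#' @return A `dgen`.
#' @export
fixture_dgen <- function(name = c("chain3", "diamond", "cascade6")) {
  name <- match.arg(name)
  adj_from <- function(w_from, w_to, edges) {
    m <- matrix(FALSE, w_from, w_to)
    m[edges] <- TRUE
    m
  }
  switch(name,
    chain3 = new_dgen(
      L = 3L, gamma0 = 1L,
      ids = list(1L, 2L, 3L), labels = list(1L, 2L, 3L),
      t0 = list(0L, 0L, 0L),
      adj = list(matrix(TRUE, 1, 1), matrix(TRUE, 1, 1)),
      next_id = 4L, next_label = 4L
    ),
    diamond = new_dgen(
      L = 3L, gamma0 = 1L,
      ids = list(c(1L, 2L), 3L, 4L), labels = list(c(1L, 2L), 3L, 4L),
      t0 = list(c(0L, 0L), 0L, 0L),
      adj = list(matrix(TRUE, 2, 1), matrix(TRUE, 1, 1)),
      next_id = 5L, next_label = 5L
    ),
    cascade6 = new_dgen(
      L = 4L, gamma0 = 2L,
      ids = list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L)),
      labels = list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L)),
      t0 = list(c(0L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L)),
      adj = list(
        adj_from(2, 2, rbind(c(1, 1), c(1, 2), c(2, 2))),  # a1->b1, a1->b2, a2->b2
        adj_from(2, 2, rbind(c(1, 1), c(1, 2), c(2, 2))),  # b1->c1, b1->c2, b2->c2
        adj_from(2, 2, rbind(c(1, 1), c(2, 2)))            # c1->d1, c2->d2
      ),
      next_id = 9L, next_label = 9L
    )
  )
}
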