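#' Evolutionary events on DGENs
#'
#' Three structural perturbations act on a DGEN: gene deletion (DL), gene
#' duplication (DP) and regulatory rewiring (RW). Deleting or rewiring a
#' gene can deprive downstream genes of upstream regulators, which may
#' trigger regulatory failures (RF) that cascade through later stages; a
#' cascade reaching the final stage can push the individual below the
#' developmental-failure (DF) viability threshold.
#'
#' @name dgen_events
NULL

# ---- internal position-based mutators (no validation; hot path) ----------

# remove genes at given positions of stage l, dropping incident edges
remove_at <- function(d, l, positions) {
  if (!length(positions)) return(d)
  keep <- setdiff(seq_along(d$ids[[l]]), positions)
  d$ids[[l]] <- d$ids[[l]][keep]
  d$labels[[l]] <- d$labels[[l]][keep]
  d$t0[[l]] <- d$t0[[l]][keep]
  if (l > 1L) d$adj[[l - 1L]] <- d$adj[[l - 1L]][, keep, drop = FALSE]
  if (l < d$L) d$adj[[l]] <- d$adj[[l]][keep, , drop = FALSE]
  d
}

duplicate_at <- function(d, l, pos) {
  d$ids[[l]] <- c(d$ids[[l]], d$next_id)
  d$next_id <- d$next_id + 1L
  d$labels[[l]] <- c(d$labels[[l]], d$labels[[l]][pos])
  d$t0[[l]] <- c(d$t0[[l]], d$t0[[l]][pos])
  if (l > 1L) {
    m <- d$adj[[l - 1L]]
    d$adj[[l - 1L]] <- cbind(m, m[, pos])
  }
  if (l < d$L) {
    m <- d$adj[[l]]
    d$adj[[l]] <- rbind(m, m[pos, ])
  }
  d
}

# rewire gene at (l, pos); sprime_prev/sprime_this are s'(l-1), s'(l)
rewire_at <- function(d, l, pos, generation, sprime_prev, sprime_this) {
  dropped <- integer(0)
  if (l > 1L) {
    wprev <- length(d$ids[[l - 1L]])
    if (wprev > 0L) {
      draw <- stats::runif(wprev) < sprime_prev
      if (!any(draw)) draw[sample.int(wprev, 1L)] <- TRUE
      d$adj[[l - 1L]][, pos] <- draw
    }
  }
  if (l < d$L) {
    row <- d$adj[[l]][pos, ]
    Dpos <- which(row)
    dn <- length(Dpos)
    if (dn > 0L) {
      n_minus <- stats::rbinom(1L, dn, sprime_this)
      n_plus <- stats::rbinom(1L, dn, sprime_this)
      if (n_minus > 0L) row[Dpos[sample.int(dn, n_minus)]] <- FALSE
      if (n_plus > 0L) {
        open <- which(!row)
        if (length(open)) {
          row[open[sample.int(length(open), min(n_plus, length(open)))]] <- TRUE
        }
      }
      d$adj[[l]][pos, ] <- row
      dropped <- d$ids[[l + 1L]][Dpos[!row[Dpos]]]
    }
  }
  d$t0[[l]][pos] <- as.integer(generation)
  d$labels[[l]][pos] <- d$next_label
  d$next_label <- d$next_label + 1L
  list(d = d, dropped = dropped)
}

# ---- exported, id-based operations ---------------------------------------

#' Delete a gene from a DGEN
#'
#' Removes the gene and all its incident edges. The report lists the
#' downstream genes that lost an upstream regulator, i.e. the candidates
#' for a regulatory failure.
#'
#' @param d A `dgen`.
#' @param instance_id Instance id of a gene present in `d`.
#' @return A list with elements `dgen` (the updated network) and
#'   `lost_downstream` (instance ids at the next stage that lost this
#'   regulator).
#' @export
apply_deletion <- function(d, instance_id) {
  loc <- locate_gene(d, instance_id)
  lost <- if (loc$stage < d$L) {
    d$ids[[loc$stage + 1L]][d$adj[[loc$stage]][loc$pos, ]]
  } else integer(0)
  list(dgen = remove_at(d, loc$stage, loc$pos), lost_downstream = lost)
}

#' Duplicate a gene in a DGEN
#'
#' Creates an identical copy at the same stage with the same upstream and
#' downstream regulators. The copy shares the parent's functional label and
#' inherits its `t0`; the two copies diverge only if one is later rewired
#' or deleted.
#'
#' @param d A `dgen`.
#' @param instance_id Instance id of the gene to duplicate.
#' @param generation Current generation (kept for API symmetry; a
#'   duplicate's age is its parent's age).
#' @return A list with `dgen` and `new_instance_id`.
#' @export
apply_duplication <- function(d, instance_id, generation = NULL) {
  loc <- locate_gene(d, instance_id)
  new_id <- d$next_id
  list(dgen = duplicate_at(d, loc$stage, loc$pos), new_instance_id = new_id)
}

#' Rewire a gene's regulators
#'
#' For a gene `g` at stage `l`, the upstream set is redrawn from scratch:
#' each distinct stage-`(l-1)` gene becomes a regulator independently with
#' probability `s'(l - 1)` (an empty draw is replaced by a single uniformly
#' chosen regulator, since rewiring models regulator replacement rather
#' than gene loss). The downstream set changes incrementally: with
#' `N-` and `N+` independent `Binomial(|D(g)|, s'(l))` draws, `N-` existing
#' outgoing edges are removed uniformly and `N+` edges are added to
#' uniformly chosen unconnected stage-`(l+1)` genes (capped by
#' availability), so the new out-degree lies in `[0, 2|D(g)|]`. The gene's
#' `t0` is set to `generation` and it receives a fresh functional label.
#'
#' @param d A `dgen`.
#' @param instance_id Instance id of the gene to rewire.
#' @param profile The [specificity_profile()] governing edge probabilities.
#' @param generation Current generation (recorded as the gene's new `t0`).
#' @return A list with `dgen` and `lost_downstream` (instance ids that lost
#'   this gene as a regulator).
#' @export
apply_rewiring <- function(d, instance_id, profile, generation) {
  loc <- locate_gene(d, instance_id)
  sp_prev <- if (loc$stage > 1L) edge_prob(profile, loc$stage - 1L) else NA_real_
  sp_this <- if (loc$stage < d$L) edge_prob(profile, loc$stage) else NA_real_
  res <- rewire_at(d, loc$stage, loc$pos, generation, sp_prev, sp_this)
  list(dgen = res$d, lost_downstream = res$dropped)
}

#' Regulatory-failure probability
#'
#' A gene that loses a fraction `r` of its upstream regulators fails to
#' transition with probability `P_RF(r) = 1 - exp(-z * r / (1 - r))` for
#' `0 <= r < 1`, and with certainty when all regulators are lost
#' (`P_RF(1) = 1`). The RF parameter `z >= 0` sets how fragile regulatory
#' interactions are; `z = 0` makes partial losses harmless and `z = Inf`
#' makes any loss fatal.
#'
#' @param r Fraction of lost upstream regulators, in `[0, 1]` (vectorised).
#' @param z RF parameter, `z >= 0` (may be `Inf`).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' regulatory_failure_prob(0.5, 4)  # 1 - exp(-4)
#' @export
regulatory_failure_prob <- function(r, z) {
  if (any(r < 0 | r > 1)) stop("`r` must lie in [0, 1]", call. = FALSE)
  if (length(z) != 1 || z < 0) stop("`z` must be a single value >= 0",
                                    call. = FALSE)
  p <- numeric(length(r))
  mid <- r > 0 & r < 1
  p[mid] <- 1 - exp(-z * r[mid] / (1 - r[mid]))
  p[r == 1] <- 1
  p
}

#' Propagate a regulatory-failure cascade
#'
#' After this generation's deletion and rewiring events have been applied
#' to `d`, compares every surviving gene's upstream regulators with the
#' snapshot taken at the start of the generation. Stages are processed in
#' ascending order exactly once (edges span a single stage boundary, so one
#' top-down pass is exact): a gene that lost a fraction `r` of its baseline
#' regulators is removed with certainty when `r = 1` and with probability
#' [regulatory_failure_prob()] when `0 < r < 1`. Removals at stage `l` feed
#' the stage-`(l+1)` computation. Genes rewired this generation adopt their
#' new upstream set and are exempt; genes created this generation have no
#' baseline and are likewise skipped. Gains of new regulators never offset
#' losses.
#'
#' @param d A `dgen` with this generation's events already applied.
#' @param baseline List with `ids` and `adj` as snapshotted from the
#'   individual at the start of the generation (see [dgen_baseline()]).
#' @param z RF parameter; use `Inf` to force removal whenever `r > 0`.
#' @param rewired_ids Instance ids rewired this generation (exempt).
#' @return A list with `dgen` (after RF removals) and `removed`, a tibble
#'   of `(stage, instance_id)` for every RF-removed gene.
#' @export
propagate_cascade <- function(d, baseline, z, rewired_ids = integer(0)) {
  res <- cascade_core(d, baseline, z, rewired_ids)
  list(dgen = res$d,
       removed = tibble::tibble(stage = res$stage, instance_id = res$id))
}

#' Snapshot the upstream structure of a DGEN
#'
#' Captures the per-stage instance ids and adjacency matrices at the start
#' of a generation, for use as the baseline in [propagate_cascade()].
#'
#' @param d A `dgen`.
#' @return A list with elements `ids` and `adj`.
#' @export
dgen_baseline <- function(d) {
  list(ids = d$ids, adj = d$adj)
}

#' Developmental-failure policies
#'
#' The final stage of a DGEN represents the fully developed embryo, which
#' needs (about) the initial complement of `gamma0` final-stage genes to be
#' viable. Three policies decide failure from the final-stage width `w(L)`:
#'
#' * `strict`: fail iff `w(L) < gamma0`;
#' * `tolerant`: fail iff `w(L) < gamma0 - gamma_tol` (strict is
#'   `gamma_tol = 0`);
#' * `probabilistic`: when `w(L) < gamma0`, fail with probability
#'   `min(1, (gamma0 - w(L)) / ramp_width)` — a linear ramp in the gene
#'   deficit — and never otherwise.
#'
#' @param mode One of `"strict"`, `"tolerant"`, `"probabilistic"`.
#' @param gamma_tol Integer tolerance of the `tolerant` mode (>= 0).
#' @param ramp_width Ramp width of the `probabilistic` mode (>= 1).
#' @return An object of class `df_policy`.
#' @export
df_policy <- function(mode = c("strict", "tolerant", "probabilistic"),
                      gamma_tol = 0L, ramp_width = 1L) {
  mode <- match.arg(mode)
  stopifnot(gamma_tol >= 0, ramp_width >= 1)
  structure(list(mode = mode, gamma_tol = as.integer(gamma_tol),
                 ramp_width = as.integer(ramp_width)),
            class = "df_policy")
}

#' Evaluate developmental failure
#'
#' @param d A `dgen`.
#' @param gamma0 Viability threshold: the initial per-stage gene count.
#' @param policy A [df_policy()].
#' @return `TRUE` if the individual failed development.
#' @export
check_developmental_failure <- function(d, gamma0, policy = df_policy()) {
  stopifnot(inherits(policy, "df_policy"))
  wL <- length(d$ids[[d$L]])
  switch(policy$mode,
    strict = wL < gamma0,
    tolerant = wL < gamma0 - policy$gamma_tol,
    probabilistic = {
      if (wL >= gamma0) FALSE
      else stats::runif(1) < min(1, (gamma0 - wL) / policy$ramp_width)
    }
  )
}
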