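#' Populations of DGENs
#'
#' A population holds `N` individuals (DGENs) evolving under Wright-Fisher
#' style dynamics: each generation every individual inherits its parent's
#' network, per-gene duplication/deletion/rewiring events are drawn,
#' regulatory-failure cascades are propagated, and developmentally failed
#' individuals are replaced by clones of uniformly chosen survivors so the
#' population size stays constant. Instance-id and label counters are owned
#' by the population so ids remain unique across individuals within a run.
#'
#' @name population
NULL

# growing event log backed by an environment (reference semantics keep
# appends cheap inside the generation loop)
make_event_log <- function(capacity = 1024L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$kind <- integer(capacity)       # 1 = DL, 2 = DP, 3 = RW
  e$generation <- integer(capacity)
  e$individual <- integer(capacity)
  e$stage <- integer(capacity)
  e$gene_instance <- integer(capacity)
  e$caused_df <- logical(capacity)
  e
}

log_append <- function(log, kind, generation, individual, stage, ids) {
  k <- length(ids)
  if (k == 0L) return(invisible(log))
  need <- log$n + k
  if (need > length(log$kind)) {
    newcap <- max(2L * length(log$kind), need)
    for (f in c("kind", "generation", "individual", "stage",
                "gene_instance", "caused_df")) {
      v <- log[[f]]
      length(v) <- newcap
      log[[f]] <- v
    }
    log$caused_df[is.na(log$caused_df)] <- FALSE
  }
  idx <- (log$n + 1L):need
  log$kind[idx] <- kind
  log$generation[idx] <- generation
  log$individual[idx] <- individual
  log$stage[idx] <- stage
  log$gene_instance[idx] <- ids
  log$caused_df[idx] <- FALSE
  log$n <- need
  invisible(log)
}

#' Initialise a population from one founder DGEN
#'
#' The initial population consists of `N` identical copies of a single
#' built DGEN (clones share instance ids, so every gene starts at
#' prevalence 1).
#'
#' @param d The founder `dgen`.
#' @param N Population size.
#' @return An object of class `population`.
#' @export
init_population <- function(d, N) {
  stopifnot(inherits(d, "dgen"), N >= 1)
  structure(
    list(
      individuals = rep(list(d), N),
      N = as.integer(N),
      L = d$L,
      gamma0 = d$gamma0,
      generation = 0L,
      next_id = d$next_id,
      next_label = d$next_label,
      log = make_event_log()
    ),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> N = %d, generation %d, %d logged events\n",
              x$N, x$generation, x$log$n))
  invisible(x)
}

#' Event log of a population
#'
#' @param pop A `population`.
#' @return Tibble with one row per event: `generation`, `individual`,
#'   `kind` (`"DL"`, `"DP"`, `"RW"`), `stage`, `gene_instance`,
#'   `caused_df` (whether the event's individual failed development that
#'   generation; flagged for DL/RW events only).
#' @export
pop_events <- function(pop) {
  stopifnot(inherits(pop, "population"))
  log <- pop$log
  idx <- seq_len(log$n)
  tibble::tibble(
    generation = log$generation[idx],
    individual = log$individual[idx],
    kind = c("DL", "DP", "RW")[log$kind[idx]],
    stage = log$stage[idx],
    gene_instance = log$gene_instance[idx],
    caused_df = log$caused_df[idx]
  )
}

#' Evolution parameters
#'
#' Per-gene per-generation event probabilities and cascade/viability
#' settings for the generation loop.
#'
#' @param profile The [specificity_profile()] used for rewiring draws.
#' @param P_DL,P_DP,P_RW Per-gene per-generation probabilities of a
#'   deletion, duplication and rewiring event.
#' @param z Regulatory-failure parameter (>= 0).
#' @param policy A [df_policy()].
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(profile, P_DL = 0, P_DP = 0, P_RW = 1e-4,
                             z = 4, policy = df_policy()) {
  stopifnot(inherits(profile, "specificity_profile"),
            inherits(policy, "df_policy"))
  for (p in c(P_DL, P_DP, P_RW)) stopifnot(p >= 0, p <= 1)
  stopifnot(z >= 0)
  structure(list(profile = profile, P_DL = P_DL, P_DP = P_DP, P_RW = P_RW,
                 z = z, policy = policy),
            class = "evolution_params")
}

# map flat gene indices (over stages concatenated) to (stage, pos)
flat_to_stagepos <- function(widths, k) {
  cw <- c(0L, cumsum(widths))
  stage <- findInterval(k - 0.5, cw)
  list(stage = stage, pos = k - cw[stage])
}

# cascade core shared by the loop and the exported wrapper; returns the
# updated dgen plus parallel vectors of removed stages/ids
cascade_core <- function(d, baseline, z, rewired_ids) {
  removed_stage <- integer(0)
  removed_id <- integer(0)
  for (l in 2:d$L) {
    bl_ids <- baseline$ids[[l]]
    if (!length(bl_ids) || !length(d$ids[[l]])) next
    cur_pos <- match(bl_ids, d$ids[[l]])
    cand <- which(!is.na(cur_pos) & !(bl_ids %in% rewired_ids))
    if (!length(cand)) next
    B <- baseline$adj[[l - 1L]][, cand, drop = FALSE]
    bu <- colSums(B)
    rows_map <- match(baseline$ids[[l - 1L]], d$ids[[l - 1L]])
    surv <- !is.na(rows_map)
    Cur <- matrix(FALSE, nrow = nrow(B), ncol = ncol(B))
    if (any(surv) && length(d$ids[[l - 1L]])) {
      Cur[surv, ] <- d$adj[[l - 1L]][rows_map[surv], cur_pos[cand],
                                     drop = FALSE]
    }
    still <- colSums(B & Cur)
    lost <- bu - still
    at_risk <- which(lost > 0L & bu > 0L)
    if (!length(at_risk)) next
    r <- lost[at_risk] / bu[at_risk]
    p <- regulatory_failure_prob(r, z)
    hit <- at_risk[r >= 1 | stats::runif(length(at_risk)) < p]
    if (length(hit)) {
      pos <- cur_pos[cand[hit]]
      removed_stage <- c(removed_stage, rep(l, length(pos)))
      removed_id <- c(removed_id, d$ids[[l]][pos])
      d <- remove_at(d, l, pos)
    }
  }
  list(d = d, stage = removed_stage, id = removed_id)
}

#' Advance a population by one generation
#'
#' For each individual, in index order: snapshot the baseline upstream
#' structure, draw duplication, deletion and rewiring events (in that
#' order, each phase a set of independent per-gene Bernoulli trials over
#' the genes present at the start of the phase), apply them, propagate the
#' regulatory-failure cascade, and evaluate developmental failure. After
#' all individuals are processed, each failed individual is replaced by a
#' clone of a uniformly chosen surviving individual. If every individual
#' fails, the previous generation's population is retained and a warning is
#' issued. Events are appended to the population log with `caused_df`
#' flagged on the DL/RW events of failed individuals.
#'
#' @param pop A `population`.
#' @param params An [evolution_params()].
#' @return The updated `population` (generation counter advanced by one).
#' @export
step_generation <- function(pop, params) {
  stopifnot(inherits(pop, "population"), inherits(params, "evolution_params"))
  gen <- pop$generation + 1L
  profile <- params$profile
  policy <- params$policy
  z <- params$z
  L <- pop$L
  gamma0 <- pop$gamma0
  sprime <- edge_prob(profile, seq_len(L - 1L))
  prev_individuals <- pop$individuals
  failed <- logical(pop$N)
  log <- pop$log

  for (i in seq_len(pop$N)) {
    d <- pop$individuals[[i]]
    widths <- lengths(d$ids)
    n0 <- sum(widths)
    k_dp <- if (params$P_DP > 0 && n0 > 0) stats::rbinom(1L, n0, params$P_DP) else 0L
    # deletions/rewirings are drawn per phase below because the gene count
    # changes after duplications
    log_start <- log$n
    any_event <- FALSE

    if (k_dp > 0L) {
      any_event <- TRUE
      d$next_id <- pop$next_id; d$next_label <- pop$next_label
      baseline <- list(ids = d$ids, adj = d$adj)
      sel <- flat_to_stagepos(widths, sample.int(n0, k_dp))
      for (j in seq_len(k_dp)) {
        log_append(log, 2L, gen, i, sel$stage[j],
                   d$ids[[sel$stage[j]]][sel$pos[j]])
        d <- duplicate_at(d, sel$stage[j], sel$pos[j])
      }
      widths <- lengths(d$ids)
    }

    n1 <- sum(widths)
    k_dl <- if (params$P_DL > 0 && n1 > 0) stats::rbinom(1L, n1, params$P_DL) else 0L
    if (k_dl > 0L) {
      if (!any_event) {
        d$next_id <- pop$next_id; d$next_label <- pop$next_label
        baseline <- list(ids = d$ids, adj = d$adj)
        any_event <- TRUE
      }
      sel <- flat_to_stagepos(widths, sample.int(n1, k_dl))
      for (l in unique(sel$stage)) {
        pos <- sel$pos[sel$stage == l]
        log_append(log, 1L, gen, i, l, d$ids[[l]][pos])
        d <- remove_at(d, l, pos)
      }
      widths <- lengths(d$ids)
    }

    n2 <- sum(widths)
    rewired_ids <- integer(0)
    k_rw <- if (params$P_RW > 0 && n2 > 0) stats::rbinom(1L, n2, params$P_RW) else 0L
    if (k_rw > 0L) {
      if (!any_event) {
        d$next_id <- pop$next_id; d$next_label <- pop$next_label
        baseline <- list(ids = d$ids, adj = d$adj)
        any_event <- TRUE
      }
      sel <- flat_to_stagepos(widths, sample.int(n2, k_rw))
      for (j in seq_len(k_rw)) {
        l <- sel$stage[j]
        id <- d$ids[[l]][sel$pos[j]]
        rewired_ids <- c(rewired_ids, id)
        log_append(log, 3L, gen, i, l, id)
        res <- rewire_at(d, l, sel$pos[j], gen,
                         if (l > 1L) sprime[l - 1L] else NA_real_,
                         if (l < L) sprime[l] else NA_real_)
        d <- res$d
      }
    }

    if (any_event) {
      cas <- cascade_core(d, baseline, z, rewired_ids)
      d <- cas$d
      pop$next_id <- d$next_id
      pop$next_label <- d$next_label
      pop$individuals[[i]] <- d
      failed[i] <- check_developmental_failure(d, gamma0, policy)
      if (failed[i] && log$n > log_start) {
        idx <- (log_start + 1L):log$n
        flag <- log$kind[idx] != 2L  # DL and RW events only
        log$caused_df[idx[flag]] <- TRUE
      }
    } else if (policy$mode == "probabilistic") {
      failed[i] <- check_developmental_failure(d, gamma0, policy)
    } else {
      wL <- length(d$ids[[L]])
      thr <- if (policy$mode == "strict") gamma0 else gamma0 - policy$gamma_tol
      failed[i] <- wL < thr
    }
  }

  if (all(failed)) {
    warning(sprintf("all %d individuals failed development at generation %d; retaining previous population",
                    pop$N, gen), call. = FALSE)
    pop$individuals <- prev_individuals
  } else if (any(failed)) {
    survivors <- which(!failed)
    for (i in which(failed)) {
      pick <- survivors[sample.int(length(survivors), 1L)]
      pop$individuals[[i]] <- pop$individuals[[pick]]
    }
  }
  pop$generation <- gen
  pop
}
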