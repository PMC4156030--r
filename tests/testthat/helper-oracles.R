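# Independent oracles used across test files. These deliberately work on
# edge-list / pairwise representations rather than the package's internal
# adjacency matrices, so they constitute a second route to the same answer.

# Mann-Kendall by explicit pair enumeration over utils::combn
oracle_tau <- function(x, skip_adjacent = FALSE) {
  n <- length(x)
  gap <- if (skip_adjacent) 2L else 1L
  if (n < 1L + gap) return(0)
  pairs <- utils::combn(n, 2)
  keep <- (pairs[2, ] - pairs[1, ]) >= gap
  pairs <- pairs[, keep, drop = FALSE]
  if (!ncol(pairs)) return(0)
  sum(sign(x[pairs[2, ]] - x[pairs[1, ]])) / ncol(pairs)
}

# Transitive deprivation under forced removal: starting from the genes
# deleted this generation, a gene at stage >= 2 is removed iff it lost any
# of its baseline upstream regulators (the regulator was removed, or the
# baseline edge no longer exists). Operates on gene/edge tables only.
oracle_forced_cascade <- function(baseline_genes, baseline_edges,
                                  current_edges, deleted_ids) {
  removed <- deleted_ids
  stages <- sort(unique(baseline_genes$stage))
  cur_key <- paste(current_edges$from_instance_id,
                   current_edges$to_instance_id)
  for (l in stages[-1]) {
    for (g in baseline_genes$instance_id[baseline_genes$stage == l]) {
      if (g %in% removed) next
      regs <- baseline_edges$from_instance_id[
        baseline_edges$to_instance_id == g]
      if (!length(regs)) next
      lost <- regs %in% removed | !(paste(regs, g) %in% cur_key)
      if (any(lost)) removed <- c(removed, g)
    }
  }
  setdiff(removed, deleted_ids)
}

# deterministic micro-profile builders used in several files
const_profile <- function(L, s) specificity_profile("constant", L, value = s)
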