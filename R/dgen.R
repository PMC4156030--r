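#' Developmental gene execution networks (DGENs)
#'
#' A DGEN is a layered directed acyclic network: genes are grouped into
#' ordered developmental stages `1..L` and every edge points from a gene at
#' stage `l` to a gene at stage `l + 1`, representing the causal triggering
#' of state transitions during development. Internally a `dgen` holds, per
#' stage, the gene instance ids, functional labels and last-rewiring
#' generations (`t0`), plus one logical adjacency matrix per consecutive
#' stage boundary; `adj[[l]][i, j]` is `TRUE` when the i-th gene of stage
#' `l` regulates the j-th gene of stage `l + 1`.
#'
#' Instance ids are unique within a simulation run and survive cloning, so
#' gene age and prevalence remain comparable across individuals. Labels
#' denote functional identity: duplicates share their parent's label until a
#' rewiring assigns a fresh one.
#'
#' @name dgen
NULL

new_dgen <- function(L, gamma0, ids, labels, t0, adj, next_id, next_label) {
  structure(
    list(L = L, gamma0 = gamma0, ids = ids, labels = labels, t0 = t0,
         adj = adj, next_id = next_id, next_label = next_label),
    class = "dgen"
  )
}

#' Build a random DGEN from a specificity profile
#'
#' Places `gamma0` genes at each of `L` stages and connects each ordered
#' pair (gene at stage `l`, gene at stage `l + 1`) independently with the
#' edge probability `s'(l) = 1 - s(l)`. After the independent draws, any
#' gene at a stage above 1 left without an upstream regulator is repaired by
#' assigning it one uniformly chosen regulator from the previous stage, so
#' that every state transition has a cause. All `t0` start at 0.
#'
#' @param L Number of stages (at least 3).
#' @param gamma0 Initial number of genes per stage (at least 1).
#' @param profile A [specificity_profile()] with the same `L`.
#' @return A `dgen` object.
#' @examples
#' prof <- specificity_profile("linear", L = 10)
#' set.seed(1)
#' d <- build_dgen(10, 20, prof)
#' dgen_widths(d)
#' @export
build_dgen <- function(L, gamma0, profile) {
  stopifnot(is.numeric(L), length(L) == 1, L >= 3, L == as.integer(L))
  stopifnot(is.numeric(gamma0), length(gamma0) == 1, gamma0 >= 1,
            gamma0 == as.integer(gamma0))
  stopifnot(inherits(profile, "specificity_profile"))
  if (profile$L != L) {
    stop("profile stage count does not match `L`", call. = FALSE)
  }
  L <- as.integer(L)
  gamma0 <- as.integer(gamma0)

  n <- L * gamma0
  ids <- split(seq_len(n), rep(seq_len(L), each = gamma0))
  names(ids) <- NULL
  labels <- ids
  t0 <- lapply(seq_len(L), function(l) integer(gamma0))

  adj <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    p <- edge_prob(profile, l)
    m <- matrix(stats::runif(gamma0 * gamma0) < p, nrow = gamma0)
    # repair: every stage-(l+1) gene needs at least one upstream regulator
    empty <- which(colSums(m) == 0L)
    if (length(empty)) {
      m[cbind(sample.int(gamma0, length(empty), replace = TRUE), empty)] <- TRUE
    }
    adj[[l]] <- m
  }

  new_dgen(L, gamma0, ids, labels, t0, adj,
           next_id = n + 1L, next_label = n + 1L)
}

#' Deep-copy a DGEN
#'
#' R's copy-on-modify semantics make this a structural copy; gene instance
#' ids, labels, `t0` values and all edges are preserved, so mutating the
#' clone never affects the original.
#'
#' @param d A `dgen`.
#' @return A `dgen` identical to `d`.
#' @export
clone_dgen <- function(d) {
  stopifnot(inherits(d, "dgen"))
  # lists of atomic vectors/matrices: plain reassignment is a deep copy
  unserialize(serialize(d, NULL))
}

#' Stage widths of a DGEN
#'
#' @param d A `dgen`.
#' @return Integer vector `w(1..L)` of per-stage gene counts.
#' @export
dgen_widths <- function(d) {
  stopifnot(inherits(d, "dgen"))
  vapply(d$ids, length, integer(1))
}

#' Total number of genes in a DGEN
#' @param d A `dgen`.
#' @return Integer gene count summed over stages.
#' @export
dgen_size <- function(d) {
  sum(dgen_widths(d))
}

#' Gene and edge tables of a DGEN
#'
#' `dgen_genes()` returns one row per gene (instance id, functional label,
#' stage, last-rewiring generation `t0`); `dgen_edges()` returns the edge
#' list as instance-id pairs. Both are tibbles suitable for joining with
#' event logs and metric tables.
#'
#' @param d A `dgen`.
#' @return A tibble.
#' @export
dgen_genes <- function(d) {
  stopifnot(inherits(d, "dgen"))
  tibble::tibble(
    instance_id = unlist(d$ids),
    label = unlist(d$labels),
    stage = rep(seq_len(d$L), dgen_widths(d)),
    t0 = unlist(d$t0)
  )
}

#' @rdname dgen_genes
#' @export
dgen_edges <- function(d) {
  stopifnot(inherits(d, "dgen"))
  parts <- lapply(seq_len(d$L - 1), function(l) {
    idx <- which(d$adj[[l]], arr.ind = TRUE)
    tibble::tibble(
      from_instance_id = d$ids[[l]][idx[, 1]],
      to_instance_id = d$ids[[l + 1]][idx[, 2]]
    )
  })
  dplyr::arrange(dplyr::bind_rows(parts), .data$from_instance_id,
                 .data$to_instance_id)
}

#' Upstream and downstream regulator sets
#'
#' `dgen_upstream()` returns the instance ids regulating a gene (its
#' incoming edges from the previous stage); `dgen_downstream()` the ids it
#' regulates at the next stage.
#'
#' @param d A `dgen`.
#' @param instance_id A gene instance id present in `d`.
#' @return Integer vector of instance ids.
#' @export
dgen_upstream <- function(d, instance_id) {
  loc <- locate_gene(d, instance_id)
  if (loc$stage == 1L) return(integer(0))
  d$ids[[loc$stage - 1L]][d$adj[[loc$stage - 1L]][, loc$pos]]
}

#' @rdname dgen_upstream
#' @export
dgen_downstream <- function(d, instance_id) {
  loc <- locate_gene(d, instance_id)
  if (loc$stage == d$L) return(integer(0))
  d$ids[[loc$stage + 1L]][d$adj[[loc$stage]][loc$pos, ]]
}

# find (stage, position) of an instance id; error if absent
locate_gene <- function(d, instance_id) {
  for (l in seq_len(d$L)) {
    pos <- match(instance_id, d$ids[[l]])
    if (!is.na(pos)) return(list(stage = l, pos = pos))
  }
  stop(sprintf("gene instance %d not present in DGEN", instance_id),
       call. = FALSE)
}

#' Validate the structural invariants of a DGEN
#'
#' Checks layer consistency (adjacency dimensions match stage widths),
#' uniqueness of instance ids, and that every gene above stage 1 has at
#' least one upstream regulator.
#'
#' @param d A `dgen`.
#' @return `d`, invisibly; errors on violation.
#' @export
validate_dgen <- function(d) {
  stopifnot(inherits(d, "dgen"))
  w <- dgen_widths(d)
  stopifnot(length(d$adj) == d$L - 1)
  for (l in seq_len(d$L - 1)) {
    m <- d$adj[[l]]
    if (!is.matrix(m) || nrow(m) != w[l] || ncol(m) != w[l + 1]) {
      stop(sprintf("adjacency %d has wrong dimensions", l), call. = FALSE)
    }
    if (w[l] > 0 && any(colSums(m) == 0)) {
      stop(sprintf("stage %d has genes with no upstream regulator", l + 1),
           call. = FALSE)
    }
  }
  all_ids <- unlist(d$ids)
  if (anyDuplicated(all_ids)) stop("duplicate instance ids", call. = FALSE)
  invisible(d)
}

#' @export
print.dgen <- function(x, ...) {
  w <- dgen_widths(x)
  cat(sprintf("<dgen> %d stages, %d genes, %d edges\n", x$L, sum(w),
              sum(vapply(x$adj, sum, numeric(1)))))
  cat("widths:", paste(w, collapse = " "), "\n")
  invisible(x)
}

#' Write / read a DGEN as a TSV pair
#'
#' Serialises a DGEN to two tab-separated files: a gene table
#' (`instance_id`, `label`, `stage`, `t0`) and an edge list
#' (`from_instance_id`, `to_instance_id`). `read_dgen()` reconstructs an
#' identical network (up to within-stage gene order, which is preserved by
#' instance-id order).
#'
#' @param d A `dgen`.
#' @param genes_path,edges_path File paths for the two tables.
#' @param gamma0 Initial per-stage gene count recorded in the restored
#'   object (defaults to the maximum stage width).
#' @return `write_dgen()` returns the paths invisibly; `read_dgen()` a
#'   `dgen`.
#' @export
write_dgen <- function(d, genes_path, edges_path) {
  stopifnot(inherits(d, "dgen"))
  utils::write.table(as.data.frame(dgen_genes(d)), genes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dgen_edges(d)), edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(genes = genes_path, edges = edges_path))
}

#' @rdname write_dgen
#' @export
read_dgen <- function(genes_path, edges_path, gamma0 = NULL) {
  genes <- utils::read.table(genes_path, header = TRUE, sep = "\t")
  edges <- utils::read.table(edges_path, header = TRUE, sep = "\t")
  need <- c("instance_id", "label", "stage", "t0")
  if (!all(need %in% names(genes))) {
    stop("gene table must have columns instance_id, label, stage, t0",
         call. = FALSE)
  }
  if (anyDuplicated(genes$instance_id)) {
    stop("duplicate instance ids in gene table", call. = FALSE)
  }
  L <- max(genes$stage)
  genes <- genes[order(genes$stage, genes$instance_id), ]
  ids <- lapply(seq_len(L), function(l) as.integer(genes$instance_id[genes$stage == l]))
  labels <- lapply(seq_len(L), function(l) as.integer(genes$label[genes$stage == l]))
  t0 <- lapply(seq_len(L), function(l) as.integer(genes$t0[genes$stage == l]))
  adj <- vector("list", L - 1)
  stage_of <- stats::setNames(genes$stage, genes$instance_id)
  for (l in seq_len(L - 1)) {
    m <- matrix(FALSE, nrow = length(ids[[l]]), ncol = length(ids[[l + 1]]))
    sel <- stage_of[as.character(edges$from_instance_id)] == l
    if (any(sel)) {
      i <- match(edges$from_instance_id[sel], ids[[l]])
      j <- match(edges$to_instance_id[sel], ids[[l + 1]])
      if (anyNA(i) || anyNA(j)) {
        stop(sprintf("edge table references genes absent from stages %d/%d",
                     l, l + 1), call. = FALSE)
      }
      m[cbind(i, j)] <- TRUE
    }
    adj[[l]] <- m
  }
  if (is.null(gamma0)) gamma0 <- max(vapply(ids, length, integer(1)))
  new_dgen(L, as.integer(gamma0), ids, labels, t0, adj,
           next_id = max(genes$instance_id) + 1L,
           next_label = max(genes$label) + 1L)
}
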