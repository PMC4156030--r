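#' Read a genes-by-stages expression matrix
#'
#' Expects a tab-separated file whose header row names the ordered
#' developmental stages and whose first column holds unique gene ids; all
#' expression values must be nonnegative numbers (any units). Duplicated
#' gene ids, negative values and ragged rows are rejected with the
#' offending row or id named.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per stage, in file order.
#' @examples
#' # a small synthetic expression matrix shipped with the package
#' f <- system.file("extdata", "example_expression.tsv",
#'                  package = "devhourglass")
#' e <- read_expression(f)
#' transitioning_genes(e, c = 2e-4, mode = "normalized")$widths
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    stop("expression file needs a gene id column and at least 2 stages",
         call. = FALSE)
  }
  names(df)[1] <- "gene_id"
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  vals <- as.matrix(df[, -1])
  if (!is.numeric(vals)) {
    stop("non-numeric expression values", call. = FALSE)
  }
  bad <- which(apply(vals < 0, 1, any))
  if (length(bad)) {
    stop(sprintf("negative expression value at data row %d", bad[1]),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a gene-age (phylostratum rank) table
#'
#' Two tab-separated columns: `gene_id` and integer rank `p_i >= 1`, where
#' lower ranks are evolutionarily older phylostrata. Genes absent from the
#' table have unknown age and are excluded from age-index computations.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id` and `rank`.
#' @examples
#' f <- system.file("extdata", "example_ages.tsv", package = "devhourglass")
#' read_ages(f)
#' @export
read_ages <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("age file needs gene_id and rank columns",
                         call. = FALSE)
  names(df)[1:2] <- c("gene_id", "rank")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(df$rank < 1 | df$rank != as.integer(df$rank))) {
    stop("ranks must be positive integers", call. = FALSE)
  }
  tibble::as_tibble(df[, c("gene_id", "rank")])
}

expr_matrix <- function(e) {
  stopifnot(is.data.frame(e), "gene_id" %in% names(e))
  m <- as.matrix(e[, setdiff(names(e), "gene_id")])
  rownames(m) <- e$gene_id
  if (ncol(m) < 2) stop("at least 2 stages are required", call. = FALSE)
  if (any(m < 0)) stop("negative expression values", call. = FALSE)
  m
}

#' Normalize expression columns to unit sums
#'
#' Divides every value by its stage's column total,
#' `e'_{i,l} = e_{i,l} / sum_j e_{j,l}`, so each stage column sums to 1
#' while within-stage ordering is preserved. A stage with zero total
#' expression is an error (remove all-zero genes first if needed, see
#' [filter_zero_genes()]). The operation is idempotent.
#'
#' @param e Expression tibble (`gene_id` plus stage columns).
#' @return Expression tibble on the normalized scale.
#' @export
normalize_expression <- function(e) {
  m <- expr_matrix(e)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop(sprintf("stage '%s' has zero total expression",
                 colnames(m)[which(tot <= 0)[1]]), call. = FALSE)
  }
  out <- sweep(m, 2, tot, "/")
  dplyr::bind_cols(tibble::tibble(gene_id = e$gene_id),
                   tibble::as_tibble(out))
}

#' Drop genes with zero expression in every stage
#'
#' @param e Expression tibble.
#' @return The tibble without all-zero genes.
#' @export
filter_zero_genes <- function(e) {
  m <- expr_matrix(e)
  e[rowSums(m) > 0, ]
}

# per-gene stage-to-stage changes; columns are pairs (l-1, l) for l = 2..L
delta_matrix <- function(e, mode = c("normalized", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "normalized") e <- normalize_expression(e)
  m <- expr_matrix(e)
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  colnames(d) <- paste0(2:ncol(m))
  d
}

#' Identify transitioning genes per stage-pair
#'
#' A gene `i` is transitioning at the stage-pair `(l - 1, l)` when the
#' absolute change of its expression between the two stages exceeds the
#' transition threshold: `|delta_{i,l}| > c` (strict), with
#' `delta_{i,l} = e_{i,l} - e_{i,l-1}` on the absolute scale or the
#' normalized scale (see [normalize_expression()]). A gene may transition
#' at several stage-pairs or at none; a gene transitioning `n` times is
#' counted in `n` stage-pair widths.
#'
#' @param e Expression tibble.
#' @param c Transition threshold (>= 0).
#' @param mode `"normalized"` (default) or `"absolute"` expression scale.
#' @return An object of class `stage_pair_report`: a list with
#'   `membership` (tibble `gene_id`, `pair` where `pair = l` labels the
#'   pair `(l - 1, l)`), `widths` (tibble `pair`, `n`), and the `c`,
#'   `mode`, `stages` used.
#' @export
transitioning_genes <- function(e, c, mode = c("normalized", "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(c) || length(c) != 1 || c < 0) {
    stop("`c` must be a single threshold >= 0", call. = FALSE)
  }
  d <- delta_matrix(e, mode)
  hit <- abs(d) > c
  idx <- which(hit, arr.ind = TRUE)
  membership <- tibble::tibble(
    gene_id = rownames(d)[idx[, 1]],
    pair = as.integer(colnames(d)[idx[, 2]])
  )
  membership <- dplyr::arrange(membership, .data$pair, .data$gene_id)
  widths <- tibble::tibble(pair = as.integer(colnames(d)),
                           n = as.integer(colSums(hit)))
  structure(
    list(membership = membership, widths = widths, c = c, mode = mode,
         stages = colnames(expr_matrix(e))),
    class = "stage_pair_report"
  )
}

#' @export
print.stage_pair_report <- function(x, ...) {
  cat(sprintf("<stage_pair_report> mode = %s, c = %g, %d memberships\n",
              x$mode, x$c, nrow(x$membership)))
  print(x$widths)
  invisible(x)
}

#' Transcriptome age index per stage-pair
#'
#' For each stage-pair `(l - 1, l)`, the TAI is the expression-weighted
#' mean phylostratum rank of its transitioning genes with known age:
#' `TAI(l) = sum_i p_i w_i / sum_i w_i` with weights `w_i = e'_{i,l}`, the
#' normalized expression at the later stage of the pair (set
#' `weights = "absolute"` to weight by raw expression instead). Lower TAI
#' means an evolutionarily older transcriptome. Pairs with fewer than
#' `min_genes` age-known transitioning genes report `NA` (the gating the
#' analysis uses to avoid unstable averages on thin pairs).
#'
#' @param report A [transitioning_genes()] report built from `e`.
#' @param e The same expression tibble the report was built from.
#' @param ages Age tibble (`gene_id`, `rank`), see [read_ages()].
#' @param min_genes Minimum number of age-known transitioning genes per
#'   pair.
#' @param weights `"normalized"` (default) or `"absolute"` expression
#'   weights.
#' @return Tibble with columns `pair`, `n_transitioning`, `n_with_age`,
#'   `tai`.
#' @export
tai_per_stage_pair <- function(report, e, ages, min_genes = 1,
                               weights = c("normalized", "absolute")) {
  stopifnot(inherits(report, "stage_pair_report"), min_genes >= 1)
  weights <- match.arg(weights)
  w_m <- expr_matrix(if (weights == "normalized") normalize_expression(e)
                     else e)
  rank_of <- stats::setNames(ages$rank, ages$gene_id)
  purrr::map_dfr(report$widths$pair, function(l) {
    genes <- report$membership$gene_id[report$membership$pair == l]
    p <- rank_of[genes]
    known <- genes[!is.na(p)]
    tai <- NA_real_
    if (length(known) >= min_genes) {
      w <- w_m[known, l]
      tai <- sum(rank_of[known] * w) / sum(w)
    }
    tibble::tibble(pair = l, n_transitioning = length(genes),
                   n_with_age = length(known), tai = tai)
  })
}

#' Sweep the transition threshold
#'
#' For each threshold in `c_grid`, computes the stage-pair widths
#' `n(2..L)` of transitioning genes and scores the resulting profile with
#' [hourglass_score()] (all pairs considered; the first-stage exclusion is
#' a simulation-only convention). The reported `waist` is the stage-pair
#' index `l` labelling `(l - 1, l)`.
#'
#' @param e Expression tibble.
#' @param c_grid Numeric vector of thresholds (>= 0).
#' @param mode Expression scale, as in [transitioning_genes()].
#' @return A tibble of class `threshold_sweep` with columns `c`, `H`,
#'   `H_robust`, `waist`, `total` (total membership count).
#' @export
threshold_sweep <- function(e, c_grid, mode = c("normalized", "absolute")) {
  mode <- match.arg(mode)
  if (!length(c_grid) || any(c_grid < 0)) {
    stop("`c_grid` must be a nonempty vector of thresholds >= 0",
         call. = FALSE)
  }
  d <- delta_matrix(e, mode)
  out <- purrr::map_dfr(sort(c_grid), function(cc) {
    n <- colSums(abs(d) > cc)
    hs <- hourglass_score(n, exclude_first = FALSE)
    tibble::tibble(c = cc, H = hs$H, H_robust = hs$H_robust,
                   waist = hs$waist + 1L, total = sum(n))
  })
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Empirical CDF of expression changes
#'
#' Pools `|delta_{i,l}|` over all genes and stage-pairs and returns the
#' empirical cumulative distribution, which supports choosing a transition
#' threshold inside the bulk of the variation range.
#'
#' @param e Expression tibble.
#' @param mode Expression scale, as in [transitioning_genes()].
#' @return Tibble with columns `abs_delta` (sorted) and `cdf` (cumulative
#'   fraction, ending at 1).
#' @export
delta_cdf <- function(e, mode = c("normalized", "absolute")) {
  d <- sort(abs(as.vector(delta_matrix(e, mode))))
  tibble::tibble(abs_delta = d, cdf = seq_along(d) / length(d))
}
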