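write_expr_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

toy_expr <- function() {
  tibble::tibble(
    gene_id = c("a", "b", "c"),
    s1 = c(1, 3, 4),
    s2 = c(2, 2, 4),
    s3 = c(5, 1, 2),
    s4 = c(5, 1, 2)
  )
}

test_that("expression and age readers validate their inputs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(toy_expr(), f)
  e <- read_expression(f)
  expect_equal(dim(e), c(3L, 5L))
  expect_equal(names(e)[1], "gene_id")

  dup <- toy_expr(); dup$gene_id[2] <- "a"
  write_expr_tsv(dup, f)
  expect_error(read_expression(f), "duplicate gene id.*a")

  neg <- toy_expr(); neg$s2[3] <- -1
  write_expr_tsv(neg, f)
  expect_error(read_expression(f), "negative expression value at data row 3")

  fa <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(tibble::tibble(gene_id = c("a", "b"), rank = c(1L, 3L)), fa)
  ages <- read_ages(fa)
  expect_equal(ages$rank, c(1L, 3L))
  write_expr_tsv(tibble::tibble(gene_id = c("a", "b"), rank = c(0L, 3L)), fa)
  expect_error(read_ages(fa), "positive integers")
})

test_that("normalization yields unit column sums and is idempotent", {
  e <- toy_expr()
  en <- normalize_expression(e)
  m <- as.matrix(en[, -1])
  expect_equal(unname(colSums(m)), rep(1, 4), tolerance = 1e-12)
  expect_equal(en$s1, c(1, 3, 4) / 8)
  expect_equal(en$s2, c(0.25, 0.25, 0.5))
  expect_equal(normalize_expression(en), en, tolerance = 1e-12)
  # within-column ordering preserved
  expect_equal(order(en$s3), order(e$s3))
  zero <- e; zero$s2 <- 0
  expect_error(normalize_expression(zero), "stage 's2' has zero total")
  expect_equal(nrow(filter_zero_genes(rbind(e, list("z", 0, 0, 0, 0)))), 3L)
})

test_that("transitioning genes use a strict threshold per stage-pair", {
  e <- tibble::tibble(gene_id = "g1", s1 = 1, s2 = 3, s3 = 3)
  rep_abs <- transitioning_genes(e, c = 1, mode = "absolute")
  expect_equal(rep_abs$membership$pair, 2L)  # delta = (2, 0)
  expect_equal(rep_abs$widths$n, c(1L, 0L))

  e2 <- toy_expr()
  # threshold above every |delta| leaves all sets empty
  rep_hi <- transitioning_genes(e2, c = 100, mode = "absolute")
  expect_equal(sum(rep_hi$widths$n), 0L)
  # c = 0: every nonzero change transitions; the flat s3 -> s4 pair is empty
  # gene c is flat into s2, and the s3 -> s4 pair is entirely flat
  rep0 <- transitioning_genes(e2, c = 0, mode = "absolute")
  expect_equal(rep0$widths$n, c(2L, 3L, 0L))
  # boundary: |delta| exactly c is NOT transitioning
  eb <- tibble::tibble(gene_id = "g", s1 = 0, s2 = 2)
  expect_equal(sum(transitioning_genes(eb, c = 2, mode = "absolute")$widths$n), 0L)
  expect_error(transitioning_genes(e2, c = -1), ">= 0")
})

test_that("threshold monotonicity: larger c gives nested membership", {
  set.seed(30)
  e <- tibble::tibble(gene_id = sprintf("g%02d", 1:40))
  for (s in 1:5) e[[paste0("s", s)]] <- runif(40, 0, 10)
  cs <- c(0.5, 1, 2, 4)
  members <- lapply(cs, function(cc) {
    r <- transitioning_genes(e, cc, mode = "absolute")$membership
    paste(r$gene_id, r$pair)
  })
  for (i in seq_along(cs)[-1]) {
    expect_true(all(members[[i]] %in% members[[i - 1]]))
  }
  sw <- threshold_sweep(e, cs, mode = "absolute")
  expect_true(all(diff(sw$total) <= 0))
})

test_that("TAI is the expression-weighted mean rank over age-known genes", {
  # single transitioning gene of rank 4 -> TAI 4
  e1 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 1), s2 = c(9, 1))
  r1 <- transitioning_genes(e1, c = 0.2, mode = "normalized")
  ages1 <- tibble::tibble(gene_id = "a", rank = 4L)
  t1 <- tai_per_stage_pair(r1, e1, ages1)
  expect_equal(t1$tai, 4)

  # equal weights, ranks 2 and 4 -> 3; weights (0.75, 0.25), ranks (1, 3) -> 1.5
  e2 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(5, 5), s2 = c(6, 6))
  r2 <- transitioning_genes(e2, c = 0.01, mode = "absolute")
  expect_equal(tai_per_stage_pair(
    r2, e2, tibble::tibble(gene_id = c("a", "b"), rank = c(2L, 4L)))$tai, 3)
  e3 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 1), s2 = c(7.5, 2.5))
  r3 <- transitioning_genes(e3, c = 0.1, mode = "normalized")
  t3 <- tai_per_stage_pair(
    r3, e3, tibble::tibble(gene_id = c("a", "b"), rank = c(1L, 3L)))
  expect_equal(t3$tai, 0.75 * 1 + 0.25 * 3)

  # min_genes gating: pairs with too few age-known genes report NA
  t1b <- tai_per_stage_pair(r1, e1, ages1, min_genes = 2)
  expect_true(is.na(t1b$tai))
  # TAI bounds: within [min, max] rank of contributors
  expect_true(t3$tai >= 1 && t3$tai <= 3)
})

test_that("the delta CDF is a valid ECDF with the right median", {
  e <- tibble::tibble(gene_id = c("a", "b", "c"),
                      s1 = c(1, 2, 3), s2 = c(2, 2, 1), s3 = c(2, 5, 1))
  cdf <- delta_cdf(e, mode = "absolute")
  # |delta| values: pair (1,2): 1,0,2; pair (2,3): 0,3,0
  expect_equal(cdf$abs_delta, sort(c(1, 0, 2, 0, 3, 0)))
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_equal(max(cdf$cdf), 1)
  expect_equal(stats::median(cdf$abs_delta), 0.5)
  flat <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 2), s2 = c(1, 2))
  expect_true(all(delta_cdf(flat, mode = "absolute")$abs_delta == 0))
})
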