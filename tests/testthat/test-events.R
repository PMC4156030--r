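test_that("deletion removes the gene and reports deprived downstream genes", {
  d <- fixture_dgen("cascade6")
  res <- apply_deletion(d, 1L)  # stage-1 gene regulating 3 and 4
  expect_setequal(res$lost_downstream, c(3L, 4L))
  expect_equal(dgen_widths(res$dgen), c(1L, 2L, 2L, 2L))
  expect_false(1L %in% dgen_genes(res$dgen)$instance_id)
  expect_error(apply_deletion(d, 999L), "not present")

  # a gene with no downstream targets reports nothing
  chain <- fixture_dgen("chain3")
  expect_equal(apply_deletion(chain, 3L)$lost_downstream, integer(0))
})

test_that("duplication copies regulators, label and t0", {
  set.seed(2)
  d <- build_dgen(4, 6, specificity_profile("linear", 4))
  g <- d$ids[[2]][1]
  d$t0[[2]][1] <- 5L
  u <- dgen_upstream(d, g); dn <- dgen_downstream(d, g)
  res <- apply_duplication(d, g)
  d2 <- res$dgen
  expect_equal(dgen_widths(d2)[2], 7L)
  new <- res$new_instance_id
  expect_setequal(dgen_upstream(d2, new), u)
  expect_setequal(dgen_downstream(d2, new), dn)
  genes <- dgen_genes(d2)
  expect_equal(genes$label[genes$instance_id == new],
               genes$label[genes$instance_id == g])
  expect_equal(genes$t0[genes$instance_id == new], 5L)
  # each downstream target gained one upstream regulator
  for (t in dn) {
    expect_equal(length(dgen_upstream(d2, t)), length(dgen_upstream(d, t)) + 1L)
  }
})

test_that("rewiring respects the degenerate binomial cases", {
  # s'(l) = 0: N- = N+ = 0, downstream untouched; upstream redraw is empty
  # and repaired to a single uniform regulator
  set.seed(4)
  d <- build_dgen(3, 4, const_profile(3, 0))  # complete bipartite
  g <- d$ids[[2]][1]
  res <- apply_rewiring(d, g, const_profile(3, 1), generation = 9)
  expect_setequal(dgen_downstream(res$dgen, g), dgen_downstream(d, g))
  expect_equal(res$lost_downstream, integer(0))
  expect_length(dgen_upstream(res$dgen, g), 1L)
  genes <- dgen_genes(res$dgen)
  expect_equal(genes$t0[genes$instance_id == g], 9L)
  expect_false(genes$label[genes$instance_id == g] %in% dgen_genes(d)$label)

  # s'(l) = 1 with full connection: all |D| removed, all re-added (the only
  # unconnected targets are the ones just dropped)
  set.seed(5)
  d1 <- build_dgen(3, 4, const_profile(3, 0))
  g1 <- d1$ids[[1]][2]
  res1 <- apply_rewiring(d1, g1, const_profile(3, 0), generation = 1)
  expect_length(dgen_downstream(res1$dgen, g1), 4L)
})

test_that("rewired out-degree stays within [0, 2|D|] over many draws", {
  set.seed(6)
  prof <- const_profile(3, 0.5)
  d <- build_dgen(3, 30, prof)
  g <- d$ids[[2]][1]
  d0 <- length(dgen_downstream(d, g))
  for (i in 1:2000) {
    nd <- length(dgen_downstream(apply_rewiring(d, g, prof, i)$dgen, g))
    expect_gte(nd, 0)
    expect_lte(nd, 2 * d0)
  }
})

test_that("regulatory-failure probability matches its closed form", {
  expect_equal(regulatory_failure_prob(0, 4), 0)
  expect_equal(regulatory_failure_prob(1, 4), 1)
  expect_equal(regulatory_failure_prob(1, 0), 1)
  expect_equal(regulatory_failure_prob(0.5, 4), 1 - exp(-4))
  expect_equal(regulatory_failure_prob(0.25, 2), 1 - exp(-2 * 0.25 / 0.75))
  # z = 0 makes partial loss harmless; z = Inf makes any loss fatal
  expect_equal(regulatory_failure_prob(c(0.1, 0.9), 0), c(0, 0))
  expect_equal(regulatory_failure_prob(c(0, 0.01, 1), Inf), c(0, 1, 1))
  expect_error(regulatory_failure_prob(1.2, 4), "\\[0, 1\\]")
  expect_error(regulatory_failure_prob(0.5, -1), ">= 0")
})

test_that("P_RF is monotone in r and z and continuous up to r -> 1", {
  r <- seq(0, 0.99, by = 0.01)
  for (z in c(0.5, 2, 4, 8)) {
    p <- regulatory_failure_prob(r, z)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_true(all(regulatory_failure_prob(0.5, c(2)) <=
                    regulatory_failure_prob(0.5, c(4))))
  expect_equal(regulatory_failure_prob(1 - 1e-9, 4), 1, tolerance = 1e-6)
})

test_that("developmental-failure policies implement their thresholds", {
  d <- fixture_dgen("cascade6")  # w(L) = 2
  expect_false(check_developmental_failure(d, 2, df_policy("strict")))
  expect_true(check_developmental_failure(d, 3, df_policy("strict")))
  expect_false(check_developmental_failure(d, 7, df_policy("tolerant", gamma_tol = 5)))
  expect_true(check_developmental_failure(d, 8, df_policy("tolerant", gamma_tol = 5)))
  # strict is tolerant with gamma_tol = 0
  expect_equal(check_developmental_failure(d, 3, df_policy("tolerant", gamma_tol = 0)),
               check_developmental_failure(d, 3, df_policy("strict")))
  # probabilistic: never fails at or above gamma0; ramps to certainty
  expect_false(check_developmental_failure(d, 2, df_policy("probabilistic", ramp_width = 4)))
  set.seed(1)
  fails <- replicate(2000, check_developmental_failure(
    d, 4, df_policy("probabilistic", ramp_width = 4)))
  expect_equal(mean(fails), 0.5, tolerance = 0.06)
  expect_true(check_developmental_failure(d, 10, df_policy("probabilistic", ramp_width = 4)))
})
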