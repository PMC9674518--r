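test_that("gene filter applies the low-expression and CV rules", {
  m <- toy_matrix(c(0.5, 10, 1, 30,
                    0.5, 10, 1, 30,
                    2.0, 10, 5, 30),
                  c("low", "flat", "varied", "flat2"),
                  c("s1", "s2", "s3"))
  fm <- filter_genes(m)
  # low in 2 of 3 samples (> half) -> rule 1
  expect_true("low" %in% fm$removed_low)
  # CV = 0 -> rule 2
  expect_true(all(c("flat", "flat2") %in% fm$removed_cv))
  # low in 0 samples, CV = sd/mean ~ 0.99 -> retained
  expect_identical(rownames(fm$expr), "varied")
  cv <- stats::sd(m["varied", ]) / mean(m["varied", ])
  expect_gt(cv, 0.8)
  # zero-mean gene has undefined CV and is removed
  m2 <- rbind(m, zero = c(0, 0, 0))
  expect_true("zero" %in% filter_genes(m2)$removed_low)
})

test_that("multiplicative updates decrease the objective monotonically", {
  set.seed(10)
  v <- matrix(runif(40 * 12, 0, 5), 40, 12,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("s%02d", 1:12)))
  # short iteration budget: convergence warnings are expected here
  nmf <- suppressWarnings(
    fit_consensus_nmf(v, k = 3, restarts = 2, seed = 1,
                      max_iter = 300, trace_objective = TRUE))
  tr <- nmf$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * tr[-length(tr)] + 1e-12))
  expect_true(all(nmf$w >= 0) && all(nmf$h >= 0))
})

test_that("an exactly factorizable matrix is recovered to machine precision", {
  set.seed(11)
  v <- outer(runif(10) + 0.5, runif(8) + 0.5)
  dimnames(v) <- list(paste0("g", 1:10), paste0("s", 1:8))
  nmf <- fit_consensus_nmf(v, k = 1, restarts = 3, seed = 2)
  expect_lt(min(nmf$objectives), 1e-6)
})

test_that("noiseless block structure yields an exact 0/1 consensus", {
  v <- matrix(0.01, 30, 30)
  for (b in 0:2) v[b * 10 + 1:10, b * 10 + 1:10] <- 10
  dimnames(v) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:30))
  nmf <- suppressWarnings(
    fit_consensus_nmf(v, k = 3, restarts = 10, seed = 3))
  truth <- rep(1:3, each = 10)
  expect_equal(unname(nmf$consensus), outer(truth, truth, function(a, b)
    as.numeric(a == b)))
  expect_equal(adjusted_rand(nmf$assignment, truth), 1)
  expect_gt(nmf$cophenetic, 0.999)
  # consensus invariants
  expect_true(isSymmetric(nmf$consensus))
  expect_true(all(diag(nmf$consensus) == 1))
  expect_true(all(nmf$consensus >= 0 & nmf$consensus <= 1))
})

test_that("consensus NMF is deterministic given a seed and validates k", {
  set.seed(12)
  v <- matrix(runif(30 * 10, 0, 3), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("s%02d", 1:10)))
  a <- suppressWarnings(
    fit_consensus_nmf(v, k = 2, restarts = 3, seed = 5, max_iter = 200))
  b <- suppressWarnings(
    fit_consensus_nmf(v, k = 2, restarts = 3, seed = 5, max_iter = 200))
  expect_identical(a$w, b$w)
  expect_identical(a$h, b$h)
  expect_error(fit_consensus_nmf(v, k = 11, restarts = 2, seed = 1),
               "exceeds")
  expect_error(fit_consensus_nmf(-v, k = 2, restarts = 2, seed = 1),
               "non-negative")
})

test_that("exemplar ranking follows the loading-margin formula", {
  w <- rbind(g1 = c(5, 1), g2 = c(1, 5), g3 = c(3, 3))
  fake <- list(w = w)
  r1 <- rank_exemplar_genes(fake, 1)
  expect_identical(r1$gene, c("g1", "g3", "g2"))
  expect_equal(r1$score, c(4, 0, -4))
  r2 <- rank_exemplar_genes(fake, 2)
  expect_identical(r2$gene, c("g2", "g3", "g1"))
  expect_error(rank_exemplar_genes(list(w = w[, 1, drop = FALSE]), 1),
               "k >= 2")
})

test_that("exemplar ranking matches the brute-force oracle on random W", {
  set.seed(13)
  for (rep in 1:3) {
    w <- matrix(runif(50 * 4), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    for (i in 1:4) {
      got <- rank_exemplar_genes(list(w = w), i)
      want <- oracle_exemplar(w, i)
      expect_identical(got$gene, want$gene)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("permutation marker test handles degenerate features", {
  set.seed(14)
  n <- 40
  assignment <- stats::setNames(rep(c("A", "B"), each = n / 2),
                                sprintf("s%02d", 1:n))
  m <- rbind(
    informative = c(rnorm(n / 2, 6, 0.3), rnorm(n / 2, 3, 0.3)),
    constant = rep(2, n),
    noise = rnorm(n, 4, 1))
  colnames(m) <- names(assignment)
  res <- select_markers(m, assignment, "A", rownames(m),
                        n_permutations = 49, seed = 3, n_trees = 200)
  # a constant feature is never split on: importance exactly 0, null ties
  expect_equal(res$p[res$gene == "constant"], 1)
  expect_false(res$selected[res$gene == "constant"])
  expect_true(res$importance[res$gene == "informative"] >
                res$importance[res$gene == "constant"])
  # add-one permutation p floor: observed beating all nulls gives 1/(1+n)
  expect_gte(min(res$p), 1 / 50)
})

test_that("NTP assigns template-identical samples at zero distance", {
  marker_sets <- list(A = paste0("a", 1:4), B = paste0("b", 1:4))
  genes <- c(marker_sets$A, marker_sets$B, paste0("n", 1:12))
  z <- matrix(0, length(genes), 3,
              dimnames = list(genes, c("pureA", "pureB", "flat")))
  z[marker_sets$A, "pureA"] <- 1
  z[marker_sets$B, "pureB"] <- 1
  res <- ntp_classify(z, marker_sets, n_permutations = 99, seed = 1,
                      standardize = FALSE)
  expect_identical(res$subtype[1:2], c("A", "B"))
  expect_equal(res$distance[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(res$p[1:2], rep(1 / 100, 2), tolerance = 0.05)
  # the all-zero sample is equidistant: deterministic name-order tie, flagged
  expect_identical(res$subtype[3], "A")
  expect_true(res$tied[3])
  expect_error(ntp_classify(z, list(A = "missing_gene", B = "b1"),
                            n_permutations = 9, seed = 1),
               "all markers missing")
})

test_that("label matching maximizes agreement up to permutation", {
  pred <- c("x", "x", "y", "y", "z", "z")
  truth <- c("M1", "M1", "M2", "M2", "B1", "B1")
  expect_identical(match_labels(pred, truth), truth)
  # imperfect but majority-consistent
  pred2 <- c("x", "y", "y", "y", "z", "z")
  expect_equal(sum(match_labels(pred2, truth) == truth), 5L)
})
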