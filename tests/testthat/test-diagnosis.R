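# deterministic planted benign/malignant cohort: `informative` genes carry a
# per-gene log2 shift in the PTC class
make_diag_cohort <- function(n = 120, n_genes = 60, informative = 5,
                             effect = 2, noise = 0.5, seed = 50) {
  set.seed(seed)
  lab <- rep(c("BTN", "PTC"), each = n / 2)
  lg <- matrix(rnorm(n_genes, 3, 1), n_genes, n) +
    matrix(rnorm(n_genes * n, 0, noise), n_genes, n)
  lg[seq_len(informative), lab == "PTC"] <-
    lg[seq_len(informative), lab == "PTC"] + effect
  m <- pmax(2^lg - 1, 0)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  list(m = m, labels = stats::setNames(lab, colnames(m)),
       informative = rownames(m)[seq_len(informative)])
}

test_that("differential expression computes the stated fold-change and flags", {
  co <- make_diag_cohort(n = 40, n_genes = 30, noise = 0.3)
  # fixed-value gene: PTC all 8, BTN all 2 -> log2(9/3)
  m <- co$m
  m["g030", co$labels == "PTC"] <- 8
  m["g030", co$labels == "BTN"] <- 2
  de <- differential_expression(m, co$labels)
  row <- de[de$gene == "g030", ]
  expect_equal(row$log2fc, log2(3), tolerance = 1e-12)
  expect_lt(row$p, 1e-4)
  expect_true(row$changed)
  expect_identical(row$direction, "up")
  # constant gene: p = 1, not changed
  m["g029", ] <- 5
  de2 <- differential_expression(m, co$labels)
  expect_equal(de2$p[de2$gene == "g029"], 1)
  expect_false(de2$changed[de2$gene == "g029"])
  # disjunction vs conjunction modes
  de_and <- differential_expression(m, co$labels, mode = "and")
  expect_true(all(which(de_and$changed) %in% which(de2$changed)))
})

test_that("null differential expression is calibrated", {
  set.seed(51)
  # large enough groups that the rank-sum null is close to continuous
  n <- 100
  lab <- stats::setNames(rep(c("BTN", "PTC"), each = n / 2),
                         sprintf("s%03d", 1:n))
  m <- matrix(runif(800 * n, 1, 100), 800, n,
              dimnames = list(sprintf("g%03d", 1:800), names(lab)))
  de <- differential_expression(m, lab)
  fpr <- mean(de$p < 0.05)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})

test_that("stratified split preserves class ratios and partitions exactly", {
  ids <- sprintf("s%03d", 1:150)
  lab <- stats::setNames(rep(c("PTC", "BTN"), c(100, 50)), ids)
  sp <- stratified_split(ids, lab, 0.2, seed = 7)
  expect_equal(sum(lab[sp$test] == "PTC"), 20L)
  expect_equal(sum(lab[sp$test] == "BTN"), 10L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)
  sp2 <- stratified_split(ids, lab, 0.2, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp, stratified_split(ids, lab, 0.2, seed = 8)))
  expect_error(stratified_split(ids, lab, 1.2), "test_fraction")
})

test_that("trapezoidal AUC equals the Mann-Whitney identity", {
  set.seed(52)
  for (rep in 1:5) {
    y <- runif(40) < 0.4
    if (!any(y) || all(y)) next
    sc <- sample(round(rnorm(40), 1))  # induce ties
    auc <- roc_curve(sc, y)$auc
    # U statistic with ties counted 1/2
    u <- sum(vapply(sc[y], function(a)
      sum(a > sc[!y]) + 0.5 * sum(a == sc[!y]), numeric(1)))
    expect_equal(auc, u / (sum(y) * sum(!y)), tolerance = 1e-12)
  }
  # perfect separation and degenerate input
  expect_equal(roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_error(roc_curve(1:3, rep(TRUE, 3)), "both classes")
})

test_that("RFE recovers planted informative genes and is deterministic", {
  co <- make_diag_cohort(n = 120, n_genes = 40, informative = 4,
                         noise = 0.5, seed = 53)
  sig <- rfe_signature(co$m, co$labels, rownames(co$m),
                       fold_list = c(4, 6), seed = 9)
  # the panel is drawn from the informative genes (RFE drops noise first)
  expect_true(all(sig$panel %in% co$informative))
  expect_gte(length(sig$panel), 1L)
  sig2 <- rfe_signature(co$m, co$labels, rownames(co$m),
                        fold_list = c(4, 6), seed = 9)
  expect_identical(sig$panel, sig2$panel)
  expect_identical(sig$coefficients, sig2$coefficients)
  # two-gene pool evaluates sizes {2, 1} only
  sig3 <- rfe_signature(co$m, co$labels, co$informative[1:2],
                        fold_list = c(4), seed = 9)
  expect_setequal(sig3$sizes$size, c(2L, 1L))
  expect_error(rfe_signature(co$m, co$labels, "g001"), ">= 2 candidate")
})

test_that("test samples never influence signature training", {
  co <- make_diag_cohort(n = 150, n_genes = 30, seed = 54)
  sp <- stratified_split(colnames(co$m), co$labels, 0.2, seed = 3)
  fit1 <- rfe_signature(co$m[, sp$train], co$labels[sp$train],
                        rownames(co$m), fold_list = c(4), seed = 5)
  # leakage canary: corrupt the held-out samples wildly
  m2 <- co$m
  m2[, sp$test] <- m2[, sp$test] * 1000 + 7
  fit2 <- rfe_signature(m2[, sp$train], co$labels[sp$train],
                        rownames(co$m), fold_list = c(4), seed = 5)
  expect_identical(fit1$panel, fit2$panel)
  expect_identical(fit1$coefficients, fit2$coefficients)
  expect_identical(fit1$sizes, fit2$sizes)
})

test_that("classifier comparison separates planted classes and detects nulls", {
  co <- make_diag_cohort(n = 90, n_genes = 30, informative = 5,
                         noise = 0.4, seed = 55)
  sp <- stratified_split(colnames(co$m), co$labels, 0.3, seed = 2)
  ev <- evaluate_classifiers(co$informative, co$m[, sp$train],
                             co$m[, sp$test], co$labels[sp$train],
                             co$labels[sp$test], fold_list = c(4),
                             seed = 11)
  expect_setequal(names(ev), c("LR", "SVM", "NB", "RF", "KNN"))
  for (cn in names(ev)) expect_gte(ev[[cn]]$test_auc, 0.9)
  expect_equal(ev$LR$test_auc, 1.0)
  # shuffled labels give chance-level held-out AUC
  set.seed(56)
  shuf <- stats::setNames(sample(co$labels), names(co$labels))
  ev0 <- evaluate_classifiers(co$informative, co$m[, sp$train],
                              co$m[, sp$test], shuf[sp$train],
                              shuf[sp$test], fold_list = c(4),
                              classifiers = "LR", seed = 11)
  expect_lt(abs(ev0$LR$test_auc - 0.5), 0.25)
  expect_error(evaluate_classifiers(co$informative, co$m[, sp$train],
                                    co$m[, sp$test], co$labels[sp$train],
                                    co$labels[sp$test],
                                    classifiers = "MLP"),
               "unknown classifier")
})
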