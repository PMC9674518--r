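# Benign-vs-malignant differential expression and the diagnostic
# gene-signature builder: stratified 80/20 split, L2-regularized logistic
# regression with recursive feature elimination scored by stratified
# cross-validated AUC, and a five-classifier ROC comparison on the held-out
# test set.

#' Benign-vs-malignant differential expression
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value between the two histology
#' classes, `log2FC = log2((mean_PTC + 1) / (mean_BTN + 1))` on the linear
#' scale, Benjamini-Hochberg q. The `changed` flag follows the disjunctive
#' volcano cutoff `p < p_cutoff OR |log2FC| > lfc_cutoff` by default; set
#' `mode = "and"` for the conjunctive rule.
#'
#' @param m linear-scale expression matrix.
#' @param labels named vector of class labels over `colnames(m)`.
#' @param positive label of the malignant class (default "PTC"); fold-changes
#'   are positive when expression is higher in this class.
#' @param p_cutoff,lfc_cutoff volcano cutoffs (defaults 0.05 and 1).
#' @param mode `"or"` (default) or `"and"` combination of the two cutoffs.
#' @return data.frame `gene`, `log2fc`, `p`, `q`, `direction`, `changed`.
#' @export
differential_expression <- function(m, labels, positive = "PTC",
                                    p_cutoff = 0.05, lfc_cutoff = 1,
                                    mode = c("or", "and")) {
  mode <- match.arg(mode)
  validate_expression_matrix(m)
  labels <- labels[colnames(m)]
  pos <- labels == positive
  if (sum(pos) < 3 || sum(!pos) < 3)
    stop("need at least 3 samples per class")
  mean_pos <- rowMeans(m[, pos, drop = FALSE])
  mean_neg <- rowMeans(m[, !pos, drop = FALSE])
  lfc <- log2((mean_pos + 1) / (mean_neg + 1))
  p <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, pos]; y <- m[i, !pos]
    if (stats::sd(c(x, y)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  changed <- if (mode == "or") p < p_cutoff | abs(lfc) > lfc_cutoff
    else p < p_cutoff & abs(lfc) > lfc_cutoff
  data.frame(gene = rownames(m), log2fc = lfc, p = p, q = q,
             direction = ifelse(lfc >= 0, "up", "down"),
             changed = changed, row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratified train/test split
#'
#' Random per-class partition at `test_fraction` (rounded to nearest, at
#' least 1 test sample per class), preserving the class ratio of the full
#' cohort in both splits. The split is disjoint and exhaustive.
#'
#' @param sample_ids character vector of sample ids.
#' @param labels class labels, same length.
#' @param test_fraction fraction held out (in (0, 1); default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
stratified_split <- function(sample_ids, labels, test_fraction = 0.2,
                             seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  with_local_seed(derive_seed(seed, "stratified_split"), {
    test <- unlist(lapply(split(sample_ids, labels), function(ids) {
      n_test <- max(1L, round(test_fraction * length(ids)))
      sample(ids, n_test)
    }), use.names = FALSE)
    list(train = setdiff(sample_ids, test), test = sort(test))
  })
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the score threshold over all observed values; ties are handled so
#' the trapezoidal AUC equals the Mann-Whitney identity
#' `U / (n_pos * n_neg)` (ties counted 1/2) exactly.
#'
#' @param scores numeric prediction scores (larger = more positive).
#' @param labels logical or two-level vector of true classes.
#' @param positive the positive label (ignored for logical labels).
#' @return list of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_curve <- function(scores, labels, positive = TRUE) {
  y <- if (is.logical(labels)) labels else labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("need both classes to draw a ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & y) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !y) / n_neg, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc), class = "roc_curve")
}

standardize_train <- function(x_train, x_other = NULL) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  tr <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
  if (is.null(x_other)) return(list(train = tr))
  list(train = tr, other = sweep(sweep(x_other, 2, mu), 2, sdv, "/"))
}

ridge_lr <- function(x, y, lambda = 0.01) {
  # glmnet needs >= 2 columns; pad single-feature fits with an all-zero
  # column, which ridge assigns a zero coefficient
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, `.pad` = 0)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = c(10 * lambda, lambda),
                        standardize = FALSE)
  attr(fit, "padded") <- padded
  fit
}

ridge_coef <- function(fit, lambda = 0.01) {
  b <- as.numeric(stats::coef(fit, s = lambda))
  out <- stats::setNames(b[-1], rownames(stats::coef(fit, s = lambda))[-1])
  if (isTRUE(attr(fit, "padded"))) out <- out[names(out) != ".pad"]
  out
}

ridge_score <- function(fit, x, lambda = 0.01) {
  if (isTRUE(attr(fit, "padded"))) x <- cbind(x, `.pad` = 0)
  as.numeric(stats::predict(fit, x, s = lambda, type = "link"))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ix <- sample(which(y == lv))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# Mean and SE of per-fold ridge-LR AUCs over all schemes in `fold_list`.
cv_auc_panel <- function(x, y, fold_list) {
  aucs <- numeric(0)
  for (k in fold_list) {
    fold <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
        warning("degenerate single-class fold skipped")
        next
      }
      sx <- standardize_train(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
      fit <- ridge_lr(sx$train, y[tr])
      sc <- ridge_score(fit, sx$other)
      aucs <- c(aucs, roc_curve(sc, y[!tr] == levels(y)[2])$auc)
    }
  }
  c(mean = mean(aucs), se = stats::sd(aucs) / sqrt(length(aucs)))
}

#' Build a diagnostic gene signature by recursive feature elimination
#'
#' Starting from the candidate pool, an L2-regularized logistic regression is
#' fitted on the (train-standardized) features and the feature with the
#' smallest absolute coefficient is dropped (10% of features at a time while
#' more than 100 remain). At each subset size the stratified cross-validated
#' AUC is recorded, per-fold, over every fold count in `fold_list`. The
#' selected panel is the smallest subset whose mean CV AUC is within one
#' standard error of the best mean (`rule = "one_se"`, the default) or the
#' best-mean subset (`rule = "best_mean"`); the final model is refitted on
#' the full training set.
#'
#' @param m linear-scale expression matrix of the training cohort.
#' @param labels named class labels over `colnames(m)` (two classes; the
#'   lexicographically larger level is scored as positive).
#' @param candidates candidate gene pool (>= 2 genes present).
#' @param fold_list cross-validation fold counts (default 4, 6, 8, 10).
#' @param seed integer seed.
#' @param rule `"one_se"` or `"best_mean"` panel-size selection.
#' @param pseudocount log2 pseudocount for the feature transform.
#' @return list of class `signature_model`: `panel`, `coefficients`
#'   (including intercept), `sizes` (data.frame `size`, `mean_auc`,
#'   `se_auc`), `rule`, `fold_list`, `train_mu`, `train_sd`, `positive`.
#' @export
rfe_signature <- function(m, labels, candidates, fold_list = c(4, 6, 8, 10),
                          seed = 1L, rule = c("one_se", "best_mean"),
                          pseudocount = 1) {
  rule <- match.arg(rule)
  candidates <- intersect(candidates, rownames(m))
  if (length(candidates) < 2) stop("need >= 2 candidate genes present")
  labels <- labels[colnames(m)]
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  x_all <- t(log2(m[candidates, , drop = FALSE] + pseudocount))

  with_local_seed(derive_seed(seed, "rfe_signature"), {
    current <- candidates
    sizes <- list()
    subset_of_size <- list()
    while (TRUE) {
      cv <- cv_auc_panel(x_all[, current, drop = FALSE], y, fold_list)
      sizes[[length(sizes) + 1]] <- data.frame(size = length(current),
                                               mean_auc = cv[["mean"]],
                                               se_auc = cv[["se"]])
      subset_of_size[[as.character(length(current))]] <- current
      if (length(current) == 1) break
      sx <- standardize_train(x_all[, current, drop = FALSE])
      fit <- ridge_lr(sx$train, y)
      b <- abs(ridge_coef(fit))
      drop_n <- if (length(current) > 100)
        max(1L, floor(0.1 * length(current))) else 1L
      drop <- names(sort(b))[seq_len(drop_n)]
      current <- setdiff(current, drop)
    }
    sizes <- do.call(rbind, sizes)
    best_ix <- which.max(sizes$mean_auc)
    chosen_size <- if (rule == "one_se") {
      thr <- sizes$mean_auc[best_ix] - sizes$se_auc[best_ix]
      min(sizes$size[sizes$mean_auc >= thr])
    } else sizes$size[best_ix]
    panel <- subset_of_size[[as.character(chosen_size)]]

    sx <- standardize_train(x_all[, panel, drop = FALSE])
    fit <- ridge_lr(sx$train, y)
    mu <- colMeans(x_all[, panel, drop = FALSE])
    sdv <- apply(x_all[, panel, drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    structure(list(panel = panel,
                   coefficients = c(intercept =
                     as.numeric(stats::coef(fit, s = 0.01))[1],
                     ridge_coef(fit)),
                   sizes = sizes, rule = rule, fold_list = fold_list,
                   train_mu = mu, train_sd = sdv,
                   positive = levels(y)[2], seed = seed,
                   pseudocount = pseudocount),
              class = "signature_model")
  })
}

#' Score new samples with a fitted signature
#'
#' @param model a `signature_model`.
#' @param m linear-scale expression matrix containing the panel genes.
#' @return named numeric vector of linear predictor scores (larger = more
#'   likely the positive class).
#' @export
predict_signature <- function(model, m) {
  miss <- setdiff(model$panel, rownames(m))
  if (length(miss)) stop("panel gene(s) absent: ", paste(miss, collapse = ", "))
  x <- t(log2(m[model$panel, , drop = FALSE] + model$pseudocount))
  z <- sweep(sweep(x, 2, model$train_mu), 2, model$train_sd, "/")
  b <- model$coefficients
  stats::setNames(as.numeric(b[1] + z %*% b[-1]), colnames(m))
}

classifier_score <- function(name, x_tr, y_tr, x_te, seed) {
  pos <- levels(y_tr)[2]
  with_local_seed(seed, switch(
    name,
    LR = {
      fit <- ridge_lr(x_tr, y_tr)
      ridge_score(fit, x_te)
    },
    SVM = {
      fit <- e1071::svm(x_tr, y_tr, kernel = "radial", scale = FALSE)
      dv <- attr(stats::predict(fit, x_te, decision.values = TRUE),
                 "decision.values")
      # orient decision values toward the positive class
      if (grepl(paste0("/", pos, "$"), colnames(dv)[1])) -dv[, 1] else dv[, 1]
    },
    NB = {
      fit <- e1071::naiveBayes(x_tr, y_tr)
      stats::predict(fit, x_te, type = "raw")[, pos]
    },
    RF = {
      fit <- randomForest::randomForest(x_tr, y_tr, ntree = 500)
      stats::predict(fit, x_te, type = "prob")[, pos]
    },
    KNN = {
      pr <- class::knn(x_tr, x_te, y_tr, k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    stop("unknown classifier: ", name)))
}

#' Compare classifiers on a fixed signature panel
#'
#' Trains each requested classifier on the train-split panel features
#' (standardized by training statistics), reports the stratified
#' cross-validated AUC on the training split and the ROC/AUC on the held-out
#' test split.
#'
#' @param panel character vector of signature genes.
#' @param m_train,m_test linear-scale expression matrices for the two splits.
#' @param labels_train,labels_test named class labels for the two splits.
#' @param classifiers subset of `c("LR", "SVM", "NB", "RF", "KNN")`.
#' @param fold_list fold counts for the training-split CV.
#' @param seed integer seed.
#' @param pseudocount log2 pseudocount.
#' @return named list per classifier: `cv_auc`, `test_auc`, `roc`
#'   (a `roc_curve` on the test split).
#' @export
evaluate_classifiers <- function(panel, m_train, m_test, labels_train,
                                 labels_test,
                                 classifiers = c("LR", "SVM", "NB", "RF",
                                                 "KNN"),
                                 fold_list = c(4, 6, 8, 10), seed = 1L,
                                 pseudocount = 1) {
  bad <- setdiff(classifiers, c("LR", "SVM", "NB", "RF", "KNN"))
  if (length(bad)) stop("unknown classifier: ", paste(bad, collapse = ", "))
  y_tr <- factor(labels_train[colnames(m_train)])
  y_te <- factor(labels_test[colnames(m_test)], levels = levels(y_tr))
  pos <- levels(y_tr)[2]
  x_tr_raw <- t(log2(m_train[panel, , drop = FALSE] + pseudocount))
  x_te_raw <- t(log2(m_test[panel, , drop = FALSE] + pseudocount))
  sx <- standardize_train(x_tr_raw, x_te_raw)

  out <- lapply(stats::setNames(classifiers, classifiers), function(cn) {
    cseed <- derive_seed(seed, paste0("clf_", cn))
    # training-split CV
    aucs <- with_local_seed(derive_seed(cseed, "cv"), {
      a <- numeric(0)
      for (k in fold_list) {
        fold <- stratified_folds(y_tr, k)
        for (f in seq_len(k)) {
          tr <- fold != f
          if (length(unique(y_tr[!tr])) < 2) next
          s2 <- standardize_train(x_tr_raw[tr, , drop = FALSE],
                                  x_tr_raw[!tr, , drop = FALSE])
          sc <- classifier_score(cn, s2$train, y_tr[tr], s2$other,
                                 derive_seed(cseed, paste0("fold", k, f)))
          a <- c(a, roc_curve(sc, y_tr[!tr] == pos)$auc)
        }
      }
      a
    })
    sc_te <- classifier_score(cn, sx$train, y_tr, sx$other,
                              derive_seed(cseed, "test"))
    roc <- roc_curve(sc_te, y_te == pos)
    list(cv_auc = mean(aucs), test_auc = roc$auc, roc = roc)
  })
  out
}
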