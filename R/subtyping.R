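# Subtype discovery by consensus non-negative matrix factorization, exemplar
# gene extraction, permutation-tested marker selection, and nearest template
# prediction for transferring subtypes to new cohorts.

#' Filter genes for unsupervised clustering
#'
#' Removes (1) genes expressed at low level (RPKM < `low_rpkm`) in strictly
#' more than half of samples, and (2) genes of low variance across samples
#' (coefficient of variation sd/mean < `min_cv`, computed on the linear
#' scale). Genes with zero mean have an undefined CV and are removed under
#' rule (2).
#'
#' @param m expression matrix on the linear RPKM scale.
#' @param low_rpkm low-expression threshold (default 1.0).
#' @param min_cv minimum coefficient of variation (default 0.8).
#' @return list of class `filtered_matrix`: `expr` (retained submatrix),
#'   `removed_low`, `removed_cv` (gene symbols removed by each rule; rule (1)
#'   is applied first), `n_input`.
#' @export
filter_genes <- function(m, low_rpkm = 1.0, min_cv = 0.8) {
  validate_expression_matrix(m)
  n <- ncol(m)
  low_frac <- rowSums(m < low_rpkm)
  rule1 <- low_frac > n / 2
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  rule2 <- !rule1 & (is.na(cv) | cv < min_cv)
  keep <- !rule1 & !rule2
  structure(list(expr = m[keep, , drop = FALSE],
                 removed_low = rownames(m)[rule1],
                 removed_cv = rownames(m)[rule2],
                 n_input = nrow(m)),
            class = "filtered_matrix")
}

nmf_objective <- function(v, w, h) sum((v - w %*% h)^2) / 2

nmf_single <- function(v, k, max_iter, tol, trace = FALSE) {
  eps <- .Machine$double.eps
  g <- nrow(v); s <- ncol(v)
  scale <- sqrt(mean(v) / k)
  w <- matrix(stats::runif(g * k), g, k) * scale
  h <- matrix(stats::runif(k * s), k, s) * scale
  obj <- nmf_objective(v, w, h)
  obj0 <- obj
  objs <- if (trace) numeric(max_iter) else NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, v) / (crossprod(w, w %*% h) + eps))
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    new_obj <- nmf_objective(v, w, h)
    if (trace) objs[it] <- new_obj
    if (abs(obj - new_obj) <= tol * max(obj, eps) ||
        new_obj <= 1e-10 * max(obj0, eps)) {
      converged <- TRUE
      if (trace) objs <- objs[seq_len(it)]
      break
    }
    obj <- new_obj
  }
  list(w = w, h = h, objective = new_obj, converged = converged,
       objective_trace = objs)
}

#' Consensus non-negative matrix factorization
#'
#' Factorizes a non-negative (log2-scale) expression matrix as `V ~ W H` by
#' Lee-Seung multiplicative updates minimizing the Frobenius error, repeated
#' over random restarts. Per restart, samples are hard-assigned to the factor
#' with maximal usage (argmax over each column of `H`); the consensus matrix
#' is the across-restart co-assignment frequency. The returned `W`, `H` come
#' from the restart with the lowest objective. Clustering stability is
#' summarized by the cophenetic correlation between `1 - consensus` and its
#' average-linkage dendrogram, and `consensus_clusters` cuts that dendrogram
#' at `k` (the reporting clustering).
#'
#' @param m non-negative numeric matrix, genes x samples (log2 of RPKM + 1).
#' @param k factorization rank (number of subtypes).
#' @param restarts number of random restarts (>= 2).
#' @param seed integer seed; restarts use seeds derived from it.
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   objective-change convergence tolerance.
#' @param trace_objective keep the per-iteration objective of each restart.
#' @return list of class `nmf_result`: `w`, `h`, `k`, `objectives` (per
#'   restart), `assignment` (named factor-index vector, best restart),
#'   `consensus` (sample x sample), `cophenetic`, `consensus_clusters`,
#'   `objective_trace` (best restart, if traced).
#' @export
fit_consensus_nmf <- function(m, k, restarts = 50L, seed = 1L,
                              max_iter = 2000L, tol = 1e-6,
                              trace_objective = FALSE) {
  if (any(m < 0)) stop("NMF input must be non-negative")
  if (k < 1) stop("k must be >= 1")
  if (k > min(dim(m))) stop("k exceeds min(genes, samples)")
  if (restarts < 1) stop("restarts must be >= 1")
  s <- ncol(m)
  co <- matrix(0, s, s)
  best <- NULL
  objectives <- numeric(restarts)
  assigns <- matrix(NA_integer_, restarts, s)
  for (r in seq_len(restarts)) {
    fit <- with_local_seed(derive_seed(seed, paste0("nmf_restart_", r)),
                           nmf_single(m, k, max_iter, tol,
                                      trace = trace_objective))
    if (!fit$converged)
      warning(sprintf("NMF restart %d did not converge in %d iterations",
                      r, max_iter))
    objectives[r] <- fit$objective
    a <- apply(fit$h, 2, which.max)
    assigns[r, ] <- a
    co <- co + outer(a, a, "==")
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  consensus <- co / restarts
  dimnames(consensus) <- list(colnames(m), colnames(m))
  assignment <- apply(best$h, 2, which.max)
  names(assignment) <- colnames(m)
  rownames(best$w) <- rownames(m)
  colnames(best$w) <- paste0("F", seq_len(k))
  rownames(best$h) <- paste0("F", seq_len(k))
  colnames(best$h) <- colnames(m)
  d <- stats::as.dist(1 - consensus)
  if (s > 2) {
    hc <- stats::hclust(d, method = "average")
    coph <- if (stats::sd(d) == 0) 1 else
      suppressWarnings(stats::cor(stats::cophenetic(hc), d))
    clusters <- stats::cutree(hc, k = min(k, s))
  } else {
    coph <- NA_real_
    clusters <- stats::setNames(seq_len(s), colnames(m))
  }
  structure(list(w = best$w, h = best$h, k = k, objectives = objectives,
                 assignment = assignment, consensus = consensus,
                 cophenetic = coph, consensus_clusters = clusters,
                 objective_trace = best$objective_trace),
            class = "nmf_result")
}

#' Rank exemplar genes for one NMF factor
#'
#' Scores each gene by the difference between its loading on factor `i` and
#' its largest loading on any other factor, and ranks genes in descending
#' order of that margin. Ties are broken by gene symbol (lexicographic) so
#' rankings are reproducible.
#'
#' @param nmf an `nmf_result` (or any list with a `w` loading matrix).
#' @param factor_i factor index (column of `W`).
#' @return data.frame with columns `gene`, `score`, ordered by decreasing
#'   score.
#' @export
rank_exemplar_genes <- function(nmf, factor_i) {
  w <- nmf$w
  if (ncol(w) < 2) stop("exemplar ranking requires k >= 2")
  if (factor_i < 1 || factor_i > ncol(w)) stop("invalid factor index")
  other <- w[, -factor_i, drop = FALSE]
  score <- w[, factor_i] - apply(other, 1, max)
  ord <- order(-score, rownames(w))
  data.frame(gene = rownames(w)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Select subtype marker genes by a feature permutation test
#'
#' Trains a one-vs-rest random forest on the exemplar-gene features and scores
#' each feature by its permutation importance (mean decrease in out-of-bag
#' accuracy when the feature's values are permuted). A null distribution per
#' feature is built by refitting the forest under `n_permutations` random
#' label permutations; `p = (1 + #null >= observed) / (1 + n_permutations)`,
#' Benjamini-Hochberg adjusted across features. Markers are features with
#' adjusted p below `alpha`.
#'
#' @param m_log log2-scale expression matrix (genes x samples).
#' @param assignment named vector of subtype labels per sample.
#' @param subtype the subtype to contrast against the rest.
#' @param exemplars candidate feature genes (the factor's exemplar list).
#' @param n_permutations label-permutation rounds (default 100).
#' @param seed integer seed.
#' @param n_trees trees per forest (default 500).
#' @param alpha adjusted-p marker cutoff (default 0.05).
#' @return data.frame with columns `gene`, `importance`, `p`, `q`,
#'   `selected`, ordered by decreasing importance.
#' @export
select_markers <- function(m_log, assignment, subtype, exemplars,
                           n_permutations = 100L, seed = 1L,
                           n_trees = 500L, alpha = 0.05) {
  exemplars <- intersect(exemplars, rownames(m_log))
  if (length(exemplars) < 1) stop("no exemplar genes present in matrix")
  assignment <- assignment[colnames(m_log)]
  y <- factor(ifelse(assignment == subtype, "in", "out"),
              levels = c("in", "out"))
  if (sum(y == "in") < 2 || sum(y == "out") < 2)
    stop("need >= 2 samples inside and outside the subtype")
  x <- t(m_log[exemplars, , drop = FALSE])
  imp_of <- function(labels) {
    fit <- randomForest::randomForest(x, labels, ntree = n_trees,
                                      importance = TRUE)
    randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  }
  with_local_seed(derive_seed(seed, paste0("select_markers_", subtype)), {
    observed <- imp_of(y)
    null_imp <- matrix(NA_real_, n_permutations, length(exemplars))
    for (b in seq_len(n_permutations))
      null_imp[b, ] <- imp_of(sample(y))
    p <- vapply(seq_along(exemplars), function(j) {
      (1 + sum(null_imp[, j] >= observed[j])) / (1 + n_permutations)
    }, numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    ord <- order(-observed, exemplars)
    data.frame(gene = exemplars[ord], importance = unname(observed[ord]),
               p = p[ord], q = q[ord], selected = q[ord] < alpha,
               stringsAsFactors = FALSE)
  })
}

#' Discover molecular subtypes from an expression cohort
#'
#' Convenience pipeline: gene filtering, log2 transform, consensus NMF,
#' exemplar ranking per factor, and permutation-tested marker selection per
#' subtype. Subtypes are named `F1..Fk` after their NMF factors.
#'
#' @param m linear-scale expression matrix (typically nodule samples only).
#' @param config a [default_run_config()] list.
#' @return list of class `subtype_model`: `filtered`, `nmf`, `assignment`,
#'   `exemplars` (list of data.frames per factor), `markers` (list of
#'   data.frames per subtype), `marker_sets` (selected genes per subtype).
#' @export
discover_subtypes <- function(m, config = default_run_config()) {
  fm <- filter_genes(m)
  if (nrow(fm$expr) < config$nmf_k)
    stop("too few genes retained for the requested NMF rank")
  m_log <- log2_transform(fm$expr, config$pseudocount)
  nmf <- fit_consensus_nmf(m_log, k = config$nmf_k,
                           restarts = config$nmf_restarts,
                           seed = derive_seed(config$seed, "consensus_nmf"),
                           max_iter = config$nmf_max_iter,
                           tol = config$nmf_tol)
  subtypes <- paste0("F", seq_len(config$nmf_k))
  assignment <- stats::setNames(subtypes[nmf$assignment],
                                names(nmf$assignment))
  exemplars <- lapply(seq_len(config$nmf_k), function(i) {
    ex <- rank_exemplar_genes(nmf, i)
    utils::head(ex, config$exemplar_n)
  })
  names(exemplars) <- subtypes
  markers <- lapply(subtypes, function(s) {
    if (sum(assignment == s) < 2 || sum(assignment != s) < 2)
      return(NULL)
    select_markers(m_log, assignment, s, exemplars[[s]]$gene,
                   n_permutations = config$marker_permutations,
                   seed = config$seed, n_trees = config$rf_trees,
                   alpha = config$marker_alpha)
  })
  names(markers) <- subtypes
  marker_sets <- lapply(markers, function(df) {
    if (is.null(df)) character(0) else df$gene[df$selected]
  })
  structure(list(filtered = fm, nmf = nmf, assignment = assignment,
                 exemplars = exemplars, markers = markers,
                 marker_sets = marker_sets, config = config),
            class = "subtype_model")
}

#' Nearest template prediction
#'
#' Classifies each sample of a new cohort into the subtype whose marker
#' template is nearest in cosine distance. Expression is log2-transformed and
#' standardized per gene using the new cohort's own means and sds (no
#' training-cohort statistics leak across platforms), restricted to the union
#' of marker genes. The template of subtype `s` is the indicator vector (+1
#' on `s`'s markers, 0 elsewhere on the union), unit-normalized; distance is
#' `1 - cosine`. Significance per sample: the fraction (add-one corrected) of
#' `n_permutations` random gene sets of the same size, drawn from all
#' measured genes, whose template lies at least as close; Benjamini-Hochberg
#' adjusted across samples.
#'
#' @param m linear-scale expression matrix of the new cohort.
#' @param marker_sets named list of marker gene vectors, one per subtype.
#' @param n_permutations random gene sets per sample (default 1000).
#' @param seed integer seed.
#' @param standardize standardize genes across the cohort (default TRUE; set
#'   FALSE when the input is already on a comparable standardized scale).
#' @param pseudocount log2 pseudocount.
#' @return data.frame of class `ntp_result`: `sample_id`, `subtype`,
#'   `distance`, `tied` (degenerate all-equal distances), `p`, `q`, plus one
#'   `dist_<subtype>` column per template.
#' @export
ntp_classify <- function(m, marker_sets, n_permutations = 1000L, seed = 1L,
                         standardize = TRUE, pseudocount = 1) {
  validate_expression_matrix(m)
  subtypes <- sort(names(marker_sets))
  present <- lapply(marker_sets[subtypes], intersect, y = rownames(m))
  dropped <- sum(lengths(marker_sets)) - sum(lengths(present))
  if (dropped > 0)
    message(sprintf("ntp_classify: %d marker gene(s) absent from cohort",
                    dropped))
  empty <- subtypes[lengths(present) == 0]
  if (length(empty))
    stop("all markers missing for subtype(s): ",
         paste(empty, collapse = ", "))
  z <- log2(m + pseudocount)
  if (standardize) {
    mu <- rowMeans(z)
    sdv <- apply(z, 1, stats::sd)
    sdv[sdv == 0] <- 1
    z <- (z - mu) / sdv
  }
  union_genes <- sort(unique(unlist(present)))
  zu <- z[union_genes, , drop = FALSE]
  norm_u <- sqrt(colSums(zu^2))
  norm_u[norm_u == 0] <- 1
  dist_mat <- sapply(subtypes, function(s) {
    mk <- present[[s]]
    cosv <- colSums(zu[mk, , drop = FALSE]) / (sqrt(length(mk)) * norm_u)
    1 - cosv
  })
  dist_mat <- matrix(dist_mat, nrow = ncol(m),
                     dimnames = list(colnames(m), subtypes))
  idx <- apply(dist_mat, 1, which.min)
  pred <- subtypes[idx]
  obs_d <- dist_mat[cbind(seq_len(nrow(dist_mat)), idx)]
  tied <- apply(dist_mat, 1, function(d) sum(d <= min(d) + 1e-12) > 1)

  all_genes <- rownames(z)
  p <- with_local_seed(derive_seed(seed, "ntp_classify"), {
    vapply(seq_len(ncol(m)), function(si) {
      msize <- length(present[[pred[si]]])
      null_d <- vapply(seq_len(n_permutations), function(b) {
        r <- sample(all_genes, msize)
        zr <- z[r, si]
        nr <- sqrt(sum(zr^2))
        if (nr == 0) 1 else 1 - sum(zr) / (sqrt(msize) * nr)
      }, numeric(1))
      (1 + sum(null_d <= obs_d[si])) / (1 + n_permutations)
    }, numeric(1))
  })
  out <- data.frame(sample_id = colnames(m), subtype = pred,
                    distance = obs_d, tied = tied, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  dcols <- as.data.frame(dist_mat)
  colnames(dcols) <- paste0("dist_", subtypes)
  out <- cbind(out, dcols)
  rownames(out) <- NULL
  class(out) <- c("ntp_result", "data.frame")
  out
}

#' Relabel predicted clusters to best match reference labels
#'
#' Cluster and subtype labels are arbitrary up to permutation; this maps each
#' predicted label to a reference label so that agreement is maximized
#' (exhaustive over permutations for up to 8 labels, greedy otherwise).
#'
#' @param pred vector of predicted labels.
#' @param truth vector of reference labels, same length.
#' @return `pred` re-expressed in reference labels.
#' @export
match_labels <- function(pred, truth) {
  pu <- sort(unique(as.character(pred)))
  tu <- sort(unique(as.character(truth)))
  tab <- table(factor(pred, pu), factor(truth, tu))
  if (length(pu) <= 8 && length(tu) <= 8 && length(pu) <= length(tu)) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    best <- NULL; best_score <- -1
    for (p in perms(seq_along(tu))) {
      p <- p[seq_along(pu)]
      score <- sum(tab[cbind(seq_along(pu), p)])
      if (score > best_score) { best_score <- score; best <- p }
    }
    mapping <- stats::setNames(tu[best], pu)
  } else {
    mapping <- stats::setNames(tu[apply(tab, 1, which.max)], pu)
  }
  unname(mapping[as.character(pred)])
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over `mclust::adjustedRandIndex`, used to quantify recovery
#' of planted subtype structure.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
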