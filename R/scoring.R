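# Per-sample scores: thyroid differentiation score (TDS), single-sample
# gene-set enrichment (immune / stromal / T-cell-inflamed GEP), and the
# group-comparison statistics used throughout the pipeline. All scores are
# deterministic given their inputs; no RNG is involved.

#' Thyroid differentiation score
#'
#' For each gene of the thyroid-function set, the log2(RPKM + pseudocount)
#' expression is centered by its median across samples; the per-sample TDS is
#' the sum of the centered values. High TDS marks well-differentiated,
#' iodine-handling thyroid tissue; loss of differentiation lowers it.
#'
#' @param m linear-scale expression matrix.
#' @param tds_genes character vector of thyroid-function genes (classically
#'   16 genes: TG, TPO, TSHR, the iodide transporters, ...).
#' @param pseudocount log2 pseudocount.
#' @return data.frame with `sample_id` and `TDS` columns.
#' @export
tds <- function(m, tds_genes, pseudocount = 1) {
  validate_expression_matrix(m)
  present <- intersect(tds_genes, rownames(m))
  if (length(present) == 0) stop("no TDS genes present in matrix")
  if (length(present) < length(tds_genes))
    message(sprintf("tds: %d gene(s) of the set absent from matrix",
                    length(tds_genes) - length(present)))
  lg <- log2(m[present, , drop = FALSE] + pseudocount)
  med <- apply(lg, 1, stats::median)
  centered <- lg - med
  data.frame(sample_id = colnames(m), TDS = colSums(centered),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based single-sample enrichment: per sample, genes are ranked by
#' expression (ties by gene symbol for determinism) and the score is the
#' normalized accumulated difference between the rank-weighted empirical CDF
#' of in-set genes (weights `rank^tau`) and the uniform CDF of out-of-set
#' genes, walked from the most to the least expressed gene and divided by the
#' number of genes. Positive scores mean set members concentrate at high
#' expression. At `tau = 0` the score depends on ranks only, so it is
#' invariant under any strictly monotone transform of a sample's values and
#' exactly changes sign when a sample's ranking is reversed.
#'
#' @param m linear-scale expression matrix.
#' @param gene_set character vector of gene symbols.
#' @param tau rank-weight exponent (default 0.25).
#' @param pseudocount log2 pseudocount (monotone; affects only tau > 0
#'   weighting through ranks, i.e. not at all -- kept for interface symmetry).
#' @return data.frame with `sample_id` and `score` columns.
#' @export
ssgsea_score <- function(m, gene_set, tau = 0.25, pseudocount = 1) {
  validate_expression_matrix(m)
  genes <- rownames(m)
  inset <- genes %in% gene_set
  if (!any(inset)) stop("gene set has empty overlap with measured genes")
  n <- length(genes)
  n_in <- sum(inset)
  if (n_in == n) stop("gene set covers every measured gene")
  score <- vapply(seq_len(ncol(m)), function(s) {
    v <- m[, s]
    r <- rank(v, ties.method = "average")
    ord <- order(-v, genes)
    hit <- inset[ord]
    w <- r[ord]^tau
    w[!hit] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / (n - n_in)
    sum(p_in - p_out) / n
  }, numeric(1))
  data.frame(sample_id = colnames(m), score = score, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Immune, stromal and T-cell-inflamed GEP scores
#'
#' Applies [ssgsea_score()] to the `immune`, `stromal` and `GEP` sets of a
#' gene-set collection. Orientation invariant: a higher immune score
#' corresponds to more active immunological effects (set members more highly
#' expressed).
#'
#' @param m linear-scale expression matrix.
#' @param collection named list of gene sets; must contain `immune`,
#'   `stromal` and `GEP` entries (see the GMT shipped under
#'   `inst/extdata/default_gene_sets.gmt` for editable defaults).
#' @param tau rank-weight exponent.
#' @return data.frame with `sample_id`, `immune`, `stromal`, `GEP` columns.
#' @export
immune_stromal_gep_scores <- function(m, collection, tau = 0.25) {
  need <- c("immune", "stromal", "GEP")
  for (nm in need) {
    if (is.null(collection[[nm]]) || length(collection[[nm]]) == 0)
      stop(sprintf("gene-set collection is missing a non-empty '%s' set", nm))
    if (!any(rownames(m) %in% collection[[nm]]))
      stop(sprintf("set '%s' has empty overlap with measured genes", nm))
  }
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  for (nm in need)
    out[[nm]] <- ssgsea_score(m, collection[[nm]], tau = tau)$score
  out
}

#' Score every set of a collection
#'
#' @param m linear-scale expression matrix.
#' @param collection named list of gene sets.
#' @param tau rank-weight exponent.
#' @return data.frame with `sample_id` plus one column per set.
#' @export
score_gene_sets <- function(m, collection, tau = 0.25) {
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  for (nm in names(collection))
    out[[nm]] <- ssgsea_score(m, collection[[nm]], tau = tau)$score
  out
}

#' Two-group / contingency comparisons
#'
#' `wilcoxon`: two-sided Wilcoxon rank-sum on `values` split by the two-level
#' `groups` (the reported statistic is the rank sum of the first group);
#' exact enumeration when both groups have at most 10 untied observations,
#' otherwise the normal approximation with tie correction.
#' `chi_square`: Pearson chi-square independence test (no continuity
#' correction) on a contingency table passed as `values`, with
#' `df = (r - 1)(c - 1)`.
#'
#' @param values numeric vector (wilcoxon) or contingency matrix/table
#'   (chi_square).
#' @param groups two-level factor/vector for wilcoxon; ignored for chi_square.
#' @param test `"wilcoxon"` or `"chi_square"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values, groups = NULL, test = c("wilcoxon",
                                                           "chi_square")) {
  test <- match.arg(test)
  if (test == "wilcoxon") {
    g <- factor(groups)
    if (nlevels(g) != 2) stop("wilcoxon needs exactly two groups")
    x <- values[g == levels(g)[1]]
    y <- values[g == levels(g)[2]]
    if (length(x) == 0 || length(y) == 0) stop("empty group")
    ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- !ties && length(x) <= 10 && length(y) <= 10
    ht <- stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
    rank_sum <- sum(rank(c(x, y))[seq_along(x)])
    list(statistic = rank_sum, p_value = ht$p.value, method = "wilcoxon")
  } else {
    tab <- as.matrix(values)
    if (any(dim(tab) < 2)) stop("contingency table needs >= 2 rows and cols")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "chi_square")
  }
}
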