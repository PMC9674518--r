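# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions and kept free of any package internals.

# exemplar score: margin of a gene's loading on factor i over its best other
# factor, ranked descending, ties by gene name
oracle_exemplar <- function(w, i) {
  scores <- vapply(seq_len(nrow(w)), function(g) {
    w[g, i] - max(w[g, -i])
  }, numeric(1))
  names(scores) <- rownames(w)
  df <- data.frame(gene = rownames(w), score = unname(scores),
                   stringsAsFactors = FALSE)
  df[order(-df$score, df$gene), , drop = FALSE]
}

# MCC by exhaustive subset enumeration (graphs up to ~12 nodes): a subset is
# a clique if all pairs are adjacent, maximal if no vertex extends it
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  mcc <- stats::setNames(numeric(n), rownames(adj))
  for (size in 2:n) {
    for (subset in utils::combn(n, size, simplify = FALSE)) {
      pairs <- utils::combn(subset, 2)
      is_clique <- all(adj[t(pairs)] == 1)
      if (!is_clique) next
      extendable <- any(vapply(setdiff(seq_len(n), subset), function(v) {
        all(adj[v, subset] == 1)
      }, logical(1)))
      if (!extendable)
        mcc[subset] <- mcc[subset] + factorial(size - 1)
    }
  }
  mcc
}

# classic GSEA running-sum ES: direct accumulation over the sorted list
oracle_gsea_es <- function(scores, set, p = 1) {
  ord <- order(-scores, names(scores))
  sc <- scores[ord]
  hit <- names(sc) %in% set
  n <- length(sc)
  nh <- sum(hit)
  denom_hit <- sum(abs(sc[hit])^p)
  run <- 0
  best <- 0
  for (j in seq_len(n)) {
    run <- run + if (hit[j]) {
      if (denom_hit > 0) abs(sc[j])^p / denom_hit else 1 / nh
    } else {
      -1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# single-sample enrichment: direct accumulation of the weighted in-set ECDF
# minus the out-of-set ECDF, normalized by gene count
oracle_ssgsea <- function(values, set, tau) {
  genes <- names(values)
  r <- rank(values, ties.method = "average")
  ord <- order(-values, genes)
  run_in <- 0
  run_out <- 0
  total <- 0
  w_all <- sum(r[ord][genes[ord] %in% set]^tau)
  n_out <- sum(!(genes %in% set))
  for (g in ord) {
    if (genes[g] %in% set) run_in <- run_in + r[g]^tau / w_all
    else run_out <- run_out + 1 / n_out
    total <- total + (run_in - run_out)
  }
  unname(total / length(values))
}

# exact two-sided Wilcoxon rank-sum p by enumeration of group assignments
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- sum(rank(pooled)[seq_len(n1)])
  all_stats <- apply(utils::combn(length(pooled), n1), 2, function(ix) {
    sum(rank(pooled)[ix])
  })
  mu <- mean(all_stats)
  mean(abs(all_stats - mu) >= abs(obs - mu) - 1e-9)
}

# small deterministic expression matrix
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples))
}
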