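# Hub-gene network analysis: mutual-information co-expression edges seeded on
# subtype markers, data-processing-inequality pruning of indirect edges,
# maximal clique centrality hub ranking, pre-ranked GSEA, and the
# hub-to-pathway bipartite graph.

equal_freq_bins <- function(x, bins) {
  n <- length(x)
  if (length(unique(x)) == 1) return(rep(1L, n))
  ceiling(rank(x, ties.method = "first") * bins / n)
}

#' Mutual information between two expression vectors
#'
#' Plug-in estimator on an equal-frequency discretization: each variable is
#' binned into `bins` equal-count bins and
#' `MI = sum p(a,b) log(p(a,b) / (p(a) p(b)))` in nats. Non-negative and
#' symmetric; a constant vector collapses to a single bin and yields MI = 0
#' with a warning. For identical vectors the estimator approaches `log(bins)`
#' as n grows.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @param bins number of bins; default `ceiling(sqrt(n))` capped at 10.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8) stop("need at least 8 observations")
  if (is.null(bins) || is.na(bins)) bins <- min(10L, ceiling(sqrt(n)))
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: MI = 0")
    return(0)
  }
  bx <- equal_freq_bins(x, bins)
  by <- equal_freq_bins(y, bins)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Build a mutual-information network with DPI pruning
#'
#' ARACNe-style inference: subtype marker genes act as hubs; MI is computed
#' between every hub and every other measured gene, and among the genes
#' retained as neighbors of at least one hub. Edges with MI below
#' `mi_threshold` are dropped; when no threshold is given it is taken as the
#' Bonferroni-adjusted `(1 - alpha / n_pairs)` quantile of a pooled
#' permutation null (MI between independently permuted vectors). The data
#' processing inequality then removes, from every triangle, the weakest edge
#' whose MI falls below `(1 - tolerance)` times the smaller of the other two
#' (tolerance 0 is the classic rule; tolerance 1 disables pruning). Triangles
#' are examined against the pre-pruning MI values in deterministic sorted
#' order and marked edges are removed together.
#'
#' @param m_log log2-scale expression matrix (genes x samples).
#' @param hubs character vector of hub genes (must be measured).
#' @param dpi_tolerance DPI tolerance in `[0, 1]` (default 0).
#' @param mi_threshold fixed MI cutoff in nats, or NULL for the permutation
#'   null.
#' @param bins MI discretization bins (NULL for the default rule).
#' @param n_null permutation-null draws when `mi_threshold` is NULL.
#' @param alpha family-wise error rate for the permutation threshold.
#' @param seed integer seed (used only for the permutation null).
#' @return list of class `mi_network`: `edges` (data.frame `gene_a`,
#'   `gene_b`, `mi`, `dpi_kept`), `nodes` (data.frame `gene`, `is_hub`),
#'   `mi_threshold`.
#' @export
build_aracne_network <- function(m_log, hubs, dpi_tolerance = 0,
                                 mi_threshold = NULL, bins = NULL,
                                 n_null = 100L, alpha = 0.05, seed = 1L) {
  if (!all(hubs %in% rownames(m_log)))
    stop("hub gene(s) absent from matrix: ",
         paste(setdiff(hubs, rownames(m_log)), collapse = ", "))
  if (dpi_tolerance < 0 || dpi_tolerance > 1)
    stop("dpi_tolerance must lie in [0, 1]")
  genes <- rownames(m_log)
  hubs <- sort(unique(hubs))
  others <- setdiff(genes, hubs)

  pair_mi <- function(a, b) mutual_information(m_log[a, ], m_log[b, ], bins)

  # hub-vs-all edges
  pairs <- rbind(
    if (length(hubs) > 1) t(utils::combn(hubs, 2)) else NULL,
    as.matrix(expand.grid(gene_a = hubs, gene_b = others,
                          stringsAsFactors = FALSE)))
  colnames(pairs) <- c("gene_a", "gene_b")
  mi1 <- apply(pairs, 1, function(p) pair_mi(p[1], p[2]))

  if (is.null(mi_threshold)) {
    null_mi <- with_local_seed(derive_seed(seed, "aracne_null"), {
      vapply(seq_len(n_null), function(b) {
        i <- sample(genes, 1); j <- sample(genes, 1)
        mutual_information(sample(m_log[i, ]), m_log[j, ], bins)
      }, numeric(1))
    })
    n_pairs <- nrow(pairs)
    mi_threshold <- stats::quantile(null_mi, 1 - min(1, alpha / n_pairs),
                                    names = FALSE, type = 7)
  }
  keep1 <- mi1 >= mi_threshold
  edges <- data.frame(gene_a = pairs[keep1, 1], gene_b = pairs[keep1, 2],
                      mi = mi1[keep1], stringsAsFactors = FALSE)

  # among retained non-hub neighbors
  nbrs <- sort(setdiff(unique(c(edges$gene_a, edges$gene_b)), hubs))
  if (length(nbrs) > 1) {
    np <- t(utils::combn(nbrs, 2))
    mi2 <- apply(np, 1, function(p) pair_mi(p[1], p[2]))
    keep2 <- mi2 >= mi_threshold
    edges <- rbind(edges,
                   data.frame(gene_a = np[keep2, 1], gene_b = np[keep2, 2],
                              mi = mi2[keep2], stringsAsFactors = FALSE))
  }
  if (nrow(edges) == 0) {
    warning("no edge survives the MI threshold: empty network")
    return(structure(list(edges = edges, nodes = data.frame(
      gene = character(0), is_hub = logical(0)),
      mi_threshold = mi_threshold), class = "mi_network"))
  }
  # canonical undirected representation, deterministic order
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(edges) <- NULL

  # DPI on triangles of the thresholded graph
  mi_of <- stats::setNames(edges$mi, paste(edges$gene_a, edges$gene_b))
  adj <- split(c(edges$gene_b, edges$gene_a),
               c(edges$gene_a, edges$gene_b))
  key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  remove <- character(0)
  nodes_sorted <- sort(names(adj))
  for (i in nodes_sorted) {
    for (j in sort(adj[[i]])) {
      if (j <= i) next
      ks <- sort(intersect(adj[[i]], adj[[j]]))
      for (k in ks) {
        if (k <= j) next
        e <- c(key(i, j), key(i, k), key(j, k))
        v <- mi_of[e]
        wmin <- which.min(v)
        if (v[wmin] < (1 - dpi_tolerance) * min(v[-wmin]))
          remove <- c(remove, e[wmin])
      }
    }
  }
  edges$dpi_kept <- !(paste(edges$gene_a, edges$gene_b) %in% remove)
  node_names <- sort(unique(c(edges$gene_a, edges$gene_b, hubs)))
  nodes <- data.frame(gene = node_names, is_hub = node_names %in% hubs,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, mi_threshold = mi_threshold),
            class = "mi_network")
}

#' Maximal clique centrality
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`. Maximal
#' cliques are enumerated exactly (Bron-Kerbosch with pivoting, via igraph).
#' An isolated node scores 0; a node whose only maximal cliques are single
#' edges scores its degree.
#'
#' @param net an `mi_network` (DPI-surviving edges are used) or an igraph
#'   undirected graph.
#' @return named numeric vector of MCC scores, one per node.
#' @export
mcc_scores <- function(net) {
  if (inherits(net, "mi_network")) {
    kept <- net$edges[net$edges$dpi_kept, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      kept[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = net$nodes$gene)
  } else {
    g <- net
  }
  g <- igraph::simplify(g)
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  mcc <- stats::setNames(numeric(length(vn)), vn)
  if (igraph::ecount(g) > 0) {
    cliques <- igraph::max_cliques(g, min = 2)
    for (cl in cliques) {
      members <- vn[as.integer(cl)]
      mcc[members] <- mcc[members] + factorial(length(members) - 1)
    }
  }
  mcc
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov GSEA on a pre-ranked gene list: genes
#' sorted by decreasing score; a running sum gains
#' `|score|^p / sum_in |score|^p` at set members and loses `1/(N - |S|)`
#' elsewhere; ES is the maximal-magnitude deviation. The null distribution
#' comes from `n_permutations` random gene-label permutations; NES divides ES
#' by the mean magnitude of same-sign null ES values; the p-value is the
#' matching-sign null tail (add-one corrected) and q is Benjamini-Hochberg
#' within each sign family.
#'
#' @param scores named numeric vector (gene-level ranking scores, e.g. log2
#'   fold-changes); no duplicate names.
#' @param pathway_sets named list of gene sets.
#' @param n_permutations null permutations (default 1000).
#' @param seed integer seed.
#' @param p_weight score-weight exponent (default 1; 0 gives the unweighted
#'   KS statistic).
#' @return data.frame with `pathway`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-joined genes).
#' @export
gsea_preranked <- function(scores, pathway_sets, n_permutations = 1000L,
                           seed = 1L, p_weight = 1) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene")
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  genes <- names(scores)
  n <- length(genes)

  es_stat <- function(hit, sc) {
    n_in <- sum(hit)
    if (n_in == 0 || n_in == n) return(list(es = NA_real_, at = NA_integer_))
    w <- abs(sc)^p_weight
    w[!hit] <- 0
    sw <- sum(w)
    inc <- if (sw > 0) w / sw else as.numeric(hit) / n_in
    dec <- as.numeric(!hit) / (n - n_in)
    run <- cumsum(inc - dec)
    at <- which.max(abs(run))
    list(es = run[at], at = at)
  }

  keep <- vapply(pathway_sets, function(s) any(genes %in% s), logical(1))
  if (any(!keep))
    warning("pathway set(s) with no overlap skipped: ",
            paste(names(pathway_sets)[!keep], collapse = ", "))
  pathway_sets <- pathway_sets[keep]
  if (length(pathway_sets) == 0)
    return(data.frame(pathway = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      q = numeric(0), leading_edge = character(0),
                      stringsAsFactors = FALSE))

  res <- lapply(names(pathway_sets), function(nm) {
    hit <- genes %in% pathway_sets[[nm]]
    ob <- es_stat(hit, scores)
    null_es <- with_local_seed(derive_seed(seed, paste0("gsea_", nm)), {
      vapply(seq_len(n_permutations), function(b) {
        es_stat(sample(hit), scores)$es
      }, numeric(1))
    })
    same <- null_es[sign(null_es) == sign(ob$es)]
    nes <- if (length(same)) ob$es / mean(abs(same)) else NA_real_
    p <- if (length(same))
      (1 + sum(abs(same) >= abs(ob$es))) / (1 + length(same)) else 1
    le <- if (ob$es >= 0) genes[seq_len(ob$at)][hit[seq_len(ob$at)]]
      else genes[ob$at:n][hit[ob$at:n]]
    data.frame(pathway = nm, size = sum(hit), es = ob$es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (sgn in c(-1, 1)) {
    ix <- which(sign(out$es) == sgn)
    if (length(ix)) out$q[ix] <- stats::p.adjust(out$p[ix], method = "BH")
  }
  out[, c("pathway", "size", "es", "nes", "p", "q", "leading_edge")]
}

#' Hub-to-pathway bipartite graph
#'
#' Takes the `top_n` hubs by MCC, extracts each hub's first-layer neighbors
#' from the DPI-pruned network, ranks the neighbors by log2 fold-change of
#' the focal subtype versus all other samples, runs pre-ranked GSEA over the
#' pathway sets, and connects the hub to each enriched pathway with the
#' pathway's normalized enrichment score as edge weight. Pathway nodes carry
#' the average NES over contributing hubs and an up/down flag.
#'
#' @param net an `mi_network`.
#' @param m_log log2-scale expression matrix.
#' @param assignment named subtype labels per sample (covering `colnames`).
#' @param focal_subtype the subtype whose fold-changes rank the neighbors.
#' @param pathway_sets named list of gene sets.
#' @param top_n hubs to keep by MCC rank (default 10).
#' @param n_permutations,seed GSEA permutation control.
#' @return list of class `hub_pathway_graph`: `hubs` (data.frame `gene`,
#'   `mcc`), `pathways` (data.frame `pathway`, `avg_nes`, `direction`),
#'   `edges` (data.frame `hub`, `pathway`, `nes`, `p`, `q`).
#' @export
hub_pathway_graph <- function(net, m_log, assignment, focal_subtype,
                              pathway_sets, top_n = 10L,
                              n_permutations = 1000L, seed = 1L) {
  mcc <- mcc_scores(net)
  hub_pool <- net$nodes$gene[net$nodes$is_hub]
  mcc_h <- sort(mcc[hub_pool], decreasing = TRUE)
  top <- names(utils::head(mcc_h, top_n))
  assignment <- assignment[colnames(m_log)]
  in_s <- assignment == focal_subtype
  if (!any(in_s) || all(in_s)) stop("focal subtype must split the samples")
  kept <- net$edges[net$edges$dpi_kept, , drop = FALSE]
  edge_rows <- list()
  used_hubs <- character(0)
  for (h in top) {
    nb <- sort(setdiff(unique(c(kept$gene_b[kept$gene_a == h],
                                kept$gene_a[kept$gene_b == h])), h))
    nb <- intersect(nb, rownames(m_log))
    if (length(nb) < 2) {
      message(sprintf("hub %s has fewer than 2 measured neighbors; excluded",
                      h))
      next
    }
    lfc <- rowMeans(m_log[nb, in_s, drop = FALSE]) -
      rowMeans(m_log[nb, !in_s, drop = FALSE])
    enr <- gsea_preranked(lfc, pathway_sets,
                          n_permutations = n_permutations,
                          seed = derive_seed(seed, paste0("hub_", h)))
    if (nrow(enr)) {
      enr$hub <- h
      edge_rows[[h]] <- enr
      used_hubs <- c(used_hubs, h)
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(hub = character(0), pathway = character(0), nes = numeric(0),
               p = numeric(0), q = numeric(0))
  rownames(edges) <- NULL
  pathways <- if (nrow(edges)) {
    agg <- stats::aggregate(nes ~ pathway, data = edges, FUN = mean)
    data.frame(pathway = agg$pathway, avg_nes = agg$nes,
               direction = ifelse(agg$nes >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pathway = character(0), avg_nes = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    hubs = data.frame(gene = used_hubs, mcc = unname(mcc[used_hubs]),
                      stringsAsFactors = FALSE),
    pathways = pathways,
    edges = if (nrow(edges))
      edges[, c("hub", "pathway", "nes", "p", "q")] else edges),
    class = "hub_pathway_graph")
}
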