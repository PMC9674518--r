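# Pseudotemporal trajectory: samples are embedded by PCA, summarized by
# k-means centroids joined into a minimum spanning tree, and projected onto
# the tree; pseudotime is geodesic distance from the root (the centroid
# nearest the benign-adjacent samples). Branch-dependent expression is tested
# by a Gaussian spline likelihood-ratio (BEAM-style) model.

#' Fit a branching pseudotemporal trajectory
#'
#' Pipeline: (i) reduce samples to `n_pcs` principal components; (ii) k-means
#' into `n_centroids` centroids (default `ceiling(n / 10)`, seeded); (iii)
#' Euclidean minimum spanning tree over centroids; (iv) project every sample
#' onto its nearest tree edge, pseudotime = geodesic distance along the tree
#' from the root node (the centroid nearest the mean of the root samples);
#' (v) branch labels from the first tree node of degree >= 3 past the root:
#' samples on the root side are `pre`, the two largest subtrees beyond it are
#' `fate1` and `fate2` (further subtrees, if any, are merged into the nearest
#' fate with a warning). If the tree has no branch node, all samples beyond
#' the root centroid are `fate1`.
#'
#' @param m_log log2-scale expression matrix (variable genes x samples).
#' @param root_samples character vector of starting-state sample ids (the
#'   benign-adjacent tissue).
#' @param seed integer seed (k-means initialization).
#' @param n_centroids number of backbone centroids (NULL for the default).
#' @param n_pcs embedding dimensionality (default 2).
#' @return list of class `trajectory_state`: `embedding` (samples x PCs),
#'   `pseudotime`, `branch` (named vectors), `centroids`, `tree` (igraph),
#'   `root_node`, `branch_node`, `centroid_assignment`.
#' @export
fit_trajectory <- function(m_log, root_samples, seed = 1L,
                           n_centroids = NULL, n_pcs = 2L) {
  n <- ncol(m_log)
  if (n < 10) stop("need at least 10 samples")
  if (!all(root_samples %in% colnames(m_log)))
    stop("root sample(s) absent from matrix")
  if (is.null(n_centroids) || is.na(n_centroids))
    n_centroids <- ceiling(n / 10)
  if (n_centroids < 2) stop("need at least 2 centroids")

  pca <- stats::prcomp(t(m_log), center = TRUE, scale. = FALSE)
  emb <- pca$x[, seq_len(min(n_pcs, ncol(pca$x))), drop = FALSE]

  km <- with_local_seed(derive_seed(seed, "trajectory_kmeans"),
                        stats::kmeans(emb, centers = n_centroids,
                                      nstart = 10, iter.max = 100))
  cen <- km$centers

  d_cen <- as.matrix(stats::dist(cen))
  g_full <- igraph::graph_from_adjacency_matrix(d_cen, mode = "undirected",
                                                weighted = TRUE)
  tree <- igraph::mst(g_full)

  root_mean <- colMeans(emb[root_samples, , drop = FALSE])
  root_node <- which.min(colSums((t(cen) - root_mean)^2))

  node_dist <- igraph::distances(tree, v = root_node)[1, ]

  # project samples onto tree edges; projections may extend past a leaf
  # endpoint so samples beyond the terminal centroids keep a strict ordering
  el <- igraph::as_edgelist(tree, names = FALSE)
  deg_all <- igraph::degree(tree)
  pt <- numeric(n)
  proj_edge <- integer(n)
  for (s in seq_len(n)) {
    p <- emb[s, ]
    best <- Inf
    for (e in seq_len(nrow(el))) {
      a <- cen[el[e, 1], ]; b <- cen[el[e, 2], ]
      ab <- b - a
      len2 <- sum(ab^2)
      t_lo <- if (deg_all[el[e, 1]] == 1) -Inf else 0
      t_hi <- if (deg_all[el[e, 2]] == 1) Inf else 1
      t_par <- if (len2 == 0) 0 else
        min(t_hi, max(t_lo, sum((p - a) * ab) / len2))
      q <- a + t_par * ab
      d2 <- sum((p - q)^2)
      if (d2 < best) {
        best <- d2
        proj_edge[s] <- e
        len <- sqrt(len2)
        # geodesic through the root-side endpoint of the edge
        pt[s] <- if (node_dist[el[e, 1]] <= node_dist[el[e, 2]])
          node_dist[el[e, 1]] + t_par * len
        else
          node_dist[el[e, 2]] + (1 - t_par) * len
      }
    }
  }
  pt <- pt - min(pt)
  names(pt) <- colnames(m_log)

  # branch labels from the first degree->=3 node past the root; a valid
  # bifurcation must split off at least two non-trivial subtrees (>= 2
  # centroids each) -- single-leaf noise twigs do not define a fate
  deg <- igraph::degree(tree)
  branch_candidates <- which(deg >= 3)
  branch_candidates <- branch_candidates[order(node_dist[branch_candidates])]
  branch_node <- NA_integer_
  for (cand in branch_candidates) {
    tc2 <- igraph::delete_vertices(tree, cand)
    cmp <- igraph::components(tc2)$membership
    rem <- setdiff(seq_len(n_centroids), cand)
    rcomp <- if (root_node == cand) -1 else cmp[[match(root_node, rem)]]
    away_sizes <- table(cmp[cmp != rcomp])
    if (sum(away_sizes >= 2) >= 2) {
      branch_node <- cand
      break
    }
  }
  # fall back to the nearest candidate when no split is non-trivial
  if (is.na(branch_node) && length(branch_candidates))
    branch_node <- branch_candidates[1]

  node_region <- rep("pre", n_centroids)
  if (!is.na(branch_node)) {
    t2 <- igraph::delete_vertices(tree, branch_node)
    comp <- igraph::components(t2)$membership
    # membership indexed over remaining vertices; map back
    remaining <- setdiff(seq_len(n_centroids), branch_node)
    comp_of <- stats::setNames(comp, remaining)
    root_comp <- comp_of[[as.character(
      if (root_node == branch_node) remaining[1] else root_node)]]
    fates <- setdiff(unique(comp), root_comp)
    sizes <- vapply(fates, function(cp) sum(comp == cp), numeric(1))
    fates <- fates[order(-sizes, fates)]
    if (length(fates) > 2)
      warning("more than two subtrees past the branch point; ",
              "extra subtrees merged into the nearest fate")
    lab_of_comp <- stats::setNames(rep(NA_character_, length(fates)),
                                   fates)
    if (length(fates) >= 1) lab_of_comp[as.character(fates[1])] <- "fate1"
    if (length(fates) >= 2) lab_of_comp[as.character(fates[2])] <- "fate2"
    if (length(fates) > 2) {
      main_nodes <- lapply(fates[1:2], function(cp)
        as.integer(names(comp_of)[comp_of == cp]))
      for (cp in fates[-(1:2)]) {
        extra_nodes <- as.integer(names(comp_of)[comp_of == cp])
        dmin <- vapply(1:2, function(fi)
          min(d_cen[extra_nodes, main_nodes[[fi]]]), numeric(1))
        lab_of_comp[as.character(cp)] <- c("fate1", "fate2")[which.min(dmin)]
      }
    }
    for (v in remaining) {
      cp <- comp_of[[as.character(v)]]
      node_region[v] <- if (cp == root_comp) "pre" else
        lab_of_comp[[as.character(cp)]]
    }
    node_region[branch_node] <- "pre"
  } else {
    warning("tree has no branch point; all non-root samples labelled fate1")
    node_region[-root_node] <- "fate1"
  }
  branch <- node_region[km$cluster]
  names(branch) <- colnames(m_log)

  structure(list(embedding = emb, pseudotime = pt, branch = branch,
                 centroids = cen, tree = tree,
                 root_node = root_node, branch_node = branch_node,
                 centroid_assignment = stats::setNames(km$cluster,
                                                       colnames(m_log))),
            class = "trajectory_state")
}

beam_design <- function(traj, spline_df) {
  t <- traj$pseudotime
  basis <- splines::ns(t, df = spline_df)
  x0 <- cbind(1, basis)
  alt_ind <- as.numeric(traj$branch == "fate2")
  x1 <- cbind(x0, alt_ind, basis * alt_ind)
  list(x0 = x0, x1 = x1, added_df = spline_df + 1)
}

#' Branched expression analysis (BEAM-style) test for one gene
#'
#' Gaussian likelihood-ratio test on log2 expression: the null model is a
#' natural cubic spline in pseudotime (df = `spline_df`) shared by both
#' fates; the alternative adds branch-specific spline coefficients for the
#' fate-2 samples. `LR = n log(RSS0 / RSS1)` is referred to a chi-square with
#' the added parameter count. A constant gene yields statistic 0 and p = 1.
#'
#' @param m_log log2-scale expression matrix.
#' @param traj a fitted `trajectory_state` with two fates.
#' @param gene gene symbol.
#' @param spline_df natural-spline degrees of freedom (default 3).
#' @param design precomputed [beam_design] matrices (internal reuse).
#' @return one-row data.frame: `gene`, `lr`, `df`, `p`.
#' @export
beam_test <- function(m_log, traj, gene, spline_df = 3L, design = NULL) {
  if (!gene %in% rownames(m_log)) stop("gene not in matrix")
  if (!any(traj$branch == "fate2"))
    stop("BEAM requires a fitted two-fate trajectory")
  if (is.null(design)) design <- beam_design(traj, spline_df)
  y <- m_log[gene, names(traj$pseudotime)]
  n <- length(y)
  if (stats::sd(y) == 0)
    return(data.frame(gene = gene, lr = 0, df = design$added_df, p = 1,
                      stringsAsFactors = FALSE))
  rss0 <- sum(stats::lm.fit(design$x0, y)$residuals^2)
  rss1 <- sum(stats::lm.fit(design$x1, y)$residuals^2)
  eps <- .Machine$double.eps
  lr <- max(0, n * log(max(rss0, eps) / max(rss1, eps)))
  p <- stats::pchisq(lr, df = design$added_df, lower.tail = FALSE)
  data.frame(gene = gene, lr = lr, df = design$added_df, p = p,
             stringsAsFactors = FALSE)
}

#' Branch-dependent differential expression over all genes
#'
#' Runs [beam_test()] for every requested gene and adds a Benjamini-Hochberg
#' q-value.
#'
#' @param m_log log2-scale expression matrix.
#' @param traj fitted `trajectory_state`.
#' @param genes genes to test (default: all rows).
#' @param spline_df natural-spline degrees of freedom.
#' @return data.frame `gene`, `lr`, `df`, `p`, `q`.
#' @export
beam_branch_de <- function(m_log, traj, genes = rownames(m_log),
                           spline_df = 3L) {
  design <- beam_design(traj, spline_df)
  res <- do.call(rbind, lapply(genes, function(g)
    beam_test(m_log, traj, g, spline_df, design)))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

smoothed_curves <- function(m_log, traj, genes, n_bins = 10) {
  t <- traj$pseudotime
  br <- traj$branch
  tmax <- max(t)
  bins <- pmin(n_bins, pmax(1, ceiling(t / tmax * n_bins)))
  curve_on <- function(g, mask) {
    y <- m_log[g, names(t)]
    vapply(seq_len(n_bins), function(b) {
      sel <- mask & bins == b
      if (any(sel)) mean(y[sel]) else NA_real_
    }, numeric(1))
  }
  lapply(stats::setNames(genes, genes), function(g) {
    list(fate1 = curve_on(g, br %in% c("pre", "fate1")),
         fate2 = curve_on(g, br %in% c("pre", "fate2")))
  })
}

#' Assign branch-dependent genes to fate-pattern clusters
#'
#' Clusters significant branch-DE genes into the three canonical patterns:
#' cluster I declines along pseudotime on both fates, cluster II activates at
#' the branch point on fate 1 only, cluster III on fate 2 only. Each gene's
#' binned mean curves per fate are compared between the pre-branch start and
#' each fate's end; a gene whose contrasts clear `margin` (log2 units) is
#' assigned directly, otherwise it is flagged ambiguous and assigned by a
#' seeded k-means (k = 3) over standardized curves whose cluster centroids
#' are labelled by the same margin-0 rule.
#'
#' @param results a [beam_branch_de()] table.
#' @param m_log log2-scale expression matrix.
#' @param traj fitted `trajectory_state`.
#' @param q_cutoff FDR cutoff selecting significant genes (default 0.05).
#' @param margin log2 contrast required for a confident pattern call.
#' @param seed integer seed for the fallback k-means.
#' @return data.frame `gene`, `cluster` in {I, II, III}, `ambiguous`.
#' @export
cluster_branch_genes <- function(results, m_log, traj, q_cutoff = 0.05,
                                 margin = 0.5, seed = 1L) {
  sig <- results$gene[results$q < q_cutoff]
  if (length(sig) < 3) {
    warning("fewer than 3 significant genes; clustering skipped")
    return(data.frame(gene = character(0), cluster = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  curves <- smoothed_curves(m_log, traj, sig)
  contrasts <- t(vapply(sig, function(g) {
    c1 <- curves[[g]]$fate1; c2 <- curves[[g]]$fate2
    start <- mean(c(c1[1:2], c2[1:2]), na.rm = TRUE)
    end1 <- mean(utils::tail(c1[!is.na(c1)], 2))
    end2 <- mean(utils::tail(c2[!is.na(c2)], 2))
    c(start = start, end1 = end1, end2 = end2)
  }, numeric(3)))
  rule <- function(start, end1, end2, m) {
    if (end1 < start - m && end2 < start - m) "I"
    else if (end1 > start + m && end1 > end2 + m) "II"
    else if (end2 > start + m && end2 > end1 + m) "III"
    else NA_character_
  }
  cl <- vapply(seq_along(sig), function(i)
    rule(contrasts[i, 1], contrasts[i, 2], contrasts[i, 3], margin),
    character(1))
  ambiguous <- is.na(cl)
  if (any(ambiguous)) {
    mat <- t(vapply(sig, function(g) {
      v <- c(curves[[g]]$fate1, curves[[g]]$fate2)
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    }, numeric(20)))
    km <- with_local_seed(derive_seed(seed, "branch_gene_kmeans"),
                          stats::kmeans(mat, centers = min(3, nrow(mat)),
                                        nstart = 10))
    cent_lab <- vapply(seq_len(nrow(km$centers)), function(ci) {
      member <- which(km$cluster == ci)
      ct <- colMeans(contrasts[member, , drop = FALSE])
      lab <- rule(ct[1], ct[2], ct[3], 0)
      if (is.na(lab)) "I" else lab
    }, character(1))
    fallback <- cent_lab[km$cluster]
    # per-gene margin-0 rule wins over a colliding centroid label
    for (i in which(ambiguous)) {
      lab0 <- rule(contrasts[i, 1], contrasts[i, 2], contrasts[i, 3], 0)
      cl[i] <- if (!is.na(lab0)) lab0 else fallback[i]
    }
  }
  data.frame(gene = sig, cluster = cl, ambiguous = ambiguous,
             row.names = NULL, stringsAsFactors = FALSE)
}
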