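test_that("mutual information is symmetric, non-negative and calibrated", {
  set.seed(31)
  x <- rnorm(500)
  y <- rnorm(500)
  expect_identical(mutual_information(x, y, 5), mutual_information(y, x, 5))
  expect_gte(mutual_information(x, y, 5), 0)
  # identical vectors on an exact equal-frequency grid reach log(B)
  z <- rnorm(2000)
  expect_equal(mutual_information(z, z, 5), log(5), tolerance = 1e-12)
  expect_warning(mi0 <- mutual_information(rep(1, 100), rnorm(100)),
                 "constant")
  expect_identical(mi0, 0)
  expect_error(mutual_information(1:5, 1:5), "at least 8")
})

test_that("data processing inequality holds on a simulated Markov chain", {
  set.seed(32)
  ok <- replicate(5, {
    x <- rnorm(2000)
    y <- x + rnorm(2000, 0, 0.6)
    z <- y + rnorm(2000, 0, 0.6)
    mxz <- mutual_information(x, z, 6)
    mxz <= min(mutual_information(x, y, 6),
               mutual_information(y, z, 6)) + 0.02
  })
  expect_true(all(ok))
})

test_that("DPI removes the weakest edge of planted chain triangles", {
  set.seed(33)
  x <- rnorm(2000)
  y <- x + rnorm(2000, 0, 0.5)
  z <- y + rnorm(2000, 0, 0.5)
  ml <- rbind(X = x, Y = y, Z = z)
  colnames(ml) <- paste0("s", 1:2000)
  net <- build_aracne_network(ml, hubs = c("X", "Y", "Z"),
                              dpi_tolerance = 0, mi_threshold = 0.01)
  kept <- net$edges[net$edges$dpi_kept, ]
  expect_setequal(paste(kept$gene_a, kept$gene_b), c("X Y", "Y Z"))
  # tolerance 1 disables pruning entirely
  net2 <- build_aracne_network(ml, hubs = c("X", "Y", "Z"),
                               dpi_tolerance = 1, mi_threshold = 0.01)
  expect_true(all(net2$edges$dpi_kept))
})

test_that("an empty network is returned with a warning when nothing passes", {
  set.seed(34)
  ml <- matrix(rnorm(3 * 100), 3, 100,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:100)))
  expect_warning(net <- build_aracne_network(ml, hubs = "A",
                                             mi_threshold = 10),
                 "empty network")
  expect_equal(nrow(net$edges), 0L)
  expect_error(build_aracne_network(ml, hubs = "NOPE"), "absent")
})

test_that("MCC matches hand-derived values on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(mcc_scores(tri)), rep(2, 3))
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  got <- mcc_scores(star)
  expect_equal(unname(got["c"]), 4)
  expect_equal(unname(got[paste0("l", 1:4)]), rep(1, 4))
  # isolated vertex scores zero
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("u", "v")
  expect_equal(unname(mcc_scores(iso)), c(0, 0))
})

test_that("MCC equals the exhaustive-subset oracle on random graphs", {
  set.seed(35)
  for (p in c(0.2, 0.5)) {
    for (rep in 1:12) {
      n <- sample(5:10, 1)
      adj <- matrix(0, n, n, dimnames = list(paste0("v", 1:n),
                                             paste0("v", 1:n)))
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        adj[i, j] <- adj[j, i] <- as.numeric(runif(1) < p)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(mcc_scores(g)[rownames(adj)], oracle_mcc(adj))
    }
  }
})

test_that("preranked GSEA ES matches the direct-accumulation oracle", {
  set.seed(36)
  genes <- sprintf("g%03d", 1:150)
  for (rep in 1:5) {
    scores <- stats::setNames(rnorm(150), genes)
    set <- sample(genes, 15)
    res <- gsea_preranked(scores, list(s = set), n_permutations = 50,
                          seed = 1)
    expect_equal(res$es, oracle_gsea_es(scores, set, 1), tolerance = 1e-12)
  }
  # a set at the very top of the ranking maximizes the running sum
  scores <- stats::setNames(sort(rnorm(150), decreasing = TRUE), genes)
  top <- genes[1:15]
  res <- gsea_preranked(scores, list(top = top), n_permutations = 200,
                        seed = 2)
  expect_equal(res$es, 1, tolerance = 1e-12)
  expect_gt(res$nes, 1)
  expect_lt(res$p, 0.05)
  expect_identical(res$leading_edge, paste(top, collapse = ","))
})

test_that("flat scores give null-like NES and reversal negates unweighted ES", {
  set.seed(37)
  genes <- sprintf("g%03d", 1:200)
  scores <- stats::setNames(rep(1, 200), genes)
  nes <- replicate(10, {
    gsea_preranked(scores, list(s = sample(genes, 20)),
                   n_permutations = 100, seed = sample.int(1000, 1),
                   p_weight = 0)$nes
  })
  expect_lt(abs(mean(abs(nes)) - 1), 0.25)

  sc <- stats::setNames(seq(10, 0.1, length.out = 100),
                        sprintf("g%03d", 1:100))
  set <- sprintf("g%03d", 1:10)
  es_fwd <- gsea_preranked(sc, list(s = set), n_permutations = 10,
                           seed = 1, p_weight = 0)$es
  es_rev <- gsea_preranked(stats::setNames(rev(unname(sc)), names(sc)),
                           list(s = set), n_permutations = 10,
                           seed = 1, p_weight = 0)$es
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
})

test_that("hub-pathway graph recovers a planted upregulated pathway", {
  set.seed(38)
  n <- 120
  assignment <- stats::setNames(rep(c("F1", "F2"), each = n / 2),
                                sprintf("s%03d", 1:n))
  hub <- rnorm(n, 5, 1)
  # 12 neighbors correlated with the hub; 6 of them form a pathway
  # upregulated in F1
  nb <- t(vapply(1:12, function(i) hub + rnorm(n, 0, 0.4), numeric(n)))
  nb[1:6, assignment == "F1"] <- nb[1:6, assignment == "F1"] + 2
  other <- matrix(rnorm(20 * n, 5, 1), 20, n)
  ml <- rbind(HUB = hub, nb, other)
  rownames(ml) <- c("HUB", sprintf("NB%02d", 1:12), sprintf("OT%02d", 1:20))
  colnames(ml) <- names(assignment)
  net <- build_aracne_network(ml, hubs = "HUB", mi_threshold = 0.15,
                              dpi_tolerance = 1)
  sets <- list(planted = sprintf("NB%02d", 1:6),
               decoy = sprintf("OT%02d", 1:6))
  hp <- hub_pathway_graph(net, ml, assignment, "F1", sets, top_n = 3,
                          n_permutations = 500, seed = 4)
  expect_true("HUB" %in% hp$hubs$gene)
  planted <- hp$edges[hp$edges$pathway == "planted", ]
  expect_gt(planted$nes[1], 0)
  expect_lt(planted$q[1], 0.05)
  # empty request gives an empty graph
  hp0 <- hub_pathway_graph(net, ml, assignment, "F1", sets, top_n = 0,
                           n_permutations = 10, seed = 4)
  expect_equal(nrow(hp0$edges), 0L)
})
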