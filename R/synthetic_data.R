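# Synthetic cohorts with planted ground truth. The generator emulates the
# structures the real cohort is claimed to carry: six latent expression
# programs (four malignant-like, two benign-like) with disjoint marker blocks,
# an immune-infiltration gradient, paired nodule/adjacent tissue, and a
# branching benign-to-malignant trajectory. Truth labels are returned
# separately from the expression matrix so pipeline inputs carry no leakage.

#' Simulation specification
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 6 subtypes (4 malignant `M1..M4`, 2 benign `B1..B2`) x 20 nodule
#' samples, 1000 genes, marker log2 effect 2.0, observation noise sd 0.5.
#'
#' @param n_genes total number of genes.
#' @param subtypes character vector of subtype names; names starting with "B"
#'   are treated as benign (BTN histology, low immune infiltration).
#' @param samples_per_subtype nodule samples per subtype (scalar or vector).
#' @param markers_per_subtype size of each subtype's disjoint marker block.
#' @param marker_effect log2 expression shift of a marker in its own subtype.
#' @param baseline_mean,baseline_sd log2-scale baseline distribution of
#'   per-gene means.
#' @param noise_sd log2-scale per-observation Gaussian noise.
#' @param immune_genes number of immune-gradient genes.
#' @param immune_amplitude log2 shift of an immune gene at immune level 1.
#' @param braf_fraction fraction of `braf_subtype` samples labelled BRAF-mutant.
#' @param braf_subtype subtype carrying the planted BRAF enrichment.
#' @param traj_n_samples,traj_branch_time,traj_genes_per_cluster,traj_effect,traj_noise_sd
#'   branching-trajectory parameters: sample count, bifurcation time on
#'   `[0,1]`, genes per expression program, program amplitude (log2), noise sd.
#' @param pseudocount pseudocount used when exporting to the linear scale.
#' @param seed master seed for the cohort.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 1000L,
                            subtypes = c("M1", "M2", "M3", "M4", "B1", "B2"),
                            samples_per_subtype = 20L,
                            markers_per_subtype = 30L,
                            marker_effect = 2.0,
                            baseline_mean = 3, baseline_sd = 1,
                            noise_sd = 0.5,
                            immune_genes = 50L,
                            immune_amplitude = 2.0,
                            braf_fraction = 0.6,
                            braf_subtype = "M1",
                            traj_n_samples = 200L,
                            traj_branch_time = 0.5,
                            traj_genes_per_cluster = 50L,
                            traj_effect = 2.0,
                            traj_noise_sd = 0.3,
                            pseudocount = 1,
                            seed = 7L) {
  if (length(samples_per_subtype) == 1)
    samples_per_subtype <- rep(as.integer(samples_per_subtype),
                               length(subtypes))
  if (length(samples_per_subtype) != length(subtypes))
    stop("samples_per_subtype must match subtypes")
  spec <- list(n_genes = as.integer(n_genes), subtypes = subtypes,
               samples_per_subtype = samples_per_subtype,
               markers_per_subtype = as.integer(markers_per_subtype),
               marker_effect = marker_effect,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               noise_sd = noise_sd,
               immune_genes = as.integer(immune_genes),
               immune_amplitude = immune_amplitude,
               braf_fraction = braf_fraction, braf_subtype = braf_subtype,
               traj_n_samples = as.integer(traj_n_samples),
               traj_branch_time = traj_branch_time,
               traj_genes_per_cluster = as.integer(traj_genes_per_cluster),
               traj_effect = traj_effect, traj_noise_sd = traj_noise_sd,
               pseudocount = pseudocount, seed = as.integer(seed))
  if (any(spec$samples_per_subtype <= 0) || spec$n_genes <= 0 ||
      spec$markers_per_subtype <= 0)
    stop("counts must be positive")
  if (spec$marker_effect < 0) stop("marker_effect must be >= 0")
  n_marker <- spec$markers_per_subtype * length(spec$subtypes)
  if (n_marker + spec$immune_genes > spec$n_genes)
    stop("marker and immune gene demand exceeds n_genes")
  structure(spec, class = "simulation_spec")
}

gene_names <- function(n) sprintf("g%04d", seq_len(n))

linear_scale <- function(log2m, pseudocount) {
  pmax(2^log2m - pseudocount, 0)
}

#' Simulate a subtyped nodule/adjacent cohort
#'
#' Log-space additive model: per-gene baseline ~ Normal(mean, sd); a nodule
#' sample's log2 value adds its subtype's marker shift (for genes in that
#' subtype's marker block), the immune amplitude scaled by the sample's latent
#' immune level (for immune-gradient genes), and Normal(0, noise sd) noise.
#' Malignant-subtype samples draw immune levels from `U(0.2, 1)`, benign and
#' adjacent samples from `U(0, 0.3)`, so benign programs sit near the
#' adjacent-tissue baseline. Each nodule has a paired adjacent sample drawn
#' from the baseline-plus-immune model only. The matrix is exported on the
#' linear RPKM-like scale via `2^x - pseudocount` clipped at 0.
#'
#' @param spec a [simulation_spec()].
#' @return list with `expr` (linear-scale matrix, nodules then adjacent),
#'   `samples` (metadata with truth columns `true_subtype`, `immune_level`),
#'   `marker_sets` (named list, the planted marker blocks), `immune_genes`,
#'   and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_local_seed(derive_seed(spec$seed, "simulate_cohort"), {
    genes <- gene_names(spec$n_genes)
    K <- length(spec$subtypes)
    marker_sets <- split(
      genes[seq_len(K * spec$markers_per_subtype)],
      rep(seq_len(K), each = spec$markers_per_subtype))
    names(marker_sets) <- spec$subtypes
    immune_idx <- K * spec$markers_per_subtype + seq_len(spec$immune_genes)
    immune_genes <- genes[immune_idx]

    baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean,
                             spec$baseline_sd)
    names(baseline) <- genes

    n_nod <- sum(spec$samples_per_subtype)
    subtype_of <- rep(spec$subtypes, spec$samples_per_subtype)
    nod_ids <- sprintf("S%03dT", seq_len(n_nod))
    adj_ids <- sprintf("S%03dA", seq_len(n_nod))
    pair_ids <- sprintf("P%03d", seq_len(n_nod))
    benign <- startsWith(subtype_of, "B")
    imm_nod <- ifelse(benign, stats::runif(n_nod, 0, 0.3),
                      stats::runif(n_nod, 0.2, 1))
    imm_adj <- stats::runif(n_nod, 0, 0.3)

    build <- function(n, subtype, imm) {
      m <- matrix(baseline, nrow = spec$n_genes, ncol = n)
      for (j in seq_len(n)) {
        if (!is.na(subtype[j])) {
          mk <- marker_sets[[subtype[j]]]
          m[match(mk, genes), j] <- m[match(mk, genes), j] + spec$marker_effect
        }
        m[immune_idx, j] <- m[immune_idx, j] + spec$immune_amplitude * imm[j]
      }
      m + matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd),
                 spec$n_genes, n)
    }
    log_nod <- build(n_nod, subtype_of, imm_nod)
    log_adj <- build(n_nod, rep(NA_character_, n_nod), imm_adj)
    expr <- cbind(log_nod, log_adj)
    rownames(expr) <- genes
    colnames(expr) <- c(nod_ids, adj_ids)
    expr <- linear_scale(expr, spec$pseudocount)

    braf <- rep(FALSE, n_nod)
    in_sub <- which(subtype_of == spec$braf_subtype)
    if (length(in_sub))
      braf[sample(in_sub, round(spec$braf_fraction * length(in_sub)))] <- TRUE

    samples <- data.frame(
      sample_id = c(nod_ids, adj_ids),
      tissue = rep(c("nodule", "adjacent"), each = n_nod),
      histology = c(ifelse(benign, "BTN", "PTC"),
                    ifelse(benign, "BTN", "PTC")),
      pair_id = c(pair_ids, pair_ids),
      braf_mutant = c(braf, rep(FALSE, n_nod)),
      true_subtype = c(subtype_of, rep(NA_character_, n_nod)),
      immune_level = c(imm_nod, imm_adj),
      stringsAsFactors = FALSE)

    list(expr = expr, samples = samples, marker_sets = marker_sets,
         immune_genes = immune_genes, spec = spec)
  })
}

#' Simulate a branching benign-to-malignant trajectory cohort
#'
#' Each sample gets a latent time `t ~ U(0,1)` and a branch: `pre` before the
#' bifurcation, else `fate1`/`fate2` with equal probability. Three planted
#' gene programs ride on the baseline: cluster-I genes decline in `t` on both
#' fates, cluster-II genes rise after the bifurcation on fate 1 only, and
#' cluster-III genes rise on fate 2 only. Samples in the earliest tenth of
#' latent time are marked `adjacent` tissue (the trajectory root convention).
#'
#' @param spec a [simulation_spec()].
#' @return list with `expr` (linear scale), `samples` (with `true_time`,
#'   `true_branch`), `cluster_genes` (list I/II/III), and `spec`.
#' @export
simulate_trajectory_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  g_per <- spec$traj_genes_per_cluster
  if (3 * g_per > spec$n_genes)
    stop("trajectory program demand exceeds n_genes")
  with_local_seed(derive_seed(spec$seed, "simulate_trajectory_cohort"), {
    n <- spec$traj_n_samples
    genes <- gene_names(spec$n_genes)
    cl <- list(I = genes[seq_len(g_per)],
               II = genes[g_per + seq_len(g_per)],
               III = genes[2 * g_per + seq_len(g_per)])
    tt <- sort(stats::runif(n))
    bt <- spec$traj_branch_time
    branch <- ifelse(tt < bt, "pre",
                     ifelse(stats::runif(n) < 0.5, "fate1", "fate2"))
    baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean,
                             spec$baseline_sd)
    ramp <- pmax(0, (tt - bt) / (1 - bt))
    m <- matrix(baseline, spec$n_genes, n)
    m[match(cl$I, genes), ]  <- m[match(cl$I, genes), , drop = FALSE] +
      spec$traj_effect * rep(1 - tt, each = g_per)
    m[match(cl$II, genes), ] <- m[match(cl$II, genes), , drop = FALSE] +
      spec$traj_effect * rep(ramp * (branch == "fate1"), each = g_per)
    m[match(cl$III, genes), ] <- m[match(cl$III, genes), , drop = FALSE] +
      spec$traj_effect * rep(ramp * (branch == "fate2"), each = g_per)
    m <- m + matrix(stats::rnorm(spec$n_genes * n, 0, spec$traj_noise_sd),
                    spec$n_genes, n)
    ids <- sprintf("T%03d", seq_len(n))
    rownames(m) <- genes
    colnames(m) <- ids
    samples <- data.frame(
      sample_id = ids,
      tissue = ifelse(tt <= 0.1, "adjacent", "nodule"),
      histology = ifelse(branch == "pre", "BTN", "PTC"),
      true_time = tt, true_branch = branch,
      stringsAsFactors = FALSE)
    list(expr = linear_scale(m, spec$pseudocount), samples = samples,
         cluster_genes = cl, spec = spec)
  })
}

#' Simulate candidate fusion and mutation tables with planted truth
#'
#' Adversarial fixtures for the variant post-filters: rows sit at plus/minus
#' one around every filter threshold (split reads 4/5, spanning pairs 1/2,
#' gene-pair distance 9 kb/11 kb, tumor VAF 0.04/0.06, normal VAF 0.005/0.02,
#' coverage 9x/10x, dbSNP membership) so boundary semantics are testable.
#' Truth labels are assigned by construction, independently of the filters.
#'
#' @param spec a [simulation_spec()] (only the seed is used, for the small
#'   accompanying expression matrix).
#' @return list with `fusions`, `mutations` (data.frames carrying
#'   `truth_keep` / `truth_reason` columns) and `expr`, a small linear-scale
#'   matrix supplying the fusion partners' expression.
#' @export
simulate_variant_tables <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  # expression context: FG* genes expressed (max >= 1), LOWEXP never reaches 1
  fgenes <- c(sprintf("FG%02d", 1:12), "LOWEXP")
  with_local_seed(derive_seed(spec$seed, "simulate_variant_tables"), {
    ex <- matrix(stats::runif(length(fgenes) * 4, 1.5, 5),
                 nrow = length(fgenes), ncol = 4,
                 dimnames = list(fgenes, sprintf("V%02d", 1:4)))
    ex["LOWEXP", ] <- stats::runif(4, 0.1, 0.9)
    fus <- data.frame(
      LeftGene  = c("FG01", "FG03", "FG05", "FG07", "FG09", "FG11", "FG01",
                    "UNKNOWN1"),
      RightGene = c("FG02", "FG04", "FG06", "FG08", "FG10", "FG12", "LOWEXP",
                    "FG02"),
      JunctionReadCount = c(5L, 4L, 5L, 10L, 10L, 10L, 10L, 10L),
      SpanningFragCount = c(2L, 2L, 1L, 5L, 5L, 5L, 5L, 5L),
      SameChromosome    = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                            FALSE),
      PairDistance      = c(NA, NA, NA, 9000L, 11000L, NA, NA, NA),
      truth_keep   = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
      truth_reason = c("", "few split reads", "few spanning pairs",
                       "read-through", "", "", "low expression",
                       "unexpressed partner"),
      stringsAsFactors = FALSE)
    mut <- data.frame(
      gene = sprintf("MUT%02d", 1:9),
      position = 1000L + seq_len(9),
      ref = "A", alt = "T",
      t_depth     = c(100L, 200L, 100L, 100L, 60L, 9L, 100L, 100L, 100L),
      t_alt_count = c(5L,   8L,   6L,   20L,  4L,  5L,  20L,  20L,  20L),
      n_depth     = c(100L, 100L, 200L, 100L, 100L, 50L, 9L, 100L, 100L),
      n_alt_count = c(0L,   0L,   1L,   1L,   0L,   0L,  0L, 2L,   0L),
      dbsnp       = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE),
      truth_keep = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE),
      truth_reason = c("",                       # VAF 0.05 boundary kept
                       "low tumor VAF",          # 8/200 = 0.04
                       "",                       # normal VAF 0.005 kept
                       "high normal VAF",        # 1/100 = 0.01, strict <
                       "few alt reads",          # 4 < 5 though VAF 0.067
                       "insufficient coverage",  # tumor 9x
                       "insufficient coverage",  # normal 9x
                       "high normal VAF",        # 2/100 = 0.02
                       "dbSNP site"),
      stringsAsFactors = FALSE)
    list(fusions = fus, mutations = mut, expr = ex)
  })
}
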