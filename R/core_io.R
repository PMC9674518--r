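#' @keywords internal
"_PACKAGE"

# ---- expression matrix ------------------------------------------------------

#' Construct and validate an expression matrix
#'
#' The pipeline's universal substrate is a dense, non-negative gene-by-sample
#' matrix of RPKM-scale expression values, with gene symbols as row names and
#' sample identifiers as column names.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes character vector of gene symbols (defaults to rownames).
#' @param samples character vector of sample ids (defaults to colnames).
#' @return a validated numeric matrix with dimnames set.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples))
    stop("expression_matrix requires gene and sample identifiers")
  rownames(values) <- as.character(genes)
  colnames(values) <- as.character(samples)
  validate_expression_matrix(values)
  values
}

#' Validate expression-matrix invariants
#'
#' Checks that the matrix is numeric, finite, non-negative, and carries unique
#' gene and sample identifiers.
#'
#' @param m numeric matrix with dimnames.
#' @return invisibly, `m`.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene symbols in expression matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in expression matrix")
  if (any(!is.finite(m)))
    stop("expression matrix contains non-finite values")
  if (any(m < 0))
    stop("expression matrix contains negative values")
  invisible(m)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene symbols.
#' Duplicate gene rows are collapsed by the per-sample maximum (a common
#' convention when several transcripts map to one symbol); a warning reports
#' how many rows were collapsed. Negative values and duplicate sample ids are
#' format errors.
#'
#' @param path path to a tab-separated file.
#' @return validated expression matrix.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in expression TSV header")
  if (any(!is.finite(m)))
    stop("non-finite value in expression TSV")
  if (any(m < 0))
    stop("negative value in expression TSV")
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    warning(sprintf("collapsed %d duplicate gene row(s) by per-sample maximum",
                    ndup))
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(ix) {
      apply(m[ix, , drop = FALSE], 2, max)
    }))
    # split() sorts keys; restore first-occurrence order
    first <- genes[!duplicated(genes)]
    m <- m[first, , drop = FALSE]
    genes <- first
  }
  rownames(m) <- genes
  colnames(m) <- samples
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: gene symbols in the first column
#' (header `gene`), sample ids as remaining column headers.
#'
#' @param m expression matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2-transform an expression matrix
#'
#' Elementwise `log2(value + pseudocount)`; monotone and shape-preserving.
#' Downstream clustering, scoring and trajectory steps all consume this scale.
#'
#' @param m expression matrix on the linear (RPKM) scale.
#' @param pseudocount positive offset, default 1 so that zero maps to zero.
#' @return matrix of the same shape on log2 scale.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  validate_expression_matrix(m)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a positive scalar")
  log2(m + pseudocount)
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Within-set duplicates are
#' removed preserving first occurrence; duplicate set names and lines with
#' fewer than three fields are format errors.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (a gene-set collection), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- fields[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate gene-set name '%s' (GMT line %d)", nm, i))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop(sprintf("GMT line %d: empty gene list for set '%s'", i, nm))
    sets[[nm]] <- genes
    desc[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to "na".
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene-set collection must have unique names")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- sample metadata --------------------------------------------------------

#' Read a sample metadata table from TSV
#'
#' Requires columns `sample_id`, `tissue` (nodule/adjacent) and `histology`
#' (PTC/BTN); other columns (pair_id, braf_mutant, subtype, clinicopathologic
#' flags) are carried through as-is.
#'
#' @param path path to a tab-separated file.
#' @return data.frame, one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "histology")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample table")
  bad <- setdiff(unique(df$tissue), c("nodule", "adjacent"))
  if (length(bad))
    stop("unknown tissue class: ", paste(bad, collapse = ", "))
  df
}

#' Write a sample metadata table to TSV
#' @param df sample table data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' All named parameters of the downstream modules in one place, so a run is
#' fully described by (config, input files). Serializes through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param ... overrides of the defaults by name.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed            = 1L,
    pseudocount     = 1,
    nmf_k           = 6L,
    nmf_restarts    = 50L,
    nmf_max_iter    = 2000L,
    nmf_tol         = 1e-6,
    exemplar_n      = 50L,
    marker_permutations = 100L,
    marker_alpha    = 0.05,
    rf_trees        = 500L,
    ntp_permutations = 1000L,
    ssgsea_tau      = 0.25,
    mi_bins         = NA_integer_,   # NA -> ceiling(sqrt(n)) capped at 10
    dpi_tolerance   = 0,
    mi_null_permutations = 100L,
    mi_alpha        = 0.05,
    gsea_permutations = 1000L,
    traj_centroids  = NA_integer_,   # NA -> ceiling(n/10)
    beam_spline_df  = 3L,
    beam_q_cutoff   = 0.05,
    de_p_cutoff     = 0.05,
    de_lfc_cutoff   = 1,
    cv_folds        = c(4L, 6L, 8L, 10L),
    test_fraction   = 0.2,
    rfe_rule        = "one_se"       # or "best_mean"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param cfg a `run_config` list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return a `run_config` list with defaults filled in for absent fields.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_run_config, raw)
}

# ---- seeded randomness ------------------------------------------------------

#' Derive a child seed for a named operation
#'
#' Every stochastic operation draws from a child generator derived from the
#' global seed and the operation's name, so stages are independently
#' reproducible: re-running one stage with the same config reproduces it
#' bit-for-bit regardless of what ran before.
#'
#' @param seed integer master seed.
#' @param op_name character operation name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, op_name) {
  h <- as.double(seed %% 2147483647L)
  for (cc in utf8ToInt(op_name)) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
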