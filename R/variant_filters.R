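# Deterministic post-filters for candidate fusion and somatic-mutation calls.
# Boundary semantics are taken literally from the stated rules: "at least"
# means >=, "less than" means strict <; an off-by-one here silently changes
# results, so each rule is applied in a fixed order and the first failed rule
# becomes the row's rejection reason.

#' Filter candidate gene fusions
#'
#' Keeps a candidate iff all of the following hold, checked in order:
#' \enumerate{
#'   \item at least 5 junction-spanning split reads;
#'   \item at least 2 spanning read pairs;
#'   \item both partner genes are present in the expression matrix and at
#'     least one sample expresses each partner at RPKM >= 1 (a partner whose
#'     maximum RPKM over all samples is below 1 never reaches reliable
#'     expression and marks the call as a likely false positive);
#'   \item the partners are not a same-chromosome pair closer than 10 kb
#'     (annotated as a read-through event).
#' }
#' An unknown partner gene yields a rejection reason, never an exception.
#'
#' @param candidates data.frame with columns `LeftGene`, `RightGene`,
#'   `JunctionReadCount`, `SpanningFragCount`, `SameChromosome`,
#'   `PairDistance` (bp; may be NA when partners sit on different
#'   chromosomes).
#' @param expression linear-scale expression matrix covering the cohort.
#' @param min_split,min_spanning,min_rpkm,read_through_bp filter thresholds.
#' @return the input data.frame plus columns `keep` (logical) and `reason`
#'   ("" for kept rows).
#' @export
filter_fusions <- function(candidates, expression,
                           min_split = 5L, min_spanning = 2L,
                           min_rpkm = 1, read_through_bp = 10000L) {
  validate_expression_matrix(expression)
  stopifnot(all(c("LeftGene", "RightGene", "JunctionReadCount",
                  "SpanningFragCount", "SameChromosome", "PairDistance")
                %in% colnames(candidates)))
  gene_max <- apply(expression, 1, max)
  reason <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, ]
    reason[i] <- if (r$JunctionReadCount < min_split) {
      "few split reads"
    } else if (r$SpanningFragCount < min_spanning) {
      "few spanning pairs"
    } else if (!(r$LeftGene %in% rownames(expression)) ||
               !(r$RightGene %in% rownames(expression))) {
      "unexpressed partner"
    } else if (gene_max[[r$LeftGene]] < min_rpkm ||
               gene_max[[r$RightGene]] < min_rpkm) {
      "low expression"
    } else if (isTRUE(r$SameChromosome) && !is.na(r$PairDistance) &&
               r$PairDistance < read_through_bp) {
      "read-through"
    } else ""
  }
  out <- candidates
  out$keep <- reason == ""
  out$reason <- reason
  out
}

#' Filter candidate somatic mutations
#'
#' A high-confidence somatic mutation must satisfy, in order: tumor and
#' normal depth both at least `min_depth` (10x); tumor variant allele
#' fraction at least `min_tumor_vaf` (5\%, inclusive); normal VAF strictly
#' below `max_normal_vaf` (1\%); at least `min_alt_reads` (5) supporting
#' reads in the tumor; and absence from dbSNP (membership consumed as a
#' boolean column -- no database lookup is performed). Zero tumor depth makes
#' the VAF undefined and is rejected as insufficient coverage.
#'
#' @param candidates data.frame with columns `gene`, `position`, `ref`,
#'   `alt`, `t_depth`, `t_alt_count`, `n_depth`, `n_alt_count`, `dbsnp`.
#' @param min_depth,min_tumor_vaf,max_normal_vaf,min_alt_reads thresholds.
#' @return the input data.frame plus `keep` and `reason` columns.
#' @export
filter_mutations <- function(candidates, min_depth = 10L,
                             min_tumor_vaf = 0.05, max_normal_vaf = 0.01,
                             min_alt_reads = 5L) {
  stopifnot(all(c("t_depth", "t_alt_count", "n_depth", "n_alt_count",
                  "dbsnp") %in% colnames(candidates)))
  if (any(candidates$t_alt_count > candidates$t_depth) ||
      any(candidates$n_alt_count > candidates$n_depth))
    stop("alt read count exceeds depth")
  reason <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, ]
    reason[i] <- if (r$t_depth < min_depth || r$n_depth < min_depth) {
      "insufficient coverage"
    } else if (r$t_alt_count / r$t_depth < min_tumor_vaf) {
      "low tumor VAF"
    } else if (r$n_alt_count / r$n_depth >= max_normal_vaf) {
      "high normal VAF"
    } else if (r$t_alt_count < min_alt_reads) {
      "few alt reads"
    } else if (isTRUE(r$dbsnp)) {
      "dbSNP site"
    } else ""
  }
  out <- candidates
  out$keep <- reason == ""
  out$reason <- reason
  out
}
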