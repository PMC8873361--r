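# End-to-end orchestration: per-sample calling across a cohort with a
# shared alignment cache, aggregation and annotation.

#' Run the per-sample caller across a cohort
#'
#' Applies [call_sites()] to every sample (sharing one alignment cache,
#' since read sequences recur across samples), aggregates the calls into
#' a [aggregate_cohort()] matrix and applies SNP and pseudo annotation
#' when the reference provides the necessary inputs.
#'
#' @param reads named list of read data.frames (or a `simulate_cohort()`
#'   result, in which case `precursors`, `genome`, `snps` and the sheet
#'   are taken from it).
#' @param precursors named list of [precursor] objects.
#' @param sample_sheet data.frame (`sample_id`, `group`).
#' @param genome optional genome for cross-mapping correction.
#' @param snps optional SNP table for [annotate_snps()].
#' @param prevalence prevalence fraction for [prevalence_filter()]
#'   (0 disables).
#' @param keep_alignments retain per-sample alignments/hits (needed for
#'   [flag_pseudo()], which is then applied automatically).
#' @param ... further arguments passed to [call_sites()].
#' @return list with `samples` (named list of `sample_calls`) and
#'   `matrix` (annotated, prevalence-filtered `cohort_matrix`).
#' @export
run_cohort <- function(reads, precursors = NULL, sample_sheet = NULL,
                       genome = NULL, snps = NULL, prevalence = 0.07,
                       keep_alignments = FALSE, ...) {
  if (!is.null(reads$ref)) {               # a simulate_cohort() result
    cohort <- reads
    reads <- cohort$reads
    precursors <- precursors %||% cohort$ref$precursors
    genome <- genome %||% cohort$ref$genome
    snps <- snps %||% cohort$ref$snps
    sample_sheet <- sample_sheet %||% cohort$sheet
  }
  cache <- new.env(parent = emptyenv())
  samples <- lapply(reads, function(r)
    call_sites(r, precursors, genome = genome, cache = cache,
               keep_alignments = keep_alignments, ...))
  names(samples) <- names(reads)
  cm <- aggregate_cohort(samples, sample_sheet)
  cm <- prevalence_filter(cm, prevalence)
  if (!is.null(snps) && nrow(snps))
    cm <- annotate_snps(cm, snps, precursors)
  if (keep_alignments) {
    aln <- do.call(rbind, lapply(samples, `[[`, "alignments"))
    hits <- do.call(rbind, lapply(samples, function(s) s$hits))
    if (!is.null(hits)) hits <- unique(hits)
    cm <- flag_pseudo(cm, aln, hits, precursors)
  }
  list(samples = samples, matrix = cm)
}
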