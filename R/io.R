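# Readers and writers for every external representation the pipeline
# touches: precursor FASTA + annotation, FASTQ reads, SNP tables, sample
# sheets and the per-sample site report.

#' Construct a pre-miRNA precursor
#'
#' A precursor holds the hairpin sequence, its genomic locus and the
#' coordinates of its mature arms.  All precursor coordinates are 1-based
#' inclusive; genomic spans are 1-based inclusive on the named strand.
#'
#' @param id precursor name, e.g. `"hsa-mir-10b"`.
#' @param seq hairpin sequence 5'->3' (U accepted, stored as T).
#' @param chrom genome sequence name.
#' @param g_start,g_end genomic span (1-based inclusive).
#' @param strand `"+"` or `"-"`.
#' @param arms data.frame with columns `name`, `p_start`, `p_end` giving
#'   mature miRNA coordinates within the precursor.
#' @return an object of class `precursor`.
#' @export
precursor <- function(id, seq, chrom = "chr?", g_start = 1L,
                      g_end = nchar(seq), strand = "+",
                      arms = data.frame(name = character(),
                                        p_start = integer(),
                                        p_end = integer())) {
  seq <- toupper(to_dna(seq))
  p <- structure(
    list(id = id, seq = seq, chrom = chrom,
         g_start = as.integer(g_start), g_end = as.integer(g_end),
         strand = strand, arms = arms),
    class = "precursor")
  validate_precursor(p)
  p
}

validate_precursor <- function(p) {
  len <- nchar(p$seq)
  if (p$g_end - p$g_start + 1L != len)
    stop("precursor '", p$id, "': genomic span (", p$g_start, "-", p$g_end,
         ") does not match sequence length ", len)
  if (!p$strand %in% c("+", "-"))
    stop("precursor '", p$id, "': invalid strand '", p$strand, "'")
  if (grepl("[^ACGTN]", p$seq))
    stop("precursor '", p$id, "': non-nucleotide characters in sequence")
  a <- p$arms
  if (nrow(a)) {
    if (any(a$p_start < 1L) || any(a$p_end > len) || any(a$p_start >= a$p_end))
      stop("precursor '", p$id, "': arm interval outside [1, ", len, "]")
    if (any(a$p_end - a$p_start + 1L < 18L))
      stop("precursor '", p$id, "': mature arm shorter than 18 nt")
    o <- order(a$p_start)
    if (nrow(a) > 1L && any(a$p_start[o][-1L] <= a$p_end[o][-nrow(a)]))
      stop("precursor '", p$id, "': overlapping mature arms")
  }
  invisible(p)
}

#' @export
print.precursor <- function(x, ...) {
  cat("<precursor>", x$id, " (", nchar(x$seq), " nt, ", x$chrom, ":",
      x$g_start, "-", x$g_end, x$strand, ")\n", sep = "")
  for (i in seq_len(nrow(x$arms)))
    cat("  arm ", x$arms$name[i], " ", x$arms$p_start[i], "-",
        x$arms$p_end[i], "\n", sep = "")
  invisible(x)
}

#' Load precursors from FASTA plus an annotation table
#'
#' The annotation is a TSV with columns `precursor_id`, `chrom`, `start`,
#' `end`, `strand`, `arm_name`, `arm_start`, `arm_end` (one row per mature
#' arm, miRBase style).  Every FASTA record must have at least one
#' annotation row.
#'
#' @param fasta_path path to the hairpin FASTA (U or T alphabet).
#' @param annotation_path path to the annotation TSV.
#' @return named list of [precursor] objects.
#' @export
load_precursors <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)   # tolerates U (RNA)
  ids <- sub("\\s.*$", "", names(seqs))
  anno <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("precursor_id", "chrom", "start", "end", "strand",
            "arm_name", "arm_start", "arm_end")
  if (!all(need %in% names(anno)))
    stop("annotation is missing columns: ",
         paste(setdiff(need, names(anno)), collapse = ", "))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rows <- anno[anno$precursor_id == ids[i], , drop = FALSE]
    if (!nrow(rows))
      stop("no annotation for FASTA record '", ids[i], "'")
    out[[i]] <- precursor(
      id = ids[i],
      seq = as.character(seqs[[i]]),
      chrom = rows$chrom[1L],
      g_start = rows$start[1L], g_end = rows$end[1L],
      strand = rows$strand[1L],
      arms = data.frame(name = rows$arm_name,
                        p_start = as.integer(rows$arm_start),
                        p_end = as.integer(rows$arm_end)))
  }
  names(out) <- ids
  out
}

#' Write precursors back to FASTA + annotation TSV
#'
#' @param precursors named list of [precursor] objects.
#' @param fasta_path,annotation_path output paths.
#' @param alphabet `"dna"` or `"rna"` for the emitted FASTA.
#' @export
write_precursors <- function(precursors, fasta_path, annotation_path,
                             alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  seqs <- vapply(precursors, function(p) p$seq, "")
  if (alphabet == "rna") seqs <- to_rna(seqs)
  writeLines(paste0(">", vapply(precursors, `[[`, "", "id"), "\n", seqs),
             fasta_path)
  rows <- do.call(rbind, lapply(precursors, function(p) {
    data.frame(precursor_id = p$id, chrom = p$chrom, start = p$g_start,
               end = p$g_end, strand = p$strand, arm_name = p$arms$name,
               arm_start = p$arms$p_start, arm_end = p$arms$p_end)
  }))
  utils::write.table(rows, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read small RNA-seq reads from FASTQ
#'
#' @param path FASTQ path (Phred+33; plain or gzip).
#' @return data.frame with columns `id`, `seq`, `qual`, `count` (count is 1
#'   until reads are collapsed by [quality_filter()]).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: number of lines not a multiple of 4 in ", path)
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  data.frame(
    id = sub("^@", "", sub("\\s.*$", "", lines[4L * idx - 3L])),
    seq = toupper(to_dna(lines[4L * idx - 2L])),
    qual = lines[4L * idx],
    count = 1L,
    stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' Reads with `count > 1` are emitted once per record; the multiplicity is
#' kept in the read id as `id_xN`.
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  id <- ifelse(reads$count > 1L, paste0(reads$id, "_x", reads$count),
               reads$id)
  writeLines(paste0("@", id, "\n", reads$seq, "\n+\n", reads$qual), path)
  invisible(NULL)
}

#' Quality-filter and collapse reads
#'
#' Keeps reads whose first `span` bases (all bases for shorter reads) each
#' have Phred quality at least `q_min` and whose length strictly exceeds
#' `len_min`; identical surviving sequences are collapsed with summed
#' counts.  Filtering is idempotent.
#'
#' @param reads data.frame with `seq`, `qual`, `count` columns.
#' @param q_min minimum per-base Phred quality (default 30).
#' @param span number of leading bases the quality rule applies to
#'   (default 25).
#' @param len_min reads must be longer than this (default 18).
#' @return collapsed data.frame of surviving reads (`id` is the id of the
#'   first read of each collapsed group).
#' @export
quality_filter <- function(reads, q_min = 30L, span = 25L, len_min = 18L) {
  if (!nrow(reads)) return(reads)
  len <- nchar(reads$seq)
  ok_q <- vapply(seq_len(nrow(reads)), function(i) {
    q <- phred_ints(reads$qual[i])
    all(q[seq_len(min(span, length(q)))] >= q_min)
  }, logical(1))
  keep <- reads[ok_q & len > len_min, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  agg <- tapply(keep$count, keep$seq, sum)
  first <- keep[!duplicated(keep$seq), , drop = FALSE]
  first$count <- as.integer(agg[first$seq])
  # collapsed reads keep a representative quality string
  rownames(first) <- NULL
  first
}

# ---- site names --------------------------------------------------------

#' Parse an M/E site name
#'
#' Site names follow the convention
#' `<precursor>_<position>_<REF>_<alt>`: the precursor name, the 1-based
#' position within the precursor, the original nucleotide in upper case and
#' the edited/mutated nucleotide in lower case (RNA alphabet; `-` marks a
#' deletion).  Example: `hsa-mir-10b_26_A_c`.
#'
#' @param name site name string (vectorised).
#' @return data.frame with columns `precursor`, `position`, `ref`, `alt`.
#' @export
parse_site_name <- function(name) {
  m <- regmatches(name,
                  regexec("^(.+)_([0-9]+)_([ACGUT-])_([acgut-])$", name))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("malformed site name: ", paste(name[bad], collapse = ", "))
  data.frame(
    precursor = vapply(m, `[[`, "", 2L),
    position = as.integer(vapply(m, `[[`, "", 3L)),
    ref = vapply(m, `[[`, "", 4L),
    alt = vapply(m, `[[`, "", 5L),
    stringsAsFactors = FALSE)
}

#' Format an M/E site name
#'
#' Inverse of [parse_site_name()].  Bases may be given in DNA or RNA
#' alphabet; the name always renders in RNA (T -> U).
#'
#' @param precursor precursor name.
#' @param position 1-based precursor position.
#' @param ref reference base (upper case on output).
#' @param alt alternative base (lower case on output) or `-` for deletion.
#' @return character vector of site names.
#' @export
format_site_name <- function(precursor, position, ref, alt) {
  paste(precursor, position, toupper(to_rna(ref)), tolower(to_rna(alt)),
        sep = "_")
}

# ---- tabular writers ---------------------------------------------------

site_table_cols <- c("name", "precursor", "position", "ref", "alt",
                     "category", "region", "coverage", "edited_weight",
                     "level", "p_raw", "p_adj", "tptm")

#' Write a site-call table to TSV
#'
#' Columns are emitted in a stable order with floats at 6 significant
#' digits; [read_site_table()] reproduces the values.
#'
#' @param sites data.frame of site calls (see [call_sites()]).
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  out <- data.frame(matrix(nrow = nrow(sites), ncol = 0L))
  for (cn in site_table_cols) {
    v <- if (cn %in% names(sites)) sites[[cn]] else NA
    if (is.double(v)) v <- signif(v, 6L)
    out[[cn]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a site-call table written by [write_site_table()]
#'
#' @param path TSV path.
#' @return data.frame with the standard site columns.
#' @export
read_site_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(name = "character", ref = "character",
                                   alt = "character"))
}

#' Read a SNP table
#'
#' A TSV dialect of the dbSNP fields used here: `rsid`, `chrom`, `g_pos`,
#' `ref_allele`, `alt_allele` (plus-strand single-base alleles).
#'
#' @param path TSV path.
#' @return data.frame of SNP records.
#' @export
read_snp_table <- function(path) {
  snp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "g_pos", "ref_allele", "alt_allele")
  if (!all(need %in% names(snp)))
    stop("SNP table is missing columns: ",
         paste(setdiff(need, names(snp)), collapse = ", "))
  if (any(snp$ref_allele == snp$alt_allele))
    stop("SNP table has rows with identical ref and alt alleles")
  snp
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id` and `group`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ss)))
    stop("sample sheet must have columns sample_id and group")
  ss
}
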