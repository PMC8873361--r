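# Construction of edited mature miRNA variants and comparison of their
# target repertoires using PAR-CLIP style T-to-C evidence.  Target calling
# here follows the documented evidence rules (a cluster must contain at
# least one T-to-C converted read; prioritised targets need at least 10
# reads; the seed is mature nucleotides 1-8) plus a transparent seed-match
# probability score; it is a deliberately lightweight scheme referred to
# as "MiCPAR-lite" in the reports.

#' Build an edited/mutated mature miRNA variant
#'
#' Applies one M/E site to a mature arm: a 5'-editing site prepends its
#' base to the mature sequence (shifting the seed register by one), a
#' central substitution replaces the base (A-to-I renders as G), a 3'-tail
#' site appends the base, and a central deletion removes it.  The variant
#' is named `<precursor>_<pos><alt>`, e.g. `hsa-mir-10b_26c`.
#'
#' @param precursor a [precursor] object.
#' @param arm_name name of the mature arm the site affects.
#' @param position,ref,alt the site (precursor coordinates; `alt` lower
#'   case, RNA or DNA alphabet).
#' @return object of class `mature_variant`: list with `name`,
#'   `base_name`, `seq` (DNA alphabet), `seed` (first 8 nt), `position`,
#'   `alt`.
#' @export
apply_edit <- function(precursor, arm_name, position, ref, alt) {
  arm <- precursor$arms[precursor$arms$name == arm_name, , drop = FALSE]
  if (!nrow(arm)) stop("no arm named '", arm_name, "' on ", precursor$id)
  alt_d <- tolower(to_dna(alt))
  ref_d <- toupper(to_dna(ref))
  if (alt_d == tolower(ref_d))
    stop("site has identical reference and alternative base")
  mature <- substr(precursor$seq, arm$p_start, arm$p_end)
  k <- position - arm$p_start + 1L
  if (position >= arm$p_start - 2L && position < arm$p_start) {
    seq <- paste0(toupper(alt_d), mature)
  } else if (position >= arm$p_start && position <= arm$p_end) {
    if (alt_d == "-") {
      seq <- paste0(substr(mature, 1L, k - 1L),
                    substr(mature, k + 1L, nchar(mature)))
    } else {
      seq <- mature
      substr(seq, k, k) <- toupper(alt_d)
    }
  } else if (position > arm$p_end && position <= arm$p_end + 3L) {
    seq <- paste0(mature, toupper(alt_d))
  } else {
    stop("site at position ", position, " is not adjacent to arm ",
         arm_name)
  }
  if (nchar(seq) < 18L || nchar(seq) > 25L)
    stop("variant sequence length ", nchar(seq), " outside 18-25")
  structure(list(name = paste0(precursor$id, "_", position,
                               tolower(to_rna(alt_d))),
                 base_name = arm_name, seq = seq,
                 seed = substr(seq, 1L, 8L),
                 position = position, alt = alt_d),
            class = "mature_variant")
}

#' Mature variant from an unedited arm
#'
#' @param precursor a [precursor] object.
#' @param arm_name mature arm name.
#' @return a `mature_variant` holding the unmodified mature sequence.
#' @export
mature_sequence <- function(precursor, arm_name) {
  arm <- precursor$arms[precursor$arms$name == arm_name, , drop = FALSE]
  if (!nrow(arm)) stop("no arm named '", arm_name, "' on ", precursor$id)
  seq <- substr(precursor$seq, arm$p_start, arm$p_end)
  structure(list(name = arm_name, base_name = arm_name, seq = seq,
                 seed = substr(seq, 1L, 8L), position = NA_integer_,
                 alt = NA_character_),
            class = "mature_variant")
}

#' @export
print.mature_variant <- function(x, ...) {
  cat("<mature_variant> ", x$name, " ", to_rna(x$seq), " (seed ",
      to_rna(x$seed), ")\n", sep = "")
  invisible(x)
}

# Align one PAR-CLIP read to the transcript set: placements with at most
# `max_mm` mismatches, where read C over template T (a crosslink-induced
# conversion) is not counted against the limit.  Candidate positions come
# from pigeonhole search in a T->C collapsed alphabet, in which every
# conversion (and any C/T mismatch) is invisible; candidates are then
# verified against the original sequences.
.parclip_place <- function(seq, mseqs, mints, mnames, max_mm = 1L) {
  seq_int <- utf8ToInt(seq)
  seq_c <- chartr("T", "C", seq)
  L <- nchar(seq)
  tT <- utf8ToInt("T")
  tC <- utf8ToInt("C")
  out <- list()
  for (mi in seq_along(mseqs)) {
    cand <- pigeon_starts(seq_c, chartr("T", "C", mseqs[[mi]]), max_mm)
    for (s in cand) {
      tb <- mints[[mi]][s:(s + L - 1L)]
      mis <- seq_int != tb
      t2c <- mis & tb == tT & seq_int == tC
      if (sum(mis & !t2c) > max_mm) next
      out[[length(out) + 1L]] <- list(
        mrna = mnames[mi], start = s, end = s + L - 1L,
        mm = sum(mis & !t2c), n_t2c = sum(t2c))
    }
  }
  out
}

#' Cluster PAR-CLIP reads on transcripts
#'
#' Reads are aligned to the mRNA set (at most one non-T-to-C mismatch;
#' T-to-C conversions are free), overlapping placements are merged into
#' clusters, and T-to-C-converted reads are counted per cluster.
#'
#' @param reads data.frame with `id`, `seq`, `count`.
#' @param mrnas named character vector (or `DNAStringSet`) of transcript
#'   sequences.
#' @param max_mm non-conversion mismatch limit per read (default 1).
#' @return data.frame with `mrna`, `start`, `end`, `total_reads`,
#'   `t2c_reads`.
#' @export
find_clusters <- function(reads, mrnas, max_mm = 1L) {
  mseqs <- if (inherits(mrnas, "DNAStringSet"))
    stats::setNames(as.character(mrnas), names(mrnas))
  else toupper(to_dna(mrnas))
  mnames <- names(mseqs) %||% paste0("mrna", seq_along(mseqs))
  mints <- lapply(mseqs, utf8ToInt)
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    pls <- .parclip_place(reads$seq[i], mseqs, mints, mnames, max_mm)
    if (!length(pls)) next
    mm <- vapply(pls, `[[`, 0L, "mm")
    pls <- pls[mm == min(mm)]
    for (pl in pls)
      rows[[length(rows) + 1L]] <- data.frame(
        mrna = pl$mrna, start = pl$start, end = pl$end,
        count = reads$count[i], t2c = pl$n_t2c > 0L,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(mrna = character(), start = integer(),
                      end = integer(), total_reads = integer(),
                      t2c_reads = integer(), stringsAsFactors = FALSE))
  pl <- do.call(rbind, rows)
  out <- list()
  for (m in unique(pl$mrna)) {
    sub <- pl[pl$mrna == m, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cl_start <- sub$start[1L]
    cl_end <- sub$end[1L]
    tot <- 0L
    t2c <- 0L
    flush <- function() data.frame(mrna = m, start = cl_start,
                                   end = cl_end, total_reads = tot,
                                   t2c_reads = t2c,
                                   stringsAsFactors = FALSE)
    for (k in seq_len(nrow(sub))) {
      if (sub$start[k] > cl_end) {         # gap: new cluster
        out[[length(out) + 1L]] <- flush()
        cl_start <- sub$start[k]
        cl_end <- sub$end[k]
        tot <- 0L
        t2c <- 0L
      }
      cl_end <- max(cl_end, sub$end[k])
      tot <- tot + sub$count[k]
      if (sub$t2c[k]) t2c <- t2c + sub$count[k]
    }
    out[[length(out) + 1L]] <- flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Probability of at least one complementary match of length >= m in a
# window of length W, under an i.i.d. background with the window's own
# base frequencies.
.seed_match_p <- function(word, window_chars, W) {
  freq <- table(factor(window_chars, levels = c("A", "C", "G", "T")))
  freq <- as.numeric(freq) / max(1L, length(window_chars))
  names(freq) <- c("A", "C", "G", "T")
  q <- prod(freq[strsplit(word, "", fixed = TRUE)[[1L]]])
  n_win <- max(1L, W - nchar(word) + 1L)
  1 - (1 - q)^n_win
}

#' Predict target sites of a mature miRNA variant from PAR-CLIP clusters
#'
#' Within each cluster holding at least `min_t2c` T-to-C converted reads
#' (extended by `flank` nt on each side), searches for the reverse
#' complement of the miRNA seed: 8mer (mature positions 1-8), 7mer (2-8)
#' or 6mer (2-7).  Each site gets a score `p_s`: the probability of a
#' match at least that long arising in a window of that span under an
#' i.i.d. background with the window's base frequencies (smaller is
#' better).  The best (longest-match, then smallest `p_s`) site per
#' cluster is reported.
#'
#' @param mirna a `mature_variant`.
#' @param mrnas named character vector or `DNAStringSet` of transcripts.
#' @param clusters cluster table from [find_clusters()].
#' @param min_t2c minimum T-to-C read support per cluster (default 1).
#' @param flank search flank around the cluster (default 10).
#' @return data.frame with `mrna`, `site_start`, `site_end`, `match`
#'   (8mer/7mer/6mer), `p_s`, `cluster_start`, `cluster_end`,
#'   `cluster_reads`, `t2c_reads`.
#' @export
predict_targets <- function(mirna, mrnas, clusters, min_t2c = 1L,
                            flank = 10L) {
  mset <- if (inherits(mrnas, "DNAStringSet")) mrnas
          else Biostrings::DNAStringSet(toupper(to_dna(mrnas)))
  mnames <- names(mset) %||% paste0("mrna", seq_along(mset))
  words <- c(`8mer` = revcomp(substr(mirna$seq, 1L, 8L)),
             `7mer` = revcomp(substr(mirna$seq, 2L, 8L)),
             `6mer` = revcomp(substr(mirna$seq, 2L, 7L)))
  cl <- clusters[clusters$t2c_reads >= min_t2c, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    mi <- match(cl$mrna[i], mnames)
    if (is.na(mi)) next
    mseq <- as.character(mset[[mi]])
    from <- max(1L, cl$start[i] - flank)
    to <- min(nchar(mseq), cl$end[i] + flank)
    window <- substr(mseq, from, to)
    wchars <- strsplit(window, "", fixed = TRUE)[[1L]]
    for (w in names(words)) {
      hit <- regexpr(words[[w]], window, fixed = TRUE)
      if (hit > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          mrna = cl$mrna[i],
          site_start = from + as.integer(hit) - 1L,
          site_end = from + as.integer(hit) + nchar(words[[w]]) - 2L,
          match = w,
          p_s = .seed_match_p(words[[w]], wchars, nchar(window)),
          cluster_start = cl$start[i], cluster_end = cl$end[i],
          cluster_reads = cl$total_reads[i], t2c_reads = cl$t2c_reads[i],
          stringsAsFactors = FALSE)
        break                        # best (longest) match per cluster
      }
    }
  }
  if (!length(rows))
    return(data.frame(mrna = character(), site_start = integer(),
                      site_end = integer(), match = character(),
                      p_s = double(), cluster_start = integer(),
                      cluster_end = integer(), cluster_reads = integer(),
                      t2c_reads = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Compare original and edited target gene sets
#'
#' @param orig,edited character vectors of target gene ids (or target
#'   data.frames with an `mrna` column), collapsed to unique genes.
#' @return list with `common`, `new` (edited only) and `lost` (original
#'   only) gene vectors.
#' @export
compare_target_sets <- function(orig, edited) {
  g <- function(x) unique(if (is.data.frame(x)) x$mrna else x)
  o <- g(orig)
  e <- g(edited)
  list(common = intersect(o, e), new = setdiff(e, o),
       lost = setdiff(o, e))
}

#' Prioritise newly gained targets
#'
#' Removes duplicate genes and non-coding genes, then keeps genes whose
#' best supporting cluster has at least `min_reads` PAR-CLIP reads.
#'
#' @param new_targets target data.frame (from [predict_targets()], rows
#'   restricted to the `new` set) with `mrna` and `cluster_reads`.
#' @param annotations data.frame with `mrna`, `gene`, `coding` (logical).
#' @param min_reads minimum PAR-CLIP reads in the best cluster
#'   (default 10).
#' @return data.frame with `gene`, `mrna`, `cluster_reads`, sorted by
#'   decreasing read support.
#' @export
prioritize_new_targets <- function(new_targets, annotations,
                                   min_reads = 10L) {
  if (!nrow(new_targets))
    return(data.frame(gene = character(), mrna = character(),
                      cluster_reads = integer(), stringsAsFactors = FALSE))
  i <- match(new_targets$mrna, annotations$mrna)
  if (any(is.na(i))) {
    warning("targets missing from the gene annotation: ",
            paste(unique(new_targets$mrna[is.na(i)]), collapse = ", "))
    new_targets <- new_targets[!is.na(i), , drop = FALSE]
    i <- i[!is.na(i)]
  }
  new_targets$gene <- annotations$gene[i]
  new_targets$coding <- annotations$coding[i]
  sel <- new_targets[new_targets$coding, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(gene = character(), mrna = character(),
                      cluster_reads = integer(), stringsAsFactors = FALSE))
  sel <- sel[order(-sel$cluster_reads), , drop = FALSE]
  sel <- sel[!duplicated(sel$gene), , drop = FALSE]
  sel <- sel[sel$cluster_reads >= min_reads,
             c("gene", "mrna", "cluster_reads"), drop = FALSE]
  rownames(sel) <- NULL
  sel
}
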