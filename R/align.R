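# Read placement on pre-miRNA hairpins and genomic multi-mapping.
#
# The precursor aligner is a seed-and-extend matcher specialised for short
# reads against <= 200 nt hairpins.  A placement may contain up to
# `max_sub` internal substitutions, one single-base indel, an untemplated
# 3' tail of up to `max_tail` bases and up to `max_add5` extra 5' bases
# (classified as 5' additions only when they sit immediately upstream of a
# mature arm).  Genomic multi-mapping reproduces a report-all, <= 1
# mismatch contract, and multi-mapped reads are down-weighted by iterative
# cross-mapping correction against perfect-match locus expression.

# Candidate start offsets (position of read base 1 on the precursor) from
# an internal core that excludes the mutable head and tail.
.candidate_starts <- function(seq, subject, max_sub, max_tail, max_add5) {
  L <- nchar(seq)
  core_from <- max_add5 + 1L
  core_to <- L - max_tail
  core <- substr(seq, core_from, core_to)
  pigeon_starts(core, subject, max_sub) - (core_from - 1L)
}

# Anchor-derived candidate starts for indel placements.  The left anchor
# fixes the 5' register; the right anchor fixes the 3' register assuming
# one deleted or one inserted base in between.
.indel_candidates <- function(seq, subject, max_tail, max_add5) {
  L <- nchar(seq)
  r0L <- max_add5 + 1L
  la <- substr(seq, r0L, r0L + 7L)
  r1R <- L - max_tail
  r0R <- r1R - 7L
  ra <- substr(seq, r0R, r1R)
  sL <- fixed_starts(la, subject)
  sR <- fixed_starts(ra, subject)
  starts <- unique(c(sL - (r0L - 1L),        # gapless register from left
                     sR - r0R,               # register if one base deleted
                     sR - r0R + 2L))         # register if one base inserted
  starts[starts > -max_add5]
}

# Evaluate one placement: read base 1 at precursor position `start`, with
# an optional deleted template base (del_pos, precursor coords) or an
# inserted read base (ins_pos, read coords).  Returns NULL when the
# placement violates the edit budget, otherwise a list describing the ops.
.evaluate_placement <- function(chars, prec, arms, start,
                                del_pos = NA_integer_,
                                ins_pos = NA_integer_,
                                max_sub = 1L, max_tail = 3L, max_add5 = 2L) {
  L <- length(chars)
  plen <- length(prec)
  tpos <- start + seq_len(L) - 1L
  if (!is.na(del_pos)) {
    if (del_pos <= start || del_pos >= start + L) return(NULL)
    tpos[tpos >= del_pos] <- tpos[tpos >= del_pos] + 1L
  }
  if (!is.na(ins_pos)) {
    if (ins_pos < 2L || ins_pos > L - 1L) return(NULL)
    shift <- seq_len(L) > ins_pos
    tpos[shift] <- tpos[shift] - 1L
    tpos[ins_pos] <- NA_integer_
  }
  inb <- !is.na(tpos) & tpos >= 1L & tpos <= plen
  tbase <- rep(NA_character_, L)
  tbase[inb] <- prec[tpos[inb]]
  mis <- is.na(tbase) | chars != tbase
  if (!is.na(ins_pos)) mis[ins_pos] <- FALSE   # handled as its own op

  kind <- rep("", L)   # per-base role: "", add5, tail3, sub

  # untemplated 3' tail: trailing contiguous mismatches, at most max_tail
  j <- L
  while (j >= 1L && mis[j] && (L - j + 1L) <= max_tail) {
    kind[j] <- "tail3"
    j <- j - 1L
  }

  # 5' additions: leading contiguous mismatches within the first max_add5
  # bases, eligible only upstream of an arm start or off the 5' boundary
  i <- 1L
  while (i <= max_add5 && i <= L && mis[i]) {
    p <- tpos[i]
    eligible <- is.na(p) || p < 1L ||
      any(p >= arms$p_start - max_add5 & p < arms$p_start)
    if (!eligible) break
    kind[i] <- "add5"
    i <- i + 1L
  }

  internal <- which(mis & kind == "")
  # bases hanging off the precursor must be explained as head or tail
  if (any(!inb[internal])) return(NULL)
  if (length(internal) > max_sub) return(NULL)
  kind[internal] <- "sub"

  n_indel <- as.integer(!is.na(del_pos)) + as.integer(!is.na(ins_pos))
  edits <- length(internal) + n_indel
  matched <- sum(!mis & kind == "")
  templ <- which(kind != "add5" & kind != "tail3" &
                   (is.na(ins_pos) | seq_len(L) != ins_pos))
  if (!length(templ)) return(NULL)
  t_start <- min(tpos[templ])
  t_end <- max(tpos[templ])
  if (t_start < 1L || t_end > plen) return(NULL)

  ops <- NULL
  op_row <- function(p_pos, ref, alt, k) {
    data.frame(p_pos = p_pos, ref = ref, alt = alt, kind = k,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (b in which(kind == "add5"))
    rows[[length(rows) + 1L]] <- op_row(tpos[b],
      ifelse(is.na(tbase[b]), "-", tbase[b]), tolower(chars[b]), "add5")
  for (b in which(kind == "sub"))
    rows[[length(rows) + 1L]] <- op_row(tpos[b], tbase[b],
                                        tolower(chars[b]), "substitution")
  if (!is.na(del_pos))
    rows[[length(rows) + 1L]] <- op_row(del_pos, prec[del_pos], "-",
                                        "deletion")
  if (!is.na(ins_pos))
    rows[[length(rows) + 1L]] <- op_row(start + ins_pos - 1L, "-",
                                        tolower(chars[ins_pos]), "insertion")
  for (b in which(kind == "tail3"))
    rows[[length(rows) + 1L]] <- op_row(tpos[b],
      ifelse(is.na(tbase[b]), "-", tbase[b]), tolower(chars[b]), "tail3")
  ops <- if (length(rows)) do.call(rbind, rows) else
    data.frame(p_pos = integer(), ref = character(), alt = character(),
               kind = character(), stringsAsFactors = FALSE)

  list(start = start, del_pos = del_pos, ins_pos = ins_pos,
       t_start = t_start, t_end = t_end, edits = edits,
       matched = matched, ops = ops)
}

# All acceptable placements of one read sequence on one precursor.
.place_read <- function(seq, pprep, max_sub, max_tail, max_add5) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- list()
  starts <- tryCatch(
    .candidate_starts(seq, pprep$seq, max_sub, max_tail, max_add5),
    error = function(e) integer(0))
  for (s in starts) {
    pl <- .evaluate_placement(chars, pprep$chars, pprep$arms, s,
                              max_sub = max_sub, max_tail = max_tail,
                              max_add5 = max_add5)
    if (!is.null(pl)) out[[length(out) + 1L]] <- pl
  }
  best_edits <- if (length(out)) min(vapply(out, `[[`, 0, "edits")) else Inf
  if (best_edits > 0L) {
    # no clean gapless placement: look for single-base indel placements
    istarts <- tryCatch(
      .indel_candidates(seq, pprep$seq, max_tail, max_add5),
      error = function(e) integer(0))
    L <- length(chars)
    for (s in istarts) {
      for (d in (s + 1L):(s + L - 1L)) {
        if (d < 1L || d > length(pprep$chars)) next
        pl <- .evaluate_placement(chars, pprep$chars, pprep$arms, s,
                                  del_pos = d, max_sub = max_sub,
                                  max_tail = max_tail, max_add5 = max_add5)
        if (!is.null(pl) && pl$edits <= 1L)
          out[[length(out) + 1L]] <- pl
      }
      for (ip in 2L:(L - 1L)) {
        pl <- .evaluate_placement(chars, pprep$chars, pprep$arms, s,
                                  ins_pos = ip, max_sub = max_sub,
                                  max_tail = max_tail, max_add5 = max_add5)
        if (!is.null(pl) && pl$edits <= 1L)
          out[[length(out) + 1L]] <- pl
      }
    }
  }
  out
}

#' Align reads to pre-miRNA hairpins
#'
#' Each read is placed at its best-scoring positions (fewest internal
#' edits, then most templated matching bases).  Deviations from the
#' template are recorded as edit operations: internal substitutions,
#' single-base indels, untemplated 3'-tail bases (up to `max_tail`) and
#' 5' additions (up to `max_add5` bases immediately upstream of a mature
#' arm).  When a read has several equally good placements its initial
#' weight is split uniformly; see [cross_map_correct()] for
#' expression-informed reweighting.
#'
#' @param reads data.frame with `id`, `seq`, `count` columns (collapsed,
#'   see [quality_filter()]).
#' @param precursors named list of [precursor] objects.
#' @param max_sub maximum internal substitutions per placement (default 1).
#' @param max_tail maximum untemplated 3'-tail length (default 3).
#' @param max_add5 maximum extra 5' bases (default 2).
#' @param cache optional environment used to memoise placements per read
#'   sequence across calls (precursor set must not change between calls).
#' @return data.frame with one row per placement: `read_id`, `seq`,
#'   `count`, `precursor_id`, `p_offset`, `t_start`, `t_end`, `edits`,
#'   `weight`, `chrom`, `g_pos`, `strand` and a list column `ops`.  The
#'   attribute `"log"` summarises reads in/aligned/dropped.
#' @export
align_to_precursors <- function(reads, precursors, max_sub = 1L,
                                max_tail = 3L, max_add5 = 2L, cache = NULL) {
  prep <- lapply(precursors, function(p) {
    list(id = p$id, seq = p$seq,
         chars = strsplit(p$seq, "", fixed = TRUE)[[1L]],
         arms = p$arms, chrom = p$chrom, g_start = p$g_start,
         g_end = p$g_end, strand = p$strand)
  })
  prep <- prep[order(vapply(prep, `[[`, "", "id"))]

  place_seq <- function(seq) {
    if (!is.null(cache) && !is.null(cache[[seq]])) return(cache[[seq]])
    cand <- list()
    for (pp in prep) {
      pls <- .place_read(seq, pp, max_sub, max_tail, max_add5)
      for (pl in pls) {
        pl$precursor <- pp
        cand[[length(cand) + 1L]] <- pl
      }
    }
    if (length(cand)) {
      edits <- vapply(cand, `[[`, 0, "edits")
      matched <- vapply(cand, `[[`, 0, "matched")
      best <- edits == min(edits)
      cand <- cand[best]
      matched <- matched[best]
      cand <- cand[matched == max(matched)]
      # deduplicate equivalent placements; for indels in homopolymer runs
      # keep the leftmost gap position (deterministic tie-break)
      pos_key <- vapply(cand, function(x) {
        v <- c(x$del_pos, x$ins_pos)
        v <- v[!is.na(v)]
        if (length(v)) min(v) else 0
      }, 0)
      cand <- cand[order(vapply(cand, function(x) x$precursor$id, ""),
                         vapply(cand, `[[`, 0L, "start"), pos_key)]
      key <- vapply(cand, function(x)
        paste(x$precursor$id, x$start,
              is.na(x$del_pos), is.na(x$ins_pos)), "")
      cand <- cand[!duplicated(key)]
    }
    if (!is.null(cache)) cache[[seq]] <- cand
    cand
  }

  rows <- list()
  n_unaligned <- 0L
  for (i in seq_len(nrow(reads))) {
    cand <- place_seq(reads$seq[i])
    if (!length(cand)) {
      n_unaligned <- n_unaligned + 1L
      next
    }
    w <- 1 / length(cand)
    for (pl in cand) {
      pp <- pl$precursor
      g_pos <- if (pp$strand == "+") pp$g_start + pl$t_start - 1L
               else pp$g_start + (length(pp$chars) - pl$t_end)
      rows[[length(rows) + 1L]] <- list(
        read_id = reads$id[i], seq = reads$seq[i], count = reads$count[i],
        precursor_id = pp$id, p_offset = pl$start, t_start = pl$t_start,
        t_end = pl$t_end, edits = pl$edits, weight = w, chrom = pp$chrom,
        g_pos = g_pos, strand = pp$strand, ops = list(pl$ops))
    }
  }
  if (!length(rows)) {
    out <- data.frame(read_id = character(), seq = character(),
                      count = integer(), precursor_id = character(),
                      p_offset = integer(), t_start = integer(),
                      t_end = integer(), edits = integer(),
                      weight = double(), chrom = character(),
                      g_pos = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    out$ops <- list()
  } else {
    out <- data.frame(
      read_id = vapply(rows, `[[`, "", "read_id"),
      seq = vapply(rows, `[[`, "", "seq"),
      count = vapply(rows, `[[`, 0L, "count"),
      precursor_id = vapply(rows, `[[`, "", "precursor_id"),
      p_offset = vapply(rows, `[[`, 0L, "p_offset"),
      t_start = vapply(rows, `[[`, 0L, "t_start"),
      t_end = vapply(rows, `[[`, 0L, "t_end"),
      edits = vapply(rows, function(r) as.integer(r$edits), 0L),
      weight = vapply(rows, `[[`, 0, "weight"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      g_pos = vapply(rows, function(r) as.integer(r$g_pos), 0L),
      strand = vapply(rows, `[[`, "", "strand"),
      stringsAsFactors = FALSE)
    out$ops <- lapply(rows, function(r) r$ops[[1L]])
  }
  attr(out, "log") <- list(reads_in = nrow(reads),
                           reads_aligned = nrow(reads) - n_unaligned,
                           reads_unaligned = n_unaligned)
  out
}

#' Find all genomic hits of reads with at most one mismatch
#'
#' Emulates a report-all short-read mapping with a one-mismatch ceiling:
#' every placement of each read on either strand of the genome with at
#' most one substitution is reported.
#'
#' @param reads data.frame with `id`, `seq` (and optionally `count`).
#' @param genome named character vector or `DNAStringSet` of genome
#'   sequences.
#' @param cache optional environment memoising hits per read sequence.
#' @return data.frame with `read_id`, `chrom`, `g_pos` (plus-strand start,
#'   1-based), `strand`, `mismatches`.
#' @export
genomic_multimap <- function(reads, genome, cache = NULL) {
  gseq <- if (inherits(genome, "DNAStringSet"))
    stats::setNames(as.character(genome), names(genome))
  else toupper(to_dna(genome))
  chroms <- names(gseq)
  if (is.null(chroms)) chroms <- paste0("seq", seq_along(gseq))
  gint <- lapply(gseq, utf8ToInt)

  hits_for <- function(seq) {
    if (!is.null(cache)) {
      key <- paste0("g:", seq)
      if (!is.null(cache[[key]])) return(cache[[key]])
    }
    res <- list()
    pats <- c(`+` = seq, `-` = revcomp(seq))
    for (ci in seq_along(gseq)) {
      for (st in c("+", "-")) {
        pat_int <- utf8ToInt(pats[[st]])
        cand <- pigeon_starts(pats[[st]], gseq[[ci]], 1L)
        if (!length(cand)) next
        mm <- vapply(cand, function(s) mm_at(pat_int, gint[[ci]], s), 0)
        keep <- mm <= 1L
        if (!any(keep)) next
        res[[length(res) + 1L]] <- data.frame(
          chrom = chroms[ci], g_pos = cand[keep], strand = st,
          mismatches = as.integer(mm[keep]),
          stringsAsFactors = FALSE)
      }
    }
    res <- if (length(res)) do.call(rbind, res) else
      data.frame(chrom = character(), g_pos = integer(),
                 strand = character(), mismatches = integer(),
                 stringsAsFactors = FALSE)
    if (!is.null(cache)) cache[[paste0("g:", seq)]] <- res
    res
  }

  out <- lapply(seq_len(nrow(reads)), function(i) {
    h <- hits_for(reads$seq[i])
    if (!nrow(h)) return(NULL)
    cbind(read_id = reads$id[i], h, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(read_id = character(), chrom = character(),
                      g_pos = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-mapping correction of multi-mapped read weights
#'
#' Genomic hits are clustered into loci (hits on the same chromosome and
#' strand within `gap` bases merge).  For each read mapping to several
#' loci, its weight at locus L is set proportional to the locus
#' expression, defined as the weighted count of perfectly matching (zero
#' mismatch) reads at L.  Because expression itself depends on the
#' weights, the proportional allocation is iterated to a fixed point
#' (maximum weight change below `tol`, or `max_iter` sweeps).  Reads whose
#' candidate loci all have zero perfect-match expression fall back to
#' uniform weights.
#'
#' @param alignments precursor alignments from [align_to_precursors()].
#' @param hits genomic hits from [genomic_multimap()].
#' @param gap locus clustering distance (default 30).
#' @param tol convergence tolerance on weights (default 1e-6).
#' @param max_iter iteration cap (default 50).
#' @return `alignments` with the `weight` column replaced by corrected
#'   weights.  The attribute `"locus_weights"` holds the per-read,
#'   per-locus weight table (weights of one read sum to 1 over its loci).
#' @export
cross_map_correct <- function(alignments, hits, gap = 30L, tol = 1e-6,
                              max_iter = 50L) {
  if (!nrow(alignments) || !nrow(hits)) return(alignments)

  o <- order(hits$chrom, hits$strand, hits$g_pos)
  h <- hits[o, , drop = FALSE]
  new_locus <- c(TRUE, h$chrom[-1L] != h$chrom[-nrow(h)] |
                   h$strand[-1L] != h$strand[-nrow(h)] |
                   diff(h$g_pos) > gap)
  h$locus <- cumsum(new_locus)

  counts <- alignments$count[!duplicated(alignments$read_id)]
  names(counts) <- alignments$read_id[!duplicated(alignments$read_id)]
  h$count <- ifelse(h$read_id %in% names(counts),
                    counts[h$read_id], 1L)

  # unique (read, locus) pairs; perfect if any hit in the pair is perfect
  key <- paste(h$read_id, h$locus)
  agg_perfect <- tapply(h$mismatches == 0L, key, any)
  rl <- h[!duplicated(key), c("read_id", "locus", "count")]
  rl$perfect <- as.logical(agg_perfect[paste(rl$read_id, rl$locus)])
  rl_by_read <- split(seq_len(nrow(rl)), rl$read_id)
  nl <- lengths(rl_by_read)[rl$read_id]
  rl$w <- 1 / as.numeric(nl)

  multi <- names(rl_by_read)[lengths(rl_by_read) > 1L]
  if (length(multi)) {
    for (iter in seq_len(max_iter)) {
      expr <- tapply(rl$count * rl$w * rl$perfect, rl$locus, sum)
      delta <- 0
      for (r in multi) {
        idx <- rl_by_read[[r]]
        e <- as.numeric(expr[as.character(rl$locus[idx])])
        e[is.na(e)] <- 0
        wnew <- if (sum(e) > 0) e / sum(e) else rep(1 / length(idx),
                                                    length(idx))
        delta <- max(delta, max(abs(wnew - rl$w[idx])))
        rl$w[idx] <- wnew
      }
      if (delta < tol) break
    }
  }

  # map corrected locus weights back onto precursor alignments
  h_by_read <- split(seq_len(nrow(h)), h$read_id)
  aln_locus <- rep(NA_integer_, nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    idx <- h_by_read[[alignments$read_id[i]]]
    if (is.null(idx)) next
    hit <- idx[h$chrom[idx] == alignments$chrom[i] &
                 h$strand[idx] == alignments$strand[i] &
                 abs(h$g_pos[idx] - alignments$g_pos[i]) <= 8L]
    if (length(hit)) aln_locus[i] <- h$locus[hit[1L]]
  }
  key_al <- paste(alignments$read_id, aln_locus)
  share <- table(key_al[!is.na(aln_locus)])
  j <- match(key_al, paste(rl$read_id, rl$locus))
  w <- alignments$weight
  # placements of one read sharing a locus split that locus's weight
  ok <- !is.na(aln_locus) & !is.na(j)
  w[ok] <- rl$w[j[ok]] / as.numeric(share[key_al[ok]])
  alignments$weight <- w
  attr(alignments, "locus_weights") <-
    rl[, c("read_id", "locus", "perfect", "w")]
  attr(alignments, "log") <- attr(alignments, "log")
  alignments
}
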