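# Per-sample conversion of weighted alignments into M/E site calls:
# position tallies, binomial significance against the sequencing-error
# rate, category classification and the significance criteria.

#' Tally read support per precursor position
#'
#' Accumulates weighted read mass per position of one precursor:
#' templated coverage over each alignment's span, plus "adjacency" mass
#' (reads whose templated end is immediately before / start immediately
#' after a position), which provides the denominator for untemplated
#' 3'-tail and 5'-addition sites.  Alternative-base mass is aggregated
#' from the alignments' edit operations.  Weights are multiplied by read
#' multiplicities.
#'
#' @param alignments alignment rows referring to this precursor.
#' @param precursor a [precursor] object.
#' @param max_tail,max_add5 virtual position allowances beyond the
#'   precursor boundaries.
#' @return list with `coverage` (data.frame `p_pos`, `cov_w`, `cov_n`;
#'   combined templated + adjacency mass) and `alts` (data.frame `p_pos`,
#'   `ref`, `alt`, `kinds`, `alt_w`, `alt_n`).
#' @export
tally_positions <- function(alignments, precursor, max_tail = 3L,
                            max_add5 = 2L) {
  plen <- nchar(precursor$seq)
  off <- max_add5 + 1L                      # vector index of position 0
  span <- plen + max_tail + max_add5 + 1L
  cov_w <- numeric(span)
  cov_n <- numeric(span)
  a <- alignments[alignments$precursor_id == precursor$id, , drop = FALSE]

  idx <- function(p) p + off               # precursor pos -> vector index
  for (i in seq_len(nrow(a))) {
    mass <- a$weight[i] * a$count[i]
    rng <- idx(a$t_start[i]):idx(a$t_end[i])
    cov_w[rng] <- cov_w[rng] + mass
    cov_n[rng] <- cov_n[rng] + a$count[i]
    # adjacency: a read ending at p-1 (or starting at p+1) is informative
    # coverage for an untemplated base at p
    for (p in c(a$t_end[i] + 1L, a$t_start[i] - 1L)) {
      if (p + off >= 1L && p + off <= span) {
        cov_w[idx(p)] <- cov_w[idx(p)] + mass
        cov_n[idx(p)] <- cov_n[idx(p)] + a$count[i]
      }
    }
  }

  ops <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    o <- a$ops[[i]]
    if (!nrow(o)) return(NULL)
    o$mass <- a$weight[i] * a$count[i]
    o$n <- a$count[i]
    o
  }))
  alts <- if (is.null(ops) || !nrow(ops)) {
    data.frame(p_pos = integer(), ref = character(), alt = character(),
               kinds = character(), alt_w = double(), alt_n = integer(),
               stringsAsFactors = FALSE)
  } else {
    key <- paste(ops$p_pos, ops$ref, ops$alt, sep = "\r")
    first <- !duplicated(key)
    data.frame(
      p_pos = ops$p_pos[first], ref = ops$ref[first], alt = ops$alt[first],
      kinds = vapply(split(ops$kind, key)[key[first]],
                     function(k) paste(sort(unique(k)), collapse = ","), ""),
      alt_w = as.numeric(tapply(ops$mass, key, sum)[key[first]]),
      alt_n = as.integer(tapply(ops$n, key, sum)[key[first]]),
      stringsAsFactors = FALSE)
  }

  pos_all <- seq(-max_add5, plen + max_tail + 1L)
  nz <- cov_w > 0
  coverage <- data.frame(p_pos = pos_all[nz], cov_w = cov_w[nz],
                         cov_n = cov_n[nz])
  list(coverage = coverage, alts = alts)
}

#' Binomial significance of an M/E event
#'
#' One-sided binomial tail probability of observing at least `k` deviant
#' reads among `n` covering reads if deviations arose purely from
#' sequencing error at rate `p_err`.  The default rate 1e-3 corresponds to
#' the Phred 30 quality floor applied during read filtering.
#'
#' @param k integer deviant-read support.
#' @param n integer coverage.
#' @param p_err per-base error probability (default `1e-3`).
#' @return P\[X >= k\] for X ~ Binomial(n, p_err).
#' @export
site_significance <- function(k, n, p_err = 1e-3) {
  if (any(k > n)) stop("edited support k exceeds coverage n")
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p_err, lower.tail = FALSE))
}

#' Classify an M/E site
#'
#' Decision order: (1) a position beyond a mature arm's templated 3' end,
#' or any read supporting it via a 3'-tail operation, is a 3' addition
#' (`3'-A`, `3'-U` or `3'-Other` by the added base); (2) a 5'-addition
#' operation or a substitution at most 2 nt before an arm's 5' start is
#' `5'-editing`; (3) substitutions inside an arm are `A-to-I` (A>g),
#' `C-to-U` (C>u) or `Other`; (4) indels inside an arm are `indel`.  Sites
#' outside any arm neighbourhood get region `outside-arm` and are excluded
#' from reports.  `SNP` and `pseudo` labels are applied at the cohort
#' stage and override these categories.
#'
#' @param precursor a [precursor] object.
#' @param p_pos 1-based precursor position of the site.
#' @param ref,alt reference and alternative symbols (DNA alphabet, alt
#'   lower case, `-` for deletions/insertions).
#' @param kinds character vector of the edit-operation kinds supporting
#'   the site.
#' @param max_tail,max_add5 neighbourhood sizes at the arm ends.
#' @return list with `region` (`central`, `end5`, `end3`, `outside-arm`)
#'   and `category`.
#' @export
classify_site <- function(precursor, p_pos, ref, alt, kinds = character(),
                          max_tail = 3L, max_add5 = 2L) {
  arms <- precursor$arms
  alt_d <- tolower(to_dna(alt))
  if (any(kinds == "tail3") ||
      any(p_pos > arms$p_end & p_pos <= arms$p_end + max_tail)) {
    cat3 <- if (alt_d == "a") "3'-A" else if (alt_d == "t") "3'-U"
            else "3'-Other"
    return(list(region = "end3", category = cat3))
  }
  if (any(kinds == "add5") ||
      (any(p_pos >= arms$p_start - max_add5 & p_pos < arms$p_start) &&
         alt_d != "-")) {
    return(list(region = "end5", category = "5'-editing"))
  }
  if (any(p_pos >= arms$p_start & p_pos <= arms$p_end)) {
    if (alt_d == "-" || ref == "-")
      return(list(region = "central", category = "indel"))
    cat <- if (ref == "A" && alt_d == "g") "A-to-I"
           else if (ref == "C" && alt_d == "t") "C-to-U"
           else "Other"
    return(list(region = "central", category = cat))
  }
  list(region = "outside-arm", category = NA_character_)
}

#' Tags-per-ten-million normalisation
#'
#' @param mass weighted read mass of interest.
#' @param sample_total total weighted read mass mapped to precursors in
#'   the sample.
#' @return `mass * 1e7 / sample_total`.
#' @export
tptm_normalize <- function(mass, sample_total) {
  if (any(sample_total == 0)) stop("sample_total must be positive")
  mass * 1e7 / sample_total
}

#' Apply the significance criteria to candidate sites
#'
#' A site is significant when (i) its editing level is at least
#' `min_level`, (ii) at least `min_reads` reads support the event (raw
#' read counts, not weights), and (iii) its Benjamini-Hochberg adjusted
#' binomial p-value is below `alpha`.  Adjustment is performed over all
#' candidate sites passed in (one sample), unless a `p_adj` column is
#' already present.
#'
#' @param sites candidate site data.frame (see [call_sites()]).
#' @param min_level minimum editing level (default 0.05).
#' @param min_reads minimum supporting read count (default 10).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @return `sites` with a logical `significant` column.
#' @export
significant_sites <- function(sites, min_level = 0.05, min_reads = 10L,
                              alpha = 0.05) {
  if (!nrow(sites)) {
    sites$significant <- logical(0)
    return(sites)
  }
  if (is.null(sites$p_adj) || all(is.na(sites$p_adj)))
    sites$p_adj <- stats::p.adjust(sites$p_raw, method = "BH")
  sites$significant <- sites$level >= min_level &
    sites$edited_reads >= min_reads & sites$p_adj < alpha
  sites
}

#' Call M/E sites in one sample
#'
#' Runs the per-sample pipeline: quality filtering and read collapsing,
#' alignment to the precursors, optional genomic multi-mapping plus
#' cross-mapping weight correction, per-position tallies and site calls
#' with binomial significance, category classification, TPTM and the
#' significance criteria.
#'
#' @param reads raw reads (data.frame `id`, `seq`, `qual`, `count`).
#' @param precursors named list of [precursor] objects.
#' @param genome optional genome (named character vector or
#'   `DNAStringSet`); when supplied, multi-mapped reads are reweighted by
#'   [cross_map_correct()].
#' @param p_err binomial error rate for [site_significance()].
#' @param min_level,min_reads,alpha significance criteria
#'   (see [significant_sites()]).
#' @param q_min,span,len_min quality-filter parameters
#'   (see [quality_filter()]).
#' @param max_sub,max_tail,max_add5 aligner parameters.
#' @param cache optional environment shared across samples to memoise
#'   alignment of recurring read sequences.
#' @param keep_alignments keep the alignment and hit tables in the result
#'   (needed for pseudo-site flagging).
#' @return object of class `sample_calls`: list with `sites` (all
#'   candidate sites, including insignificant ones, with a `significant`
#'   flag), `coverage` (per precursor position), `total_mass`, `log`, and
#'   optionally `alignments` and `hits`.
#' @export
call_sites <- function(reads, precursors, genome = NULL, p_err = 1e-3,
                       min_level = 0.05, min_reads = 10L, alpha = 0.05,
                       q_min = 30L, span = 25L, len_min = 18L,
                       max_sub = 1L, max_tail = 3L, max_add5 = 2L,
                       cache = NULL, keep_alignments = FALSE) {
  filt <- quality_filter(reads, q_min = q_min, span = span,
                         len_min = len_min)
  aln <- align_to_precursors(filt, precursors, max_sub = max_sub,
                             max_tail = max_tail, max_add5 = max_add5,
                             cache = cache)
  log <- attr(aln, "log")
  hits <- NULL
  if (!is.null(genome) && nrow(aln)) {
    # only multi-placement or edited reads can shift weight; restrict the
    # genomic search to reads that aligned to a precursor
    uniq <- aln[!duplicated(aln$read_id), c("read_id", "seq")]
    names(uniq) <- c("id", "seq")
    hits <- genomic_multimap(uniq, genome, cache = cache)
    names(hits)[names(hits) == "id"] <- "read_id"
    aln <- cross_map_correct(aln, hits)
  }

  total_mass <- sum(aln$weight * aln$count)
  site_rows <- list()
  cov_rows <- list()
  for (p in precursors) {
    tl <- tally_positions(aln, p, max_tail = max_tail,
                          max_add5 = max_add5)
    if (nrow(tl$coverage)) {
      tl$coverage$precursor <- p$id
      cov_rows[[length(cov_rows) + 1L]] <- tl$coverage
    }
    al <- tl$alts
    if (!nrow(al)) next
    cov_at <- function(pos) {
      i <- match(pos, tl$coverage$p_pos)
      ifelse(is.na(i), 0, tl$coverage$cov_w[i])
    }
    cov_n_at <- function(pos) {
      i <- match(pos, tl$coverage$p_pos)
      ifelse(is.na(i), 0L, tl$coverage$cov_n[i])
    }
    for (j in seq_len(nrow(al))) {
      kinds <- strsplit(al$kinds[j], ",", fixed = TRUE)[[1L]]
      cls <- classify_site(p, al$p_pos[j], al$ref[j], al$alt[j], kinds,
                           max_tail = max_tail, max_add5 = max_add5)
      if (cls$region == "outside-arm") next
      # positions reached only by multi-base tails have no adjacency mass;
      # the edited mass itself is then the floor of the denominator
      cov_w <- max(cov_at(al$p_pos[j]), al$alt_w[j])
      if (cov_w <= 0) next
      level <- min(1, al$alt_w[j] / cov_w)
      k <- min(round(al$alt_w[j]), round(cov_w))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        name = format_site_name(p$id, al$p_pos[j], al$ref[j], al$alt[j]),
        precursor = p$id, position = al$p_pos[j],
        ref = toupper(to_rna(al$ref[j])), alt = tolower(to_rna(al$alt[j])),
        category = cls$category, region = cls$region,
        coverage = cov_w, coverage_reads = cov_n_at(al$p_pos[j]),
        edited_weight = al$alt_w[j], edited_reads = al$alt_n[j],
        level = level,
        p_raw = site_significance(max(0L, round(al$alt_w[j])),
                                  max(1L, round(cov_w)), p_err),
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(name = character(), precursor = character(),
               position = integer(), ref = character(), alt = character(),
               category = character(), region = character(),
               coverage = double(), coverage_reads = double(),
               edited_weight = double(), edited_reads = integer(),
               level = double(), p_raw = double(), stringsAsFactors = FALSE)
  if (nrow(sites)) sites$p_adj <- stats::p.adjust(sites$p_raw, "BH")
  else sites$p_adj <- double(0)
  sites$tptm <- if (nrow(sites))
    tptm_normalize(sites$edited_weight, total_mass) else double(0)
  sites <- significant_sites(sites, min_level = min_level,
                             min_reads = min_reads, alpha = alpha)
  coverage <- if (length(cov_rows)) do.call(rbind, cov_rows) else
    data.frame(p_pos = integer(), cov_w = double(), cov_n = double(),
               precursor = character(), stringsAsFactors = FALSE)
  log$sites_called <- nrow(sites)
  log$sites_significant <- sum(sites$significant)
  out <- list(sites = sites, coverage = coverage, total_mass = total_mass,
              log = log)
  if (keep_alignments) {
    out$alignments <- aln
    out$hits <- hits
  }
  structure(out, class = "sample_calls")
}

#' @export
print.sample_calls <- function(x, ...) {
  cat("<sample_calls> ", x$log$reads_in, " reads in, ",
      x$log$reads_aligned, " aligned; ", x$log$sites_called,
      " candidate sites, ", x$log$sites_significant, " significant\n",
      sep = "")
  invisible(x)
}
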