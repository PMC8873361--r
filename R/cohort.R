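# Cohort-level aggregation: merge per-sample calls into a sites-by-samples
# matrix, apply prevalence / SNP / pseudo / conservation annotation, and
# produce the summary statistics reported per category and per region.

#' Combine per-sample site calls into a cohort matrix
#'
#' Rows are the union of sites significant in at least one sample; every
#' cell carries that sample's editing level even where the site is
#' insignificant there (required by the differential tests).  Cells where
#' the position is covered but no deviant read was seen hold level 0;
#' cells without coverage hold `NA`.
#'
#' @param samples named list of `sample_calls` objects (names = sample
#'   ids), or unnamed with ids given by `sample_sheet`.
#' @param sample_sheet data.frame with `sample_id` and `group`.
#' @return object of class `cohort_matrix`: list with `levels`,
#'   `coverage`, `significant` matrices (sites x samples), `sites`
#'   metadata data.frame and the `samples` sheet.
#' @export
aggregate_cohort <- function(samples, sample_sheet) {
  ids <- names(samples) %||% sample_sheet$sample_id
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!setequal(ids, sample_sheet$sample_id))
    stop("sample ids do not match the sample sheet")
  samples <- samples[sample_sheet$sample_id]
  ids <- sample_sheet$sample_id

  sig_names <- unique(unlist(lapply(samples, function(s)
    s$sites$name[s$sites$significant])))
  n_site <- length(sig_names)
  n_samp <- length(ids)
  lev <- matrix(NA_real_, n_site, n_samp, dimnames = list(sig_names, ids))
  cov <- matrix(0, n_site, n_samp, dimnames = list(sig_names, ids))
  sig <- matrix(FALSE, n_site, n_samp, dimnames = list(sig_names, ids))

  meta <- NULL
  for (s in samples) {
    m <- s$sites[s$sites$name %in% sig_names, , drop = FALSE]
    if (is.null(meta)) meta <- m[, c("name", "precursor", "position",
                                     "ref", "alt", "category", "region")]
    else meta <- rbind(meta,
                       m[!m$name %in% meta$name,
                         c("name", "precursor", "position", "ref", "alt",
                           "category", "region")])
  }
  meta <- meta[match(sig_names, meta$name), , drop = FALSE]
  rownames(meta) <- NULL

  for (j in seq_along(ids)) {
    s <- samples[[j]]
    i <- match(s$sites$name, sig_names)
    ok <- !is.na(i)
    lev[i[ok], j] <- s$sites$level[ok]
    sig[i[ok], j] <- s$sites$significant[ok]
    # coverage (and implicit level 0) for sites absent from this sample
    covkey <- paste(s$coverage$precursor, s$coverage$p_pos)
    ci <- match(paste(meta$precursor, meta$position), covkey)
    cv <- ifelse(is.na(ci), 0, s$coverage$cov_w[ci])
    cov[, j] <- cv
    miss <- is.na(lev[, j]) & cv > 0
    lev[miss, j] <- 0
  }

  structure(list(levels = lev, coverage = cov, significant = sig,
                 sites = meta, samples = sample_sheet),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix> ", nrow(x$levels), " sites x ", ncol(x$levels),
      " samples (groups: ",
      paste(unique(x$samples$group), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Minimum number of samples for the prevalence filter
#'
#' `ceiling(fraction * n_samples)`, at least 1.  With the 111-sample
#' cohort and the default 7% this gives 8 samples.
#'
#' @param n_samples cohort size.
#' @param fraction required fraction of samples (default 0.07).
#' @return integer threshold.
#' @export
prevalence_threshold <- function(n_samples, fraction = 0.07) {
  if (n_samples <= 0) stop("n_samples must be positive")
  # tiny slack so exact products (e.g. 0.07 * 100) do not round up
  max(1L, as.integer(ceiling(fraction * n_samples - 1e-9)))
}

#' Keep sites significant in enough samples
#'
#' Removes matrix rows significant in fewer than
#' [prevalence_threshold()] samples, guarding against sites produced by
#' scattered sequencing errors.
#'
#' @param cm a `cohort_matrix`.
#' @param fraction required fraction of samples (default 0.07).
#' @return filtered `cohort_matrix`.
#' @export
prevalence_filter <- function(cm, fraction = 0.07) {
  if (fraction <= 0) return(cm)
  thr <- prevalence_threshold(ncol(cm$significant), fraction)
  keep <- rowSums(cm$significant) >= thr
  cm$levels <- cm$levels[keep, , drop = FALSE]
  cm$coverage <- cm$coverage[keep, , drop = FALSE]
  cm$significant <- cm$significant[keep, , drop = FALSE]
  cm$sites <- cm$sites[keep, , drop = FALSE]
  cm
}

#' Relabel sites that are known SNPs
#'
#' A site is relabelled `SNP` when (i) its genomic position equals a SNP
#' record's position, (ii) its reference and alternative nucleotides equal
#' the SNP's alleles (reverse-complemented for precursors on the minus
#' strand, since SNP alleles are plus-strand), and (iii) its editing level
#' reaches 100% in at least one sample.  Criterion (iii) tolerates
#' `level_tol` of sequencing-error dropout (levels at or above
#' `1 - level_tol` count as 100%).
#'
#' @param cm a `cohort_matrix`.
#' @param snps SNP data.frame (see [read_snp_table()]).
#' @param precursors named list of [precursor] objects.
#' @param level_tol tolerance on the 100%-level criterion (default 0.005).
#' @return `cm` with matching sites' category set to `"SNP"`.
#' @export
annotate_snps <- function(cm, snps, precursors, level_tol = 0.005) {
  if (!nrow(cm$sites) || !nrow(snps)) return(cm)
  for (i in seq_len(nrow(cm$sites))) {
    st <- cm$sites[i, ]
    if (st$alt == "-" || st$ref == "-") next
    p <- precursors[[st$precursor]]
    if (is.null(p)) next
    if (st$position < 1L || st$position > nchar(p$seq))
      stop("site ", st$name, " lies beyond its precursor's genomic span")
    if (p$strand == "+") {
      g_pos <- p$g_start + st$position - 1L
      ref <- toupper(to_dna(st$ref))
      alt <- toupper(to_dna(st$alt))
    } else {
      g_pos <- p$g_end - st$position + 1L
      ref <- revcomp(toupper(to_dna(st$ref)))
      alt <- revcomp(toupper(to_dna(st$alt)))
    }
    hit <- snps$chrom == p$chrom & snps$g_pos == g_pos &
      toupper(snps$ref_allele) == ref & toupper(snps$alt_allele) == alt
    if (!any(hit)) next
    if (max(cm$levels[i, ], na.rm = TRUE) >= 1 - level_tol)
      cm$sites$category[i] <- "SNP"
  }
  cm
}

#' Flag pseudo sites
#'
#' An apparent M/E site is flagged `pseudo` when more than half of its
#' deviant read mass maps perfectly (zero mismatches) to a genomic locus
#' other than the precursor's own, i.e. the "edited" reads are explainable
#' as templated products of another locus.
#'
#' @param cm a `cohort_matrix`.
#' @param alignments combined alignment table (with `ops` list column)
#'   from the samples used to support the calls.
#' @param hits combined genomic hit table.
#' @param precursors named list of [precursor] objects.
#' @param threshold mass fraction that must be explainable elsewhere
#'   (strictly greater; default 0.5).
#' @return `cm` with flagged sites' category set to `"pseudo"`.
#' @export
flag_pseudo <- function(cm, alignments, hits, precursors, threshold = 0.5) {
  if (!nrow(cm$sites) || is.null(hits) || !nrow(hits)) return(cm)
  for (i in seq_len(nrow(cm$sites))) {
    st <- cm$sites[i, ]
    p <- precursors[[st$precursor]]
    if (is.null(p)) next
    alt_d <- tolower(to_dna(st$alt))
    ref_d <- toupper(to_dna(st$ref))
    sup <- vapply(seq_len(nrow(alignments)), function(k) {
      if (alignments$precursor_id[k] != st$precursor) return(FALSE)
      o <- alignments$ops[[k]]
      any(o$p_pos == st$position & o$alt == alt_d &
            (o$ref == ref_d | o$ref == "-"))
    }, TRUE)
    if (!any(sup)) next
    sup_aln <- alignments[sup, , drop = FALSE]
    total <- 0
    elsewhere <- 0
    for (k in seq_len(nrow(sup_aln))) {
      mass <- sup_aln$count[k]
      total <- total + mass
      hh <- hits[hits$read_id == sup_aln$read_id[k] &
                   hits$mismatches == 0L, , drop = FALSE]
      inside <- hh$chrom == p$chrom & hh$g_pos >= p$g_start - 3L &
        hh$g_pos <= p$g_end
      if (any(!inside)) elsewhere <- elsewhere + mass
    }
    if (total > 0 && elsewhere / total > threshold)
      cm$sites$category[i] <- "pseudo"
  }
  cm
}

#' Flag editing sites conserved across species
#'
#' A site is conserved when an editing site of the same type at the same
#' mature-miRNA position (1-based offset from the arm's 5' start) is
#' reported for at least one other species.
#'
#' @param cm a `cohort_matrix`.
#' @param species_tables data.frame with columns `species`, `mature_name`,
#'   `mature_pos`, `type`.
#' @param precursors named list of [precursor] objects.
#' @return `cm` with a logical `conserved` column added to `$sites`.
#' @export
annotate_conservation <- function(cm, species_tables, precursors) {
  cons <- rep(FALSE, nrow(cm$sites))
  if (nrow(cm$sites) && !is.null(species_tables) &&
      nrow(species_tables)) {
    for (i in seq_len(nrow(cm$sites))) {
      st <- cm$sites[i, ]
      p <- precursors[[st$precursor]]
      if (is.null(p)) next
      arm <- p$arms[p$arms$p_start <= st$position &
                      p$arms$p_end >= st$position, , drop = FALSE]
      if (!nrow(arm)) next          # sites outside arms are never conserved
      mpos <- st$position - arm$p_start[1L] + 1L
      cons[i] <- any(species_tables$mature_name == arm$name[1L] &
                       species_tables$mature_pos == mpos &
                       species_tables$type == st$category)
    }
  }
  cm$sites$conserved <- cons
  cm
}

#' Category counts and percentages
#'
#' @param categories character vector of site categories (or a site
#'   data.frame with a `category` column).
#' @return data.frame with `category`, `count` and `pct` (percent of the
#'   total, one decimal, rounded half away from zero), sorted by
#'   decreasing count.
#' @export
category_summary <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  if (!length(categories))
    return(data.frame(category = character(), count = integer(),
                      pct = double(), stringsAsFactors = FALSE))
  tab <- sort(table(categories), decreasing = TRUE)
  data.frame(category = names(tab), count = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / length(categories),
                                 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Base composition flanking editing sites
#'
#' Frequency of each base immediately 5' and 3' of the edited positions in
#' the precursor, over sites of one category.  A-to-I sites in brain tend
#' to sit in a U(-1)/G(+1) context; C-to-U sites in a C/C context (the
#' APOBEC3G CCC motif).
#'
#' @param sites site data.frame (needs `precursor`, `position`,
#'   `category`).
#' @param precursors named list of [precursor] objects.
#' @param category category to select (e.g. `"A-to-I"`).
#' @return list with `p5` and `p3` (named frequency vectors over
#'   A/C/G/U) and `skipped` (count of boundary sites with a missing
#'   flank).
#' @export
neighbor_base_distribution <- function(sites, precursors, category) {
  sel <- sites[!is.na(sites$category) & sites$category == category, ,
               drop = FALSE]
  b5 <- character()
  b3 <- character()
  skipped <- 0L
  for (i in seq_len(nrow(sel))) {
    p <- precursors[[sel$precursor[i]]]
    pos <- sel$position[i]
    if (pos - 1L >= 1L) b5 <- c(b5, substr(p$seq, pos - 1L, pos - 1L))
    else skipped <- skipped + 1L
    if (pos + 1L <= nchar(p$seq)) b3 <- c(b3, substr(p$seq, pos + 1L,
                                                     pos + 1L))
    else skipped <- skipped + 1L
  }
  freq <- function(b) {
    if (!length(b)) return(stats::setNames(numeric(0), character(0)))
    t <- table(to_rna(b))
    stats::setNames(as.numeric(t) / length(b), names(t))
  }
  list(p5 = freq(b5), p3 = freq(b3), skipped = skipped)
}

#' Distribution of edited-position counts per precursor and region
#'
#' For each region class (5' end, 3' end, central) counts how many
#' precursors carry exactly k edited positions of that class.
#'
#' @param sites site data.frame (needs `precursor`, `position`, `region`).
#' @return data.frame with `region`, `k`, `n_precursors`.
#' @export
end_edit_distribution <- function(sites) {
  out <- list()
  for (reg in c("end5", "central", "end3")) {
    sel <- sites[sites$region == reg, , drop = FALSE]
    if (!nrow(sel)) next
    per_prec <- tapply(sel$position, sel$precursor,
                       function(x) length(unique(x)))
    tab <- table(per_prec)
    out[[length(out) + 1L]] <- data.frame(
      region = reg, k = as.integer(names(tab)),
      n_precursors = as.integer(tab), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(region = character(), k = integer(),
                      n_precursors = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composition of the reference cohort emulated by the simulator
#'
#' The reference brain-cohort composition the simulator's defaults
#' mirror: prefrontal cortex samples from Huntington's disease patients
#' (HD-PC) and seven healthy-control sample groups.
#'
#' @return data.frame with `group`, `condition` and `n_samples`.
#' @export
hd_cohort_design <- function() {
  data.frame(
    group = c("HD-PC", "PC", "Am", "FC", "CC", "As", "NG", "Unknown"),
    condition = c("HD", rep("control", 7L)),
    n_samples = c(28L, 38L, 14L, 6L, 6L, 3L, 1L, 15L),
    stringsAsFactors = FALSE)
}
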