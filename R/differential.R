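# Between-group comparison of editing levels (and edited-form expression)
# with Mann-Whitney U tests and Benjamini-Hochberg correction.

#' Mann-Whitney U test for two groups of editing levels
#'
#' Exact p-value by complete enumeration of group assignments when the
#' combined sample size is at most 12 (valid with or without ties, via
#' midranks); otherwise the normal approximation with tie-corrected
#' variance and continuity correction.  Two-sided.
#'
#' @param a,b numeric vectors of levels per group.
#' @return list with `U` (the U statistic for `a`: number of (a, b) pairs
#'   with a > b, ties counting 1/2) and `p` (two-sided p-value).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n <- length(a)
  m <- length(b)
  if (n + m <= 12L) {
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    centre <- n * m / 2
    cs <- utils::combn(n + m, n)
    Us <- colSums(matrix(r[cs], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - centre) >= abs(U - centre) - 1e-12)
    return(list(U = U, p = p))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: values are capped at
#' 1 and monotone in the ranking of the raw p-values.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Differential editing between two cohort groups
#'
#' For each site in a (prevalence-filtered) cohort matrix, compares
#' editing levels between the two groups with [mann_whitney_u()].  Cells
#' where the site was callable (coverage of at least `min_reads`) but not
#' detected enter as level 0; uncallable cells are excluded.  Two
#' significance tiers are reported: raw p below `alpha`, and BH-adjusted
#' FDR below `alpha`.
#'
#' @param cm a `cohort_matrix`.
#' @param group_a,group_b group labels from the sample sheet (direction is
#'   expressed for `group_a`).
#' @param alpha significance threshold (default 0.05).
#' @param min_reads coverage needed for a missing cell to count as level 0
#'   (default 10).
#' @return data.frame with one row per tested site: `site`, `n_a`, `n_b`,
#'   `median_a`, `median_b`, `U`, `p_raw`, `fdr`, `direction`
#'   (increased/decreased in group A), `sig_raw`, `sig_fdr`.
#' @export
differential_editing <- function(cm, group_a, group_b, alpha = 0.05,
                                 min_reads = 10L) {
  for (g in c(group_a, group_b))
    if (!g %in% cm$samples$group) stop("unknown group label: ", g)
  ia <- which(cm$samples$group == group_a)
  ib <- which(cm$samples$group == group_b)
  rows <- list()
  for (i in seq_len(nrow(cm$levels))) {
    vals <- function(idx) {
      lv <- cm$levels[i, idx]
      cv <- cm$coverage[i, idx]
      lv[is.na(lv)] <- 0
      lv[cv >= min_reads]
    }
    va <- vals(ia)
    vb <- vals(ib)
    if (!length(va) || !length(vb)) next
    mw <- mann_whitney_u(va, vb)
    med_a <- stats::median(va)
    med_b <- stats::median(vb)
    dir <- if (med_a > med_b) "increased"
           else if (med_a < med_b) "decreased"
           else if (mw$U >= length(va) * length(vb) / 2) "increased"
           else "decreased"
    rows[[length(rows) + 1L]] <- data.frame(
      site = rownames(cm$levels)[i], n_a = length(va), n_b = length(vb),
      median_a = med_a, median_b = med_b, U = mw$U, p_raw = mw$p,
      direction = dir, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(site = character(), n_a = integer(),
                      n_b = integer(), median_a = double(),
                      median_b = double(), U = double(), p_raw = double(),
                      fdr = double(), direction = character(),
                      sig_raw = logical(), sig_fdr = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_raw)
  res$sig_raw <- res$p_raw < alpha
  res$sig_fdr <- res$fdr < alpha
  res[, c("site", "n_a", "n_b", "median_a", "median_b", "U", "p_raw",
          "fdr", "direction", "sig_raw", "sig_fdr")]
}

#' Summarise flagged differential sites
#'
#' Counts increased/decreased sites among those flagged at the requested
#' tier, with percentages at two decimals (half away from zero), and
#' optionally the category composition of the flagged set in the same
#' format.
#'
#' @param records output of [differential_editing()].
#' @param tier `"raw"` or `"fdr"`.
#' @param categories optional named character vector mapping site name to
#'   category.
#' @return list with `n_flagged`, `direction` (data.frame direction /
#'   count / pct) and, when categories are given, `category` (data.frame
#'   category / count / pct).
#' @export
differential_summary <- function(records, tier = c("raw", "fdr"),
                                 categories = NULL) {
  tier <- match.arg(tier)
  flag <- if (tier == "raw") records$sig_raw else records$sig_fdr
  sel <- records[flag, , drop = FALSE]
  n <- nrow(sel)
  dir_tab <- table(factor(sel$direction,
                          levels = c("increased", "decreased")))
  direction <- data.frame(
    direction = names(dir_tab), count = as.integer(dir_tab),
    pct = if (n) round_half_up(100 * as.integer(dir_tab) / n, 2L)
          else rep(0, length(dir_tab)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(n_flagged = n, direction = direction)
  if (!is.null(categories) && n) {
    cats <- categories[sel$site]
    tab <- sort(table(cats), decreasing = TRUE)
    out$category <- data.frame(
      category = names(tab), count = as.integer(tab),
      pct = round_half_up(100 * as.integer(tab) / n, 2L),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Compare expression of an edited miRNA form between groups
#'
#' Applies the same Mann-Whitney machinery to per-sample normalised
#' expression (TPTM) of one sequence variant, e.g. the edited mature form
#' of a miRNA.
#'
#' @param tptm matrix of TPTM values, variants x samples.
#' @param variant row name of the variant to test.
#' @param cm_or_sheet a `cohort_matrix` or a sample sheet data.frame
#'   (`sample_id`, `group`).
#' @param group_a,group_b group labels.
#' @param alpha significance threshold (default 0.05).
#' @return one-row data.frame in the [differential_editing()] format.
#' @export
expression_compare <- function(tptm, variant, cm_or_sheet, group_a,
                               group_b, alpha = 0.05) {
  sheet <- if (inherits(cm_or_sheet, "cohort_matrix")) cm_or_sheet$samples
           else cm_or_sheet
  if (!variant %in% rownames(tptm))
    stop("variant absent from the expression matrix: ", variant)
  v <- tptm[variant, sheet$sample_id]
  if (all(v == 0)) stop("variant absent from all samples: ", variant)
  va <- v[sheet$group == group_a]
  vb <- v[sheet$group == group_b]
  mw <- mann_whitney_u(va, vb)
  med_a <- stats::median(va)
  med_b <- stats::median(vb)
  dir <- if (med_a > med_b) "increased"
         else if (med_a < med_b) "decreased"
         else if (mw$U >= length(va) * length(vb) / 2) "increased"
         else "decreased"
  data.frame(site = variant, n_a = length(va), n_b = length(vb),
             median_a = med_a, median_b = med_b, U = mw$U, p_raw = mw$p,
             fdr = mw$p, direction = dir, sig_raw = mw$p < alpha,
             sig_fdr = mw$p < alpha, stringsAsFactors = FALSE)
}

#' Per-sample TPTM of reads carrying a given edit
#'
#' Builds the variants-x-samples expression matrix used by
#' [expression_compare()]: for each sample, the TPTM of the site's edited
#' read mass (0 when the site was not observed there).
#'
#' @param samples named list of `sample_calls` objects.
#' @param site_names character vector of site names.
#' @return matrix, `site_names` x samples.
#' @export
variant_tptm <- function(samples, site_names) {
  out <- matrix(0, length(site_names), length(samples),
                dimnames = list(site_names, names(samples)))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    i <- match(s$sites$name, site_names)
    ok <- !is.na(i)
    out[i[ok], j] <- s$sites$tptm[ok]
  }
  out
}
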