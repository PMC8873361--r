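# Cohort aggregation, prevalence, SNP / pseudo / conservation annotation
# and the summary statistics.

# Construct a cohort_matrix directly (bypassing the caller) for the
# matrix-level operations.
make_matrix <- function(sig, levels = NULL, coverage = NULL,
                        sites = NULL, groups = NULL) {
  n <- nrow(sig)
  m <- ncol(sig)
  if (is.null(levels)) levels <- matrix(0.2, n, m,
                                        dimnames = dimnames(sig))
  if (is.null(coverage)) coverage <- matrix(100, n, m,
                                            dimnames = dimnames(sig))
  if (is.null(sites))
    sites <- data.frame(name = rownames(sig),
                        precursor = "p1", position = seq_len(n) + 9L,
                        ref = "A", alt = "g", category = "A-to-I",
                        region = "central", stringsAsFactors = FALSE)
  if (is.null(groups)) groups <- rep("G", m)
  structure(list(levels = levels, coverage = coverage, significant = sig,
                 sites = sites,
                 samples = data.frame(sample_id = colnames(sig),
                                      group = groups,
                                      stringsAsFactors = FALSE)),
            class = "cohort_matrix")
}

sig_matrix <- function(n_sig, n_samples, site = "p1_10_A_g") {
  sig <- matrix(FALSE, 1, n_samples,
                dimnames = list(site, sprintf("S%03d", 1:n_samples)))
  sig[1, seq_len(n_sig)] <- TRUE
  sig
}

test_that("per-sample calls aggregate into a cohort matrix", {
  spec <- single_event_spec(5, level_a = 0.3, depth = 400,
                            groups = c(A = 2L, B = 1L))
  co <- simulate_cohort(spec)
  cache <- new.env()
  samples <- lapply(co$reads, call_sites, precursors = co$ref$precursors,
                    cache = cache)
  cm <- aggregate_cohort(samples, co$sheet)
  expect_true(co$truth$name %in% rownames(cm$levels))
  expect_equal(ncol(cm$levels), 3L)
  # every cell populated: site is covered in all samples
  expect_true(all(!is.na(cm$levels[co$truth$name, ])))

  expect_error(aggregate_cohort(samples[c(1, 1, 2)], co$sheet),
               "duplicate")

  empty <- aggregate_cohort(list(), co$sheet[0, ])
  expect_equal(nrow(empty$levels), 0L)
})

test_that("prevalence threshold and filter use the ceiling rule", {
  expect_equal(prevalence_threshold(111, 0.07), 8L)
  expect_equal(prevalence_threshold(100, 0.07), 7L)
  expect_equal(prevalence_threshold(1, 0.07), 1L)
  expect_error(prevalence_threshold(0), "positive")

  cm8 <- make_matrix(sig_matrix(8, 111))
  expect_equal(nrow(prevalence_filter(cm8, 0.07)$levels), 1L)
  cm7 <- make_matrix(sig_matrix(7, 111))
  expect_equal(nrow(prevalence_filter(cm7, 0.07)$levels), 0L)
  expect_equal(nrow(prevalence_filter(cm7, 0)$levels), 1L)

  # row set is monotone non-increasing in the fraction
  set.seed(3)
  sig <- matrix(runif(20 * 30) < 0.2, 20, 30,
                dimnames = list(sprintf("p1_%d_A_g", 1:20),
                                sprintf("S%03d", 1:30)))
  cm <- make_matrix(sig)
  prev <- Inf
  for (f in c(0, 0.05, 0.1, 0.2, 0.5)) {
    n <- nrow(prevalence_filter(cm, f)$levels)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("SNP annotation needs position, alleles and a 100% level", {
  p_plus <- fixture_precursor()
  # site at precursor pos 16 -> genomic 101 + 15 = 116, ref A alt G
  snps <- data.frame(rsid = "rs1", chrom = "chrT", g_pos = 116L,
                     ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  base <- function(maxlev) {
    lev <- matrix(c(maxlev, 0.3), 1, 2,
                  dimnames = list("hsa-mir-sim1_16_A_g", c("S1", "S2")))
    make_matrix(matrix(TRUE, 1, 2, dimnames = dimnames(lev)),
                levels = lev,
                sites = data.frame(name = "hsa-mir-sim1_16_A_g",
                                   precursor = "hsa-mir-sim1",
                                   position = 16L, ref = "A", alt = "g",
                                   category = "A-to-I",
                                   region = "central",
                                   stringsAsFactors = FALSE))
  }
  out <- annotate_snps(base(1.0), snps, list(`hsa-mir-sim1` = p_plus))
  expect_equal(out$sites$category, "SNP")
  out2 <- annotate_snps(base(0.8), snps, list(`hsa-mir-sim1` = p_plus))
  expect_equal(out2$sites$category, "A-to-I")
  swapped <- snps
  swapped$ref_allele <- "G"
  swapped$alt_allele <- "A"
  out3 <- annotate_snps(base(1.0), swapped, list(`hsa-mir-sim1` = p_plus))
  expect_equal(out3$sites$category, "A-to-I")

  # minus-strand precursor: alleles compare reverse-complemented
  p_minus <- p_plus
  p_minus$strand <- "-"
  snps_m <- data.frame(rsid = "rs2", chrom = "chrT",
                       g_pos = p_minus$g_end - 16L + 1L,
                       ref_allele = "T", alt_allele = "C",
                       stringsAsFactors = FALSE)
  out4 <- annotate_snps(base(1.0), snps_m, list(`hsa-mir-sim1` = p_minus))
  expect_equal(out4$sites$category, "SNP")
})

test_that("pseudo flagging requires a strict majority mapped elsewhere", {
  p <- fixture_precursor()
  cm <- make_matrix(
    matrix(TRUE, 1, 1, dimnames = list("hsa-mir-sim1_16_A_g", "S1")),
    sites = data.frame(name = "hsa-mir-sim1_16_A_g",
                       precursor = "hsa-mir-sim1", position = 16L,
                       ref = "A", alt = "g", category = "A-to-I",
                       region = "central", stringsAsFactors = FALSE))
  sup <- function(counts, elsewhere_perfect) {
    aln <- make_alignment(sprintf("e%d", seq_along(counts)), "chrT",
                          106L, count = counts,
                          precursor_id = "hsa-mir-sim1")
    aln$ops <- replicate(nrow(aln), data.frame(
      p_pos = 16L, ref = "A", alt = "g", kind = "substitution",
      stringsAsFactors = FALSE), simplify = FALSE)
    hits <- do.call(rbind, lapply(seq_along(counts), function(i) {
      h <- make_hits(sprintf("e%d", i), 106L, 1L)
      if (elsewhere_perfect[i])
        h <- rbind(h, make_hits(sprintf("e%d", i), 9000L, 0L))
      h
    }))
    flag_pseudo(cm, aln, hits, list(`hsa-mir-sim1` = p))
  }
  expect_equal(sup(c(6L, 4L), c(TRUE, FALSE))$sites$category, "pseudo")
  expect_equal(sup(c(6L, 4L), c(FALSE, FALSE))$sites$category, "A-to-I")
  # exactly 50% explainable stays unflagged (strict >)
  expect_equal(sup(c(5L, 5L), c(TRUE, FALSE))$sites$category, "A-to-I")
})

test_that("conservation needs same type and mature position in another species", {
  p <- fixture_precursor()
  cm <- make_matrix(
    matrix(TRUE, 1, 1, dimnames = list("hsa-mir-sim1_16_A_g", "S1")),
    sites = data.frame(name = "hsa-mir-sim1_16_A_g",
                       precursor = "hsa-mir-sim1", position = 16L,
                       ref = "A", alt = "g", category = "A-to-I",
                       region = "central", stringsAsFactors = FALSE))
  # precursor pos 16 = mature position 11 on the 5p arm (starts at 6)
  tbl <- data.frame(species = "mml", mature_name = "hsa-mir-sim1-5p",
                    mature_pos = 11L, type = "A-to-I",
                    stringsAsFactors = FALSE)
  out <- annotate_conservation(cm, tbl, list(`hsa-mir-sim1` = p))
  expect_true(out$sites$conserved)
  tbl$type <- "C-to-U"
  out2 <- annotate_conservation(cm, tbl, list(`hsa-mir-sim1` = p))
  expect_false(out2$sites$conserved)
  out3 <- annotate_conservation(cm, tbl[0, ], list(`hsa-mir-sim1` = p))
  expect_false(out3$sites$conserved)
})

test_that("category summaries report one-decimal percentages", {
  counts <- c(`3'-A` = 515L, `3'-U` = 456L, `3'-Other` = 76L,
              `5'-editing` = 55L, SNP = 30L, `A-to-I` = 27L, Other = 13L,
              pseudo = 6L, `C-to-U` = 4L)
  cats <- rep(names(counts), counts)
  out <- category_summary(cats)
  expect_equal(sum(out$count), 1182L)
  expect_equal(out$pct[out$category == "3'-A"], 43.6)
  expect_equal(out$pct[out$category == "3'-U"], 38.6)
  expect_equal(out$pct[out$category == "A-to-I"], 2.3)
  expect_equal(out$pct[out$category == "C-to-U"], 0.3)
  expect_equal(out$pct[out$category == "3'-Other"], 6.4)
  expect_equal(out$pct[out$category == "Other"], 1.1)

  expect_equal(category_summary("A-to-I")$pct, 100)
  two <- category_summary(c("A-to-I", "C-to-U"))
  expect_equal(two$pct, c(50, 50))
  expect_equal(nrow(category_summary(character(0))), 0L)

  # percentages recompute from counts exactly (half away from zero)
  set.seed(9)
  for (i in 1:5) {
    cats <- sample(letters[1:4], 37, replace = TRUE)
    out <- category_summary(cats)
    expect_equal(out$pct,
                 round_half_up(100 * out$count / sum(out$count), 1))
  }
})

test_that("flanking-base distributions reflect the sequence context", {
  p <- fixture_precursor()     # position 16 sits in a T A G context
  sites <- data.frame(name = "s", precursor = "hsa-mir-sim1",
                      position = 16L, category = "A-to-I",
                      stringsAsFactors = FALSE)
  out <- neighbor_base_distribution(sites, list(`hsa-mir-sim1` = p),
                                    "A-to-I")
  expect_equal(out$p5, c(U = 1))
  expect_equal(out$p3, c(G = 1))
  empty <- neighbor_base_distribution(sites, list(`hsa-mir-sim1` = p),
                                      "C-to-U")
  expect_length(empty$p5, 0L)
})

test_that("end-edit histograms match a brute-force recount", {
  one <- data.frame(precursor = "p1", position = c(72L, 75L),
                    region = "end3", stringsAsFactors = FALSE)
  out <- end_edit_distribution(one)
  expect_equal(out$k, 2L)
  expect_equal(out$n_precursors, 1L)
  expect_equal(nrow(end_edit_distribution(one[0, ])), 0L)

  set.seed(21)
  for (i in 1:20) {
    sites <- data.frame(
      precursor = sample(paste0("p", 1:5), 30, replace = TRUE),
      position = sample(1:80, 30, replace = TRUE),
      region = sample(c("end5", "central", "end3"), 30, replace = TRUE),
      stringsAsFactors = FALSE)
    sites <- sites[!duplicated(sites[c("precursor", "position",
                                       "region")]), ]
    out <- end_edit_distribution(sites)
    for (r in unique(out$region)) {
      sub <- sites[sites$region == r, ]
      cnt <- table(tapply(sub$position, sub$precursor,
                          function(x) length(unique(x))))
      got <- out[out$region == r, ]
      expect_equal(got$n_precursors[order(got$k)],
                   as.integer(cnt[order(as.integer(names(cnt)))]))
    }
  }
})
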