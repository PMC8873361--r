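# Mann-Whitney machinery, BH adjustment and the group comparison.

test_that("Mann-Whitney U matches hand results and the enumeration oracle", {
  res <- mann_whitney_u(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  same <- mann_whitney_u(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))
  expect_equal(same$U, 4.5)                 # n_a * n_b / 2
  expect_equal(same$p, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")

  # all 3x3 multisets over {0, 0.5, 1}: agreement with brute force
  vals <- c(0, 0.5, 1)
  sets <- unique(t(apply(expand.grid(vals, vals, vals), 1, sort)))
  for (i in seq_len(nrow(sets))) for (j in seq_len(nrow(sets))) {
    a <- sets[i, ]
    b <- sets[j, ]
    expect_equal(mann_whitney_u(a, b)$p, mwu_enum_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate MWU p agree for moderate samples", {
  set.seed(14)
  for (i in 1:100) {
    a <- runif(8)
    b <- runif(8)                           # tie-free w.p. 1
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    exact_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = TRUE))$p.value
    # the continuity-corrected approximation deviates from the exact
    # distribution by at most ~0.011 at these sample sizes
    expect_lt(abs(approx_p - exact_p), 0.011)
    # and the small-sample path here is the exact one
    expect_equal(mann_whitney_u(a[1:6], b[1:6])$p,
                 suppressWarnings(stats::wilcox.test(
                   a[1:6], b[1:6], exact = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    # independent step-up construction
    m <- length(p)
    o <- order(p)
    stepped <- pmin(1, cummin((p[o] * m / seq_len(m))[m:1])[m:1])
    manual <- numeric(m)
    manual[o] <- stepped
    expect_equal(bh_adjust(p), manual, tolerance = 1e-12)
    expect_true(all(diff(sort(bh_adjust(p))) >= -1e-12))
  }
})

test_that("differential editing applies the callable-zero policy", {
  lev <- matrix(c(0.5, 0.5, NA, 0.1, 0.1, 0.1), 1, 6,
                dimnames = list("p1_10_A_g", sprintf("S%d", 1:6)))
  cov <- matrix(c(100, 100, 50, 100, 100, 5), 1, 6,
                dimnames = dimnames(lev))
  sig <- matrix(TRUE, 1, 6, dimnames = dimnames(lev))
  cm <- structure(list(
    levels = lev, coverage = cov, significant = sig,
    sites = data.frame(name = "p1_10_A_g", precursor = "p1",
                       position = 10L, ref = "A", alt = "g",
                       category = "A-to-I", region = "central",
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("S%d", 1:6),
                         group = rep(c("A", "B"), each = 3),
                         stringsAsFactors = FALSE)),
    class = "cohort_matrix")
  rec <- differential_editing(cm, "A", "B")
  # S3 callable (cov 50) enters as level 0; S6 (cov 5) is excluded
  expect_equal(rec$n_a, 3L)
  expect_equal(rec$n_b, 2L)
  expect_equal(rec$median_a, 0.5)
  expect_equal(rec$direction, "increased")
  expect_error(differential_editing(cm, "A", "Z"), "unknown")

  # identical groups: p = 1, never flagged
  lev2 <- matrix(0.2, 1, 6, dimnames = dimnames(lev))
  cm$levels <- lev2
  cm$coverage <- matrix(100, 1, 6, dimnames = dimnames(lev))
  rec2 <- differential_editing(cm, "A", "B")
  expect_equal(rec2$p_raw, 1)
  expect_false(rec2$sig_raw)
})

test_that("differential summaries print two-decimal percentages", {
  rec <- data.frame(
    site = sprintf("s%03d", 1:129),
    direction = rep(c("increased", "decreased"), c(76, 53)),
    sig_raw = TRUE, sig_fdr = FALSE, stringsAsFactors = FALSE)
  out <- differential_summary(rec, tier = "raw")
  expect_equal(out$n_flagged, 129L)
  expect_equal(out$direction$pct[out$direction$direction == "increased"],
               58.91)
  expect_equal(out$direction$pct[out$direction$direction == "decreased"],
               41.09)
  expect_equal(sum(out$direction$pct), 100)

  cats <- stats::setNames(rep(c("3'-end", "A-to-I(G)", "Other"),
                              c(115, 1, 13)), rec$site)
  out2 <- differential_summary(rec, tier = "raw", categories = cats)
  expect_equal(out2$category$pct[out2$category$category == "3'-end"],
               89.15)
  expect_equal(out2$category$pct[out2$category$category == "A-to-I(G)"],
               0.78)

  # increased + decreased percentages sum to 100.00 for random flag sets
  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:200, 1)
    r <- data.frame(site = sprintf("x%d", 1:n),
                    direction = sample(c("increased", "decreased"), n,
                                       replace = TRUE),
                    sig_raw = TRUE, sig_fdr = FALSE,
                    stringsAsFactors = FALSE)
    s <- differential_summary(r, tier = "raw")
    expect_equal(sum(s$direction$pct), 100, tolerance = 0.011)
  }
})

test_that("expression comparison flags shifted TPTM and rejects absent variants", {
  sheet <- data.frame(sample_id = sprintf("S%d", 1:12),
                      group = rep(c("A", "B"), each = 6),
                      stringsAsFactors = FALSE)
  tptm <- matrix(c(150 + 1:6, 50 + 1:6), 1, 12,
                 dimnames = list("mir-x_5c", sheet$sample_id))
  rec <- expression_compare(tptm, "mir-x_5c", sheet, "A", "B")
  expect_equal(rec$direction, "increased")
  expect_true(rec$sig_raw)

  flat <- matrix(rep(c(10, 10), 6), 1, 12,
                 dimnames = list("mir-x_5c", sheet$sample_id))
  rec2 <- expression_compare(flat, "mir-x_5c", sheet, "A", "B")
  expect_equal(rec2$p_raw, 1)

  zero <- matrix(0, 1, 12, dimnames = list("mir-x_5c", sheet$sample_id))
  expect_error(expression_compare(zero, "mir-x_5c", sheet, "A", "B"),
               "absent")
  expect_error(expression_compare(tptm, "nope", sheet, "A", "B"),
               "absent")
})
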