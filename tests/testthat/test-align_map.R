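# Precursor placement, edit-operation decomposition, genomic
# multi-mapping and cross-mapping weight correction.

test_that("exact arm reads place uniquely with no ops", {
  p <- fixture_precursor()
  aln <- align_to_precursors(make_reads(arm_seq(p, "3p")), list(p))
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$t_start, 50L)
  expect_equal(aln$t_end, 71L)
  expect_equal(aln$edits, 0L)
  expect_equal(nrow(aln$ops[[1]]), 0L)
  expect_equal(aln$weight, 1)
  expect_equal(aln$g_pos, 101L + 50L - 1L)   # genomic offset honoured
})

test_that("non-templated 3' tails and 5' additions become ops", {
  p <- fixture_precursor()
  # template base at 72 is G; appended A is untemplated
  tail_read <- paste0(arm_seq(p, "3p"), "A")
  aln <- align_to_precursors(make_reads(tail_read), list(p))
  op <- aln$ops[[1]]
  expect_equal(nrow(op), 1L)
  expect_equal(op$p_pos, 72L)
  expect_equal(op$ref, "G")
  expect_equal(op$alt, "a")
  expect_equal(op$kind, "tail3")

  # template base at 5 (one before the 5p arm) is A; prepended C
  add_read <- paste0("C", arm_seq(p, "5p"))
  aln <- align_to_precursors(make_reads(add_read), list(p))
  op <- aln$ops[[1]]
  expect_equal(op$p_pos, 5L)
  expect_equal(op$ref, "A")
  expect_equal(op$alt, "c")
  expect_equal(op$kind, "add5")
  expect_equal(aln$t_start, 6L)              # added base is untemplated
})

test_that("internal substitutions are bounded and deletions detected", {
  p <- fixture_precursor()
  arm <- arm_seq(p, "5p")

  one_sub <- arm
  substr(one_sub, 11, 11) <- if (substr(arm, 11, 11) == "A") "G" else "A"
  aln <- align_to_precursors(make_reads(one_sub), list(p))
  expect_equal(aln$edits, 1L)
  expect_equal(aln$ops[[1]]$kind, "substitution")
  expect_equal(aln$ops[[1]]$p_pos, 16L)      # arm starts at 6

  two_sub <- one_sub
  substr(two_sub, 15, 15) <- if (substr(arm, 15, 15) == "C") "T" else "C"
  aln2 <- align_to_precursors(make_reads(two_sub), list(p))
  expect_equal(nrow(aln2), 0L)
  expect_equal(attr(aln2, "log")$reads_unaligned, 1L)

  # single-base deletion: read = arm minus position 11 of the arm
  del_read <- paste0(substr(arm, 1, 10), substr(arm, 12, nchar(arm)))
  aln3 <- align_to_precursors(make_reads(del_read), list(p))
  op <- aln3$ops[[1]]
  expect_equal(op$kind, "deletion")
  expect_equal(op$p_pos, 16L)
  expect_equal(op$alt, "-")
})

test_that("genomic multimapping reports all <=1-mismatch hits", {
  p <- fixture_precursor()
  arm <- arm_seq(p, "3p")
  decoy <- arm
  substr(decoy, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                 substr(arm, 4, 4))[1]
  genome <- c(chrT = paste0(strrep("ACCTG", 20), p$seq,
                            strrep("TTGCA", 20), decoy,
                            strrep("GGATC", 10)))
  hits <- genomic_multimap(make_reads(arm), genome)
  expect_equal(nrow(hits), 2L)               # real locus + 1-mm decoy
  expect_equal(sort(hits$mismatches), c(0L, 1L))

  # reverse-strand placement
  hits_rc <- genomic_multimap(make_reads(revcomp(arm)), genome)
  expect_true(all(hits_rc$strand == "-"))
  expect_equal(nrow(hits_rc), 2L)

  # two mismatches everywhere -> no hits
  bad <- arm
  substr(bad, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(arm, 2, 2))[1]
  substr(bad, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                 substr(arm, 12, 12))[1]
  expect_equal(nrow(genomic_multimap(make_reads(bad), genome)), 0L)
})

test_that("cross-mapping correction allocates weight by perfect-match expression", {
  # shared read r0 at two loci; anchor reads establish expressions 300/100
  aln <- rbind(make_alignment("r0", "chrT", 1000, precursor_id = "p1"),
               make_alignment("r0", "chrT", 5000, precursor_id = "p2"))
  hits <- rbind(
    make_hits("r0", c(1000, 5000), c(1, 1)),
    make_hits("a1", 1001, 0),
    make_hits("a2", 5001, 0))
  aln_anchor <- rbind(
    make_alignment("a1", "chrT", 1001, count = 300L, precursor_id = "p1"),
    make_alignment("a2", "chrT", 5001, count = 100L, precursor_id = "p2"))
  res <- cross_map_correct(rbind(aln, aln_anchor), hits)
  w <- res$weight[res$read_id == "r0"]
  expect_equal(w, c(0.75, 0.25), tolerance = 1e-9)

  # single locus -> weight 1; equal expression -> 0.5/0.5
  res1 <- cross_map_correct(make_alignment("a1", "chrT", 1001),
                            make_hits("a1", 1001, 0))
  expect_equal(res1$weight, 1)
  aln_eq <- rbind(aln, make_alignment("a1", "chrT", 1001, count = 50L),
                  make_alignment("a2", "chrT", 5001, count = 50L))
  res_eq <- cross_map_correct(aln_eq, hits)
  expect_equal(res_eq$weight[res_eq$read_id == "r0"], c(0.5, 0.5),
               tolerance = 1e-9)

  # zero perfect expression everywhere -> uniform fallback
  res0 <- cross_map_correct(aln, make_hits("r0", c(1000, 5000), c(1, 1)))
  expect_equal(res0$weight, c(0.5, 0.5))
})

test_that("corrected weights conserve mass and match the fixed-point oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n_loci <- sample(2:3, 1)
    loci_pos <- c(1000, 5000, 9000)[seq_len(n_loci)]
    n_shared <- sample(2:5, 1)
    aln <- list()
    hits <- list()
    for (r in seq_len(n_shared)) {
      rid <- paste0("s", r)
      mine <- sort(sample(seq_len(n_loci), sample(2:n_loci, 1)))
      perfect <- sample(c(0L, 1L), length(mine), replace = TRUE)
      for (k in seq_along(mine))
        aln[[length(aln) + 1L]] <- make_alignment(
          rid, "chrT", loci_pos[mine[k]], count = sample(1:20, 1),
          precursor_id = paste0("p", mine[k]))
      hits[[length(hits) + 1L]] <- make_hits(rid, loci_pos[mine], perfect)
    }
    for (l in seq_len(n_loci)) {           # unique anchors per locus
      rid <- paste0("anchor", l)
      aln[[length(aln) + 1L]] <- make_alignment(
        rid, "chrT", loci_pos[l] + 1, count = sample(1:300, 1),
        precursor_id = paste0("p", l))
      hits[[length(hits) + 1L]] <- make_hits(rid, loci_pos[l] + 1, 0)
    }
    aln <- do.call(rbind, aln)
    # counts in hits follow alignment counts inside cross_map_correct
    res <- cross_map_correct(aln, do.call(rbind, hits))
    lw <- attr(res, "locus_weights")
    sums <- tapply(lw$w, lw$read_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))

    counts <- res$count[!duplicated(res$read_id)]
    names(counts) <- res$read_id[!duplicated(res$read_id)]
    rl <- lw
    rl$count <- as.integer(counts[rl$read_id])
    expect_equal(lw$w, crossmap_oracle(rl), tolerance = 1e-5)
  }
})

test_that("raising a locus's perfect expression never lowers its share", {
  base_anchor <- function(cnt) rbind(
    make_alignment("a1", "chrT", 1001, count = cnt, precursor_id = "p1"),
    make_alignment("a2", "chrT", 5001, count = 100L, precursor_id = "p2"))
  shared <- rbind(make_alignment("r0", "chrT", 1000, precursor_id = "p1"),
                  make_alignment("r0", "chrT", 5000, precursor_id = "p2"))
  hits <- rbind(make_hits("r0", c(1000, 5000), c(1, 1)),
                make_hits("a1", 1001, 0), make_hits("a2", 5001, 0))
  shares <- vapply(c(50L, 100L, 200L, 400L), function(cnt) {
    res <- cross_map_correct(rbind(shared, base_anchor(cnt)), hits)
    res$weight[res$read_id == "r0" & res$g_pos == 1000]
  }, 0)
  expect_true(all(diff(shares) > 0))
})
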