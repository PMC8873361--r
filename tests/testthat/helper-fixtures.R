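# Fixtures built in code: a deterministic hairpin with two arms, read
# constructors, and small alignment/hit tables for the cross-mapping
# tests.

# An 80-nt hairpin with arms at 6-27 (5p) and 50-71 (3p).  Key template
# bases are pinned: position 5 (one before the 5p arm) is A, position 72
# (one past the 3p arm) is G, position 16 (central 5p) is A with a T/G
# (U/G) flanking context.
fixture_precursor <- function(id = "hsa-mir-sim1") {
  s <- paste(withr::with_seed(424242,
    sample(c("A", "C", "G", "T"), 80, replace = TRUE)), collapse = "")
  substr(s, 5, 5) <- "A"      # upstream of 5p arm start
  substr(s, 15, 17) <- "TAG"  # central A in U_G context
  substr(s, 72, 72) <- "G"    # past the 3p arm end
  precursor(id, s, chrom = "chrT", g_start = 101, g_end = 180,
            strand = "+",
            arms = data.frame(name = paste0(id, c("-5p", "-3p")),
                              p_start = c(6L, 50L), p_end = c(27L, 71L)))
}

arm_seq <- function(p, arm = "5p") {
  a <- p$arms[endsWith(p$arms$name, arm), ]
  substr(p$seq, a$p_start, a$p_end)
}

make_reads <- function(seqs, q = 40L, count = 1L,
                       ids = sprintf("r%03d", seq_along(seqs))) {
  if (!length(seqs))
    return(data.frame(id = character(), seq = character(),
                      qual = character(), count = integer(),
                      stringsAsFactors = FALSE))
  data.frame(id = ids, seq = toupper(seqs),
             qual = strrep(intToUtf8(33L + q), nchar(seqs)),
             count = as.integer(count), stringsAsFactors = FALSE)
}

# Minimal alignment row for cross-mapping tests (no ops needed).
make_alignment <- function(read_id, chrom, g_pos, strand = "+",
                           weight = 1, count = 1L,
                           precursor_id = "p1") {
  df <- data.frame(read_id = read_id, seq = "", count = count,
                   precursor_id = precursor_id, p_offset = 1L,
                   t_start = 1L, t_end = 20L, edits = 0L,
                   weight = weight, chrom = chrom, g_pos = g_pos,
                   strand = strand, stringsAsFactors = FALSE)
  df$ops <- replicate(nrow(df), data.frame(
    p_pos = integer(), ref = character(), alt = character(),
    kind = character(), stringsAsFactors = FALSE), simplify = FALSE)
  df
}

make_hits <- function(read_id, g_pos, mismatches, chrom = "chrT",
                      strand = "+") {
  data.frame(read_id = read_id, chrom = chrom, g_pos = g_pos,
             strand = strand, mismatches = as.integer(mismatches),
             stringsAsFactors = FALSE)
}

# Independent fixed-point oracle for the cross-mapping correction: plain
# repeated application of the proportional-allocation map.
crossmap_oracle <- function(rl, iters = 10000) {
  by_read <- split(seq_len(nrow(rl)), rl$read_id)
  w <- unsplit(lapply(by_read, function(i) rep(1 / length(i),
                                               length(i))), rl$read_id)
  for (it in seq_len(iters)) {
    expr <- tapply(rl$count * w * rl$perfect, rl$locus, sum)
    for (r in names(by_read)) {
      i <- by_read[[r]]
      if (length(i) == 1L) next
      e <- as.numeric(expr[as.character(rl$locus[i])])
      e[is.na(e)] <- 0
      w[i] <- if (sum(e) > 0) e / sum(e) else rep(1 / length(i),
                                                  length(i))
    }
  }
  w
}

# Brute-force two-sided permutation p for the Mann-Whitney U statistic.
mwu_enum_oracle <- function(a, b) {
  comb <- c(a, b)
  n <- length(a)
  N <- length(comb)
  r <- rank(comb)
  centre <- n * (N - n) / 2
  obs <- abs(sum(r[seq_len(n)]) - n * (n + 1) / 2 - centre)
  cs <- utils::combn(N, n)
  Us <- colSums(matrix(r[cs], nrow = n)) - n * (n + 1) / 2
  mean(abs(Us - centre) >= obs - 1e-12)
}

# A 1-precursor simulation spec with a single planted event (or none).
single_event_spec <- function(seed, type = "A-to-I", ref = "A",
                              alt = "g", level_a = 0.2,
                              level_b = level_a, depth = 1000L,
                              groups = c(A = 1L, B = 1L)) {
  ev <- if (is.null(type)) {
    data.frame(precursor_idx = integer(), arm = character(),
               type = character(), ref = character(), alt = character(),
               level_a = double(), level_b = double(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(precursor_idx = 1L, arm = "5p", type = type, ref = ref,
               alt = alt, level_a = level_a, level_b = level_b,
               stringsAsFactors = FALSE)
  }
  simulation_spec(seed = seed, n_precursors = 1L, depth = depth,
                  groups = groups, events = ev, extra_decoys = 0L)
}
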