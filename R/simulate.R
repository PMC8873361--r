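# Synthetic-data generation with known ground truth.  The generator
# emulates the statistical structure the analysis assumes: hairpin-derived
# reads at a configurable depth with small 5'/3' trimming jitter, planted
# editing events of every category at per-group true levels, homozygous
# SNPs, i.i.d. per-base sequencing error tied to a constant quality
# string, duplicated decoy loci for cross-mapping and pseudo-site tests,
# and PAR-CLIP style reads with T-to-C conversions.

#' Default plan of planted editing events
#'
#' One event of each category across ten precursors: 3'-A, 3'-U,
#' 3'-Other, 5'-editing, central A-to-I, C-to-U, Other, a deletion, a
#' homozygous SNP and a pseudo site backed by a decoy locus.  Central
#' events sit at mature position 11; 5'/3' events immediately outside the
#' arm.  Levels are 0.3 in both groups except the 5'-editing site
#' (0.4 vs 0.1, the group-differential event) and the SNP (1.0).
#'
#' @return data.frame with `precursor_idx`, `arm`, `type`, `ref`, `alt`,
#'   `level_a`, `level_b`.
#' @export
default_editing_plan <- function() {
  data.frame(
    precursor_idx = 1:10,
    arm = "5p",
    type = c("3'-A", "3'-U", "3'-Other", "5'-editing", "A-to-I",
             "C-to-U", "Other", "deletion", "SNP", "pseudo"),
    ref = c("G", "G", "A", "A", "A", "C", "T", "A", "G", "C"),
    alt = c("a", "t", "c", "c", "g", "t", "a", "-", "a", "t"),
    level_a = c(0.3, 0.3, 0.3, 0.4, 0.3, 0.3, 0.3, 0.3, 1.0, 0.3),
    level_b = c(0.3, 0.3, 0.3, 0.1, 0.3, 0.3, 0.3, 0.3, 1.0, 0.3),
    stringsAsFactors = FALSE)
}

#' Build a simulation specification
#'
#' Collects every knob of the synthetic cohort in one object.  Defaults
#' describe a two-group brain-cohort design (28 disease vs 38 control
#' prefrontal-cortex samples), 80-nt hairpins with 22-nt arms, per-arm
#' depth 1000 and a Q30-equivalent error rate of 1e-3.
#'
#' @param seed master seed; all outputs are deterministic given it.
#' @param n_precursors number of hairpins.
#' @param prec_len hairpin length (nt).
#' @param arm_len mature arm length (nt).
#' @param depth reads per arm per sample.
#' @param error_rate i.i.d. per-base sequencing error probability; the
#'   emitted constant quality string encodes the matching Phred score.
#' @param trim_prob probability of 1-nt templated trimming at each read
#'   end (end heterogeneity).
#' @param groups named integer vector of group sizes.
#' @param events editing plan (see [default_editing_plan()]).
#' @param extra_decoys number of exact decoy copies of otherwise
#'   event-free arms embedded in the genome (multi-mapping test beds).
#' @param spacer random genomic spacer between embedded loci (nt).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_precursors = 10L, prec_len = 80L,
                            arm_len = 22L, depth = 1000L,
                            error_rate = 1e-3, trim_prob = 0.2,
                            groups = c("HD-PC" = 28L, "PC" = 38L),
                            events = default_editing_plan(),
                            extra_decoys = 1L, spacer = 40L) {
  if (error_rate <= 0 || error_rate > 0.01)
    stop("error_rate must be in (0, 0.01]")
  if (any(events$level_a < 0 | events$level_a > 1 |
            events$level_b < 0 | events$level_b > 1))
    stop("true levels must lie in [0, 1]")
  if (any(events$precursor_idx > n_precursors))
    stop("event refers to a precursor beyond n_precursors")
  if (is.null(names(groups)) || length(groups) < 1L)
    stop("groups must be a named vector of sizes")
  structure(list(seed = as.integer(seed),
                 n_precursors = as.integer(n_precursors),
                 prec_len = as.integer(prec_len),
                 arm_len = as.integer(arm_len),
                 depth = as.integer(depth), error_rate = error_rate,
                 trim_prob = trim_prob, groups = groups, events = events,
                 extra_decoys = as.integer(extra_decoys),
                 spacer = as.integer(spacer)),
            class = "simulation_spec")
}

# Arm layout: 5p arm starts at 6; 3p arm ends 5 nt before the hairpin end.
.arm_coords <- function(spec) {
  a5 <- c(6L, 6L + spec$arm_len - 1L)
  a3 <- c(spec$prec_len - 5L - spec$arm_len + 1L, spec$prec_len - 5L)
  if (a5[2L] >= a3[1L]) stop("precursor too short for two arms")
  list(`5p` = a5, `3p` = a3)
}

# Absolute precursor position of an event.
.event_position <- function(spec, ev) {
  arms <- .arm_coords(spec)
  a <- arms[[ev$arm]]
  switch(ev$type,
         "3'-A" = , "3'-U" = , "3'-Other" = a[2L] + 1L,
         "5'-editing" = a[1L] - 1L,
         a[1L] + 10L)                      # central events: mature pos 11
}

#' Generate the synthetic reference
#'
#' Builds hairpin sequences satisfying the event plan's template
#' requirements (reference base at each planted position; a U/G flanking
#' context for A-to-I events and a C/C context for C-to-U events), embeds
#' them in a synthetic genome together with decoy loci (exact arm copies,
#' plus an edited-arm copy for every planted pseudo event), and derives
#' the SNP table and truth table.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genome` (named character), `precursors` (named list
#'   of [precursor]), `snps` (data.frame), `truth` (data.frame: one row
#'   per planted event with expected site `name`, `category`, `type`,
#'   `position`, per-group levels) and `decoys`.
#' @export
simulate_reference <- function(spec) {
  with_seed(spec$seed, {
    arms <- .arm_coords(spec)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(spec$n_precursors), function(i)
      paste(sample(bases, spec$prec_len, replace = TRUE), collapse = ""),
      "")
    ids <- sprintf("sim-mir-%02d", seq_len(spec$n_precursors))

    ev <- spec$events
    ev$position <- vapply(seq_len(nrow(ev)), function(i)
      .event_position(spec, ev[i, ]), 0L)
    # impose template requirements
    for (i in seq_len(nrow(ev))) {
      s <- seqs[ev$precursor_idx[i]]
      pos <- ev$position[i]
      substr(s, pos, pos) <- ev$ref[i]
      if (ev$type[i] == "A-to-I") {        # U(-1)/G(+1) ADAR context
        substr(s, pos - 1L, pos - 1L) <- "T"
        substr(s, pos + 1L, pos + 1L) <- "G"
      } else if (ev$type[i] %in% c("C-to-U", "pseudo")) {   # CCC motif
        substr(s, pos - 1L, pos - 1L) <- "C"
        substr(s, pos + 1L, pos + 1L) <- "C"
      } else if (ev$type[i] == "deletion") {
        # non-homopolymeric flanks keep the deleted position unambiguous
        substr(s, pos - 1L, pos - 1L) <- "C"
        substr(s, pos + 1L, pos + 1L) <- "G"
      }
      seqs[ev$precursor_idx[i]] <- s
    }

    arm_seq <- function(pi, arm) substr(seqs[pi], arms[[arm]][1L],
                                        arms[[arm]][2L])
    # decoys: an edited-arm copy per pseudo event, plus exact copies of
    # event-free arms
    decoys <- character()
    for (i in which(ev$type == "pseudo")) {
      a <- arms[[ev$arm[i]]]
      d <- arm_seq(ev$precursor_idx[i], ev$arm[i])
      k <- ev$position[i] - a[1L] + 1L
      substr(d, k, k) <- toupper(ev$alt[i])
      decoys <- c(decoys, stats::setNames(d, paste0("pseudo-decoy-",
                                                    ids[ev$precursor_idx[i]])))
    }
    free_arms <- setdiff(paste(seq_len(spec$n_precursors), "3p"),
                         paste(ev$precursor_idx, ev$arm))
    n_extra <- min(spec$extra_decoys, length(free_arms))
    if (n_extra > 0L) for (f in free_arms[seq_len(n_extra)]) {
      pi <- as.integer(strsplit(f, " ")[[1L]][1L])
      decoys <- c(decoys, stats::setNames(arm_seq(pi, "3p"),
                                          paste0("decoy-", ids[pi])))
    }

    rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                  collapse = "")
    genome <- ""
    precursors <- list()
    for (i in seq_len(spec$n_precursors)) {
      genome <- paste0(genome, rand_seq(spec$spacer))
      g_start <- nchar(genome) + 1L
      genome <- paste0(genome, seqs[i])
      precursors[[ids[i]]] <- precursor(
        id = ids[i], seq = seqs[i], chrom = "chrSim",
        g_start = g_start, g_end = nchar(genome), strand = "+",
        arms = data.frame(
          name = paste0(ids[i], c("-5p", "-3p")),
          p_start = c(arms$`5p`[1L], arms$`3p`[1L]),
          p_end = c(arms$`5p`[2L], arms$`3p`[2L])))
    }
    decoy_tbl <- data.frame(name = character(), g_start = integer(),
                            g_end = integer(), stringsAsFactors = FALSE)
    for (j in seq_along(decoys)) {
      genome <- paste0(genome, rand_seq(spec$spacer))
      g_start <- nchar(genome) + 1L
      genome <- paste0(genome, decoys[j])
      decoy_tbl <- rbind(decoy_tbl, data.frame(
        name = names(decoys)[j], g_start = g_start,
        g_end = nchar(genome), stringsAsFactors = FALSE))
    }
    genome <- paste0(genome, rand_seq(spec$spacer))
    genome <- stats::setNames(genome, "chrSim")

    snps <- data.frame(rsid = character(), chrom = character(),
                       g_pos = integer(), ref_allele = character(),
                       alt_allele = character(), stringsAsFactors = FALSE)
    truth_rows <- list()
    for (i in seq_len(nrow(ev))) {
      p <- precursors[[ids[ev$precursor_idx[i]]]]
      pos <- ev$position[i]
      expected <- switch(ev$type[i],
                         "deletion" = "indel",
                         "SNP" = "SNP",
                         "pseudo" = "pseudo",
                         ev$type[i])
      truth_rows[[i]] <- data.frame(
        name = format_site_name(p$id, pos, ev$ref[i], ev$alt[i]),
        precursor = p$id, position = pos, ref = ev$ref[i],
        alt = ev$alt[i], arm = ev$arm[i], type = ev$type[i],
        category = expected, level_a = ev$level_a[i],
        level_b = ev$level_b[i], stringsAsFactors = FALSE)
      if (ev$type[i] == "SNP")
        snps <- rbind(snps, data.frame(
          rsid = sprintf("rsSIM%04d", i), chrom = p$chrom,
          g_pos = p$g_start + pos - 1L,
          ref_allele = ev$ref[i], alt_allele = toupper(ev$alt[i]),
          stringsAsFactors = FALSE))
    }
    truth <- do.call(rbind, truth_rows) %||%
      data.frame(name = character(), stringsAsFactors = FALSE)

    list(genome = genome, precursors = precursors, snps = snps,
         truth = truth, decoys = decoy_tbl, spec = spec)
  })
}

#' Simulate one small RNA-seq sample
#'
#' Draws `depth` reads per mature arm with 0-1 nt templated trimming
#' jitter at each end, applies every planted event of the sample's group
#' at its true level (central substitutions and deletions to covering
#' reads; 3' tails appended to reads ending exactly at the arm end; 5'
#' additions prepended to reads starting exactly at the arm start), then
#' adds i.i.d. per-base errors at the spec's rate and emits a constant
#' quality string encoding that rate.
#'
#' @param ref reference from [simulate_reference()].
#' @param group group label (selects `level_a` for the first group in the
#'   spec, `level_b` otherwise).
#' @param sample_seed seed for this sample.
#' @param sample_id id prefix for read names.
#' @return data.frame of reads (`id`, `seq`, `qual`, `count`).
#' @export
simulate_sample <- function(ref, group, sample_seed,
                            sample_id = "sample") {
  spec <- ref$spec
  q <- as.integer(round(-10 * log10(spec$error_rate)))
  qchar <- intToUtf8(33L + q)
  group_a <- names(spec$groups)[1L]
  bases <- c("A", "C", "G", "T")
  with_seed(sample_seed, {
    all <- list()
    for (p in ref$precursors) {
      for (ai in seq_len(nrow(p$arms))) {
        a_start <- p$arms$p_start[ai]
        a_end <- p$arms$p_end[ai]
        arm_tag <- sub("^.*-", "", p$arms$name[ai])
        n <- spec$depth
        starts <- a_start + stats::rbinom(n, 1L, spec$trim_prob)
        ends <- a_end - stats::rbinom(n, 1L, spec$trim_prob)
        seqs <- substring(p$seq, starts, ends)
        evs <- ref$truth[ref$truth$precursor == p$id &
                           ref$truth$arm == arm_tag, , drop = FALSE]
        for (k in seq_len(nrow(evs))) {
          lvl <- if (group == group_a) evs$level_a[k] else evs$level_b[k]
          pos <- evs$position[k]
          type <- evs$type[k]
          if (type %in% c("3'-A", "3'-U", "3'-Other")) {
            sel <- ends == a_end & stats::runif(n) < lvl
            seqs[sel] <- paste0(seqs[sel], toupper(evs$alt[k]))
          } else if (type == "5'-editing") {
            sel <- starts == a_start & stats::runif(n) < lvl
            seqs[sel] <- paste0(toupper(evs$alt[k]), seqs[sel])
          } else if (type == "deletion") {
            sel <- starts <= pos & ends >= pos & stats::runif(n) < lvl
            idx <- pos - starts + 1L
            seqs[sel] <- paste0(substr(seqs[sel], 1L, idx[sel] - 1L),
                                substr(seqs[sel], idx[sel] + 1L,
                                       nchar(seqs[sel])))
          } else {                        # central substitution types
            sel <- starts <= pos & ends >= pos & stats::runif(n) < lvl
            idx <- pos - starts + 1L
            ss <- seqs[sel]
            substr(ss, idx[sel], idx[sel]) <- toupper(evs$alt[k])
            seqs[sel] <- ss
          }
        }
        # i.i.d. sequencing errors after the biological events
        len <- nchar(seqs)
        nerr <- stats::rbinom(n, len, spec$error_rate)
        for (i in which(nerr > 0L)) {
          for (bp in sample.int(len[i], nerr[i])) {
            old <- substr(seqs[i], bp, bp)
            substr(seqs[i], bp, bp) <- sample(setdiff(bases, old), 1L)
          }
        }
        all[[length(all) + 1L]] <- data.frame(
          id = sprintf("%s:%s-%s:%d", sample_id, p$id, arm_tag,
                       seq_len(n)),
          seq = seqs, qual = strrep(qchar, nchar(seqs)), count = 1L,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, all)
  })
}

#' Simulate a two-group cohort
#'
#' Per-sample seeds are derived deterministically from the master seed;
#' the truth table travels with the result.
#'
#' @param spec a [simulation_spec()].
#' @param ref optional pre-built reference (rebuilt from `spec` when
#'   missing).
#' @return list with `ref`, `sheet` (sample_id, group), `reads` (named
#'   list of read data.frames) and `truth`.
#' @export
simulate_cohort <- function(spec, ref = NULL) {
  if (is.null(ref)) ref <- simulate_reference(spec)
  sheet <- data.frame(
    sample_id = character(), group = character(), stringsAsFactors = FALSE)
  idx <- 0L
  reads <- list()
  for (g in names(spec$groups)) {
    for (k in seq_len(spec$groups[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      sheet <- rbind(sheet, data.frame(sample_id = sid, group = g,
                                       stringsAsFactors = FALSE))
      reads[[sid]] <- simulate_sample(ref, g, derive_seed(spec$seed, idx),
                                      sample_id = sid)
    }
  }
  list(ref = ref, sheet = sheet, reads = reads, truth = ref$truth)
}

# Mutate the middle base of a window (used to scrub accidental matches).
.mutate_mid <- function(seq, at, len) {
  mid <- at + len %/% 2L
  old <- substr(seq, mid, mid)
  substr(seq, mid, mid) <- c(A = "C", C = "G", G = "T", T = "A")[[old]]
  seq
}

#' Simulate PAR-CLIP evidence for miRNA variants
#'
#' Generates random transcripts, plants reverse-complement seed-match
#' sites of the requested variants, scrubs accidental seed matches
#' outside planted windows, and emits crosslink reads piled over the
#' planted sites (and over background positions without any site), each
#' read converting each covered template T to C with probability
#' `conv_rate`.
#'
#' @param variants list of `mature_variant` objects.
#' @param planted data.frame with `mrna_idx`, `variant_idx` (index into
#'   `variants`), giving one planted 8mer site per row.
#' @param n_mrnas number of transcripts.
#' @param mrna_len transcript length.
#' @param n_background number of background read clusters on
#'   transcripts beyond the planted ones.
#' @param reads_per_site reads per cluster.
#' @param read_len read length.
#' @param conv_rate per-T T-to-C conversion probability.
#' @param noncoding_idx transcript indices flagged non-coding in the
#'   annotation.
#' @param seed RNG seed.
#' @return list with `mrnas` (named character), `reads` (data.frame),
#'   `truth` (planted site table), `annotations` (mrna, gene, coding).
#' @export
simulate_parclip <- function(variants, planted, n_mrnas = 12L,
                             mrna_len = 300L, n_background = 4L,
                             reads_per_site = 20L, read_len = 25L,
                             conv_rate = 0.5, noncoding_idx = integer(),
                             seed = 1L) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    mrnas <- vapply(seq_len(n_mrnas), function(i)
      paste(sample(bases, mrna_len, replace = TRUE), collapse = ""), "")
    names(mrnas) <- sprintf("NM_SIM%03d", seq_len(n_mrnas))

    site_pos <- as.integer(round(mrna_len * 0.5))
    truth_rows <- list()
    protected <- vector("list", n_mrnas)
    for (r in seq_len(nrow(planted))) {
      v <- variants[[planted$variant_idx[r]]]
      word <- revcomp(substr(v$seq, 1L, 8L))
      # several sites on one transcript are spread apart
      prev <- sum(planted$mrna_idx[seq_len(r - 1L)] ==
                    planted$mrna_idx[r])
      at <- site_pos + prev * 60L
      mi <- planted$mrna_idx[r]
      substr(mrnas[mi], at, at + 7L) <- word
      protected[[mi]] <- rbind(protected[[mi]], c(at, at + 7L))
      truth_rows[[r]] <- data.frame(
        mrna = names(mrnas)[mi], variant = v$name, site_start = at,
        site_end = at + 7L, class = "8mer", stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth_rows)

    # scrub accidental seed matches outside the planted windows
    words6 <- unique(vapply(variants, function(v)
      revcomp(substr(v$seq, 2L, 7L)), ""))
    for (iter in 1:20) {
      dirty <- FALSE
      for (mi in seq_len(n_mrnas)) {
        for (w in words6) {
          hits <- gregexpr(w, mrnas[mi], fixed = TRUE)[[1L]]
          if (hits[1L] == -1L) next
          for (h in hits) {
            prot <- protected[[mi]]
            inside <- !is.null(prot) &&
              any(h >= prot[, 1L] - 2L & h + 5L <= prot[, 2L] + 2L)
            if (!inside) {
              mrnas[mi] <- .mutate_mid(mrnas[mi], h, nchar(w))
              dirty <- TRUE
            }
          }
        }
      }
      if (!dirty) break
    }

    emit_reads <- function(mi, centre, tag) {
      starts <- pmax(1L, pmin(mrna_len - read_len + 1L,
                              centre - read_len %/% 2L +
                                sample(-3:3, reads_per_site,
                                       replace = TRUE)))
      seqs <- substring(mrnas[mi], starts, starts + read_len - 1L)
      for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        tt <- which(ch == "T")
        conv <- tt[stats::runif(length(tt)) < conv_rate]
        ch[conv] <- "C"
        seqs[i] <- paste(ch, collapse = "")
      }
      data.frame(id = sprintf("%s:%s:%d", tag, names(mrnas)[mi],
                              seq_along(seqs)),
                 seq = seqs, qual = strrep("?", nchar(seqs)), count = 1L,
                 stringsAsFactors = FALSE)
    }

    reads <- list()
    for (r in seq_len(nrow(truth)))
      reads[[length(reads) + 1L]] <-
        emit_reads(match(truth$mrna[r], names(mrnas)),
                   as.integer(truth$site_start[r] + 4L),
                   paste0("site", r))
    bg_mrnas <- setdiff(seq_len(n_mrnas), planted$mrna_idx)
    for (b in seq_len(min(n_background, length(bg_mrnas))))
      reads[[length(reads) + 1L]] <-
        emit_reads(bg_mrnas[b], as.integer(mrna_len * 0.3),
                   paste0("bg", b))
    reads <- do.call(rbind, reads)

    annotations <- data.frame(
      mrna = names(mrnas), gene = sprintf("GENE%03d", seq_len(n_mrnas)),
      coding = !(seq_len(n_mrnas) %in% noncoding_idx),
      stringsAsFactors = FALSE)
    list(mrnas = mrnas, reads = reads, truth = truth,
         annotations = annotations)
  })
}

#' Write the reference and cohort to disk
#'
#' Emits the standard external representations: genome FASTA, precursor
#' FASTA + annotation TSV, SNP TSV, sample sheet TSV, truth TSV and one
#' FASTQ per sample.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- cohort$ref
  writeLines(paste0(">", names(ref$genome), "\n", ref$genome),
             file.path(dir, "genome.fa"))
  write_precursors(ref$precursors, file.path(dir, "hairpins.fa"),
                   file.path(dir, "hairpins.tsv"))
  utils::write.table(ref$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in names(cohort$reads))
    write_fastq(cohort$reads[[sid]], file.path(dir, paste0(sid, ".fastq")))
  invisible(dir)
}
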