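# Small shared helpers: alphabet conversion, rounding, seeded evaluation.

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(chartr("ACGTUacgtu", "TGCAAtgcaa", x), function(s)
    intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# All (possibly overlapping) start positions of a fixed pattern.
fixed_starts <- function(pattern, subject) {
  out <- integer(0)
  from <- 1L
  n <- nchar(subject)
  pl <- nchar(pattern)
  while (from + pl - 1L <= n) {
    r <- regexpr(pattern, substr(subject, from, n), fixed = TRUE)
    if (r == -1L) break
    s <- from + as.integer(r) - 1L
    out <- c(out, s)
    from <- s + 1L
  }
  out
}

# Candidate start positions of `pattern` in `subject` with at most
# `max_mm` mismatches, by the pigeonhole principle: the pattern is split
# into max_mm + 1 chunks, one of which must match exactly.  Returns a
# superset of the true positions; callers verify.
pigeon_starts <- function(pattern, subject, max_mm) {
  pl <- nchar(pattern)
  k <- max_mm + 1L
  bounds <- unique(round(seq(0L, pl, length.out = k + 1L)))
  cand <- integer(0)
  for (j in seq_len(length(bounds) - 1L)) {
    from <- bounds[j] + 1L
    to <- bounds[j + 1L]
    if (to < from) next
    s <- fixed_starts(substr(pattern, from, to), subject)
    cand <- c(cand, s - (from - 1L))
  }
  cand <- unique(as.integer(cand))
  sort(cand[cand >= 1L & cand + pl - 1L <= nchar(subject)])
}

# Mismatch count between a pattern (as utf8 ints) and subject ints at a
# given start.
mm_at <- function(pat_int, subj_int, start) {
  sum(pat_int != subj_int[start:(start + length(pat_int) - 1L)])
}

# U <-> T conversion. Sequences are held internally in the DNA alphabet so
# that genome comparison is uniform; site names render in RNA.
to_dna <- function(x) chartr("Uu", "Tt", x)
to_rna <- function(x) chartr("Tt", "Uu", x)

#' Round half away from zero
#'
#' Percentages in summary tables are rounded half-away-from-zero (so 0.25 at
#' one digit becomes 0.3), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Phred+33 quality decoding (one string -> integer vector).
phred_ints <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-unit seed from a master seed
#'
#' Deterministic seed derivation used for per-sample and per-replicate
#' randomness; results stay inside the 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param index unit index (integer).
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + index * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
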