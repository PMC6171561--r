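# Internal helpers shared across stages.
#
# Coordinate convention: 0-based half-open everywhere in memory; writers and
# readers convert to/from 1-based inclusive at the file boundary.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorised reverse complement on plain character vectors (DNA alphabet)
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

rnaify <- function(x) chartr("Tt", "Uu", toupper(x))
dnaify <- function(x) chartr("Uu", "Tt", toupper(x))

# number of mismatches of `pattern` (IUPAC R allowed) at each offset of `seq`;
# returns integer vector of length nchar(seq) - nchar(pattern) + 1 (or empty)
motifMismatches <- function(seq, pattern) {
  n <- nchar(seq)
  k <- nchar(pattern)
  if (n < k) return(integer())
  sq <- strsplit(seq, "")[[1]]
  pt <- strsplit(pattern, "")[[1]]
  allowed <- lapply(pt, function(b) switch(b, R = c("A", "G"), b))
  vapply(seq_len(n - k + 1L), function(off) {
    sum(vapply(seq_len(k), function(i) !(sq[off + i - 1L] %in% allowed[[i]]),
               logical(1)))
  }, integer(1))
}

# 0-based half-open -> 1-based inclusive (for writers)
toOneBased <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

# 1-based inclusive -> 0-based half-open (for readers)
toZeroBased <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

# deterministic per-purpose RNG seed derived from a master seed (< 2^31)
deriveSeed <- function(seed, salt) {
  (as.integer(seed) * 48271L + salt) %% 2147483562L
}

stopIfNot <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# sample random DNA string(s); alphabet restrictable (motif-hygiene zones)
randomDNA <- function(n, len, alphabet = DNA_BASES) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

emptyHybridTable <- function() {
  data.frame(
    read_id = character(), sample = character(), count = integer(),
    arm1_ref = character(), arm1_read_start = integer(),
    arm1_read_end = integer(), arm1_ref_start = integer(),
    arm1_ref_end = integer(),
    arm2_ref = character(), arm2_read_start = integer(),
    arm2_read_end = integer(), arm2_ref_start = integer(),
    arm2_ref_end = integer(),
    dG = numeric(),
    stringsAsFactors = FALSE
  )
}

HYBRID_COLS <- names(emptyHybridTable())
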