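#' Alignment / chimera-calling parameters
#'
#' Defaults mirror the blastn-style parameters of the hyb pipeline family:
#' word size 11, match +2 / mismatch -3, gap open 5 / extend 2, minimum
#' local score 24, minimum identity 0.9. Chimera calling requires two
#' disjoint read arms of >= `minArmLength` nt separated by at most
#' `maxGap` unaligned nt, jointly covering >= `minReadCoverage` of the
#' read; arms with more than `maxPlacements` equal-score placements are
#' ambiguous and dropped.
#'
#' @param wordSize k-mer seed length.
#' @param match,mismatch,gapOpen,gapExtend alignment scores (costs given
#'   positive).
#' @param minScore,minIdentity per-arm alignment thresholds.
#' @param minArmLength,maxGap,minReadCoverage,maxPlacements chimera-calling
#'   thresholds.
#' @param maxJunctionOverlap local alignments can extend well across the
#'   ligation junction on chance matches (the identity threshold permits
#'   dilute extensions); read intervals overlapping by up to this many nt
#'   -- and by no more than 60% of the shorter alignment, so genuine
#'   double-mappings of one fragment are never split -- are resolved by a
#'   match-maximising split (default 25).
#' @param preferenceOrder category preference on score ties, most preferred
#'   first.
#' @return list of class `ChimeraParams`.
#' @export
chimeraParams <- function(wordSize = 11L, match = 2L, mismatch = 3L,
                          gapOpen = 5L, gapExtend = 2L, minScore = 24L,
                          minIdentity = 0.9, minArmLength = 16L, maxGap = 4L,
                          maxJunctionOverlap = 25L,
                          minReadCoverage = 0.9, maxPlacements = 4L,
                          preferenceOrder = c("snoRNA", "rRNA", "mRNA",
                                              "other")) {
  structure(as.list(environment()), class = "ChimeraParams")
}

#' Local alignments of a read against the reference
#'
#' Seed-and-extend Smith-Waterman: exact `wordSize`-mers seed candidate
#' (reference, diagonal) clusters, each extended with an affine-gap local
#' alignment. Both read strands are searched; intervals are reported
#' 0-based half-open on the original read orientation, sorted by score
#' descending.
#'
#' @param read a read sequence (character scalar).
#' @param refset a [ReferenceSet].
#' @param params a [chimeraParams()].
#' @return data.frame: `reference_id`, `category`, `read_start`,
#'   `read_end`, `ref_start`, `ref_end`, `strand`, `score`, `identity`.
#' @export
alignFragments <- function(read, refset, params = chimeraParams()) {
  alignFragmentsBatch(read, refset, params)[[1L]]
}

# batch form: list of per-read alignment tables
alignFragmentsBatch <- function(reads, refset, params = chimeraParams()) {
  hits <- .sw_align_batch_cpp(reads, as.character(refSequences(refset)),
                              params$wordSize, params$minScore,
                              params$minIdentity, params$match,
                              params$mismatch, params$gapOpen,
                              params$gapExtend)
  ids <- names(refset)
  cats <- refCategory(refset)
  out <- rep(list(emptyAlignmentTable()), length(reads))
  if (nrow(hits)) {
    hits$reference_id <- ids[hits$ref_index]
    hits$category <- unname(cats[hits$ref_index])
    hits$strand <- ifelse(hits$strand > 0, "+", "-")
    byRead <- split(seq_len(nrow(hits)), hits$read_index)
    for (nm in names(byRead)) {
      h <- hits[byRead[[nm]], c("reference_id", "category", "read_start",
                                "read_end", "ref_start", "ref_end", "strand",
                                "score", "identity"), drop = FALSE]
      h <- h[order(-h$score, h$reference_id, h$read_start, h$ref_start), ,
             drop = FALSE]
      rownames(h) <- NULL
      out[[as.integer(nm)]] <- h
    }
  }
  out
}

emptyAlignmentTable <- function() {
  data.frame(reference_id = character(), category = character(),
             read_start = integer(), read_end = integer(),
             ref_start = integer(), ref_end = integer(), strand = character(),
             score = integer(), identity = numeric(), stringsAsFactors = FALSE)
}

#' Call a two-arm chimera from a read's alignments
#'
#' Chooses the highest-scoring pair of alignments covering disjoint read
#' intervals (each arm >= `minArmLength`, unaligned middle gap <= `maxGap`,
#' joint read coverage >= `minReadCoverage`). Local alignments often
#' overrun the ligation junction by a few chance matches; read intervals
#' overlapping by up to `maxJunctionOverlap` nt are resolved by the split
#' point that maximises the number of matching bases on both sides
#' (middle of the tie plateau). Among score-tied candidate pairs, pairs
#' containing
#' a snoRNA arm are preferred (then rRNA, mRNA, other), mirroring
#' preferential extraction of snoRNA hybrids. A read fully explained by
#' one alignment is `single`; an arm with more than `maxPlacements`
#' equal-score placements makes the read `ambiguous`; anything else is
#' `unmapped`. In the returned record the snoRNA arm comes first
#' (canonical order; ties by reference id then coordinate).
#'
#' @param read the read sequence (used to resolve junction overlaps).
#' @param alignments alignment table from [alignFragments()].
#' @param refset the [ReferenceSet] the alignments refer to.
#' @param params a [chimeraParams()].
#' @return list with `status` ("hybrid", "single", "ambiguous", "unmapped")
#'   and, for hybrids, `arm1`/`arm2` (one-row alignment tables, canonical
#'   order).
#' @export
callChimera <- function(read, alignments, refset, params = chimeraParams()) {
  seqChr <- setNames(as.character(refSequences(refset)), names(refset))
  callChimeraFast(read, alignments, seqChr, params)
}

# hot path shared with callHybrids: refs pre-extracted as character vector
callChimeraFast <- function(read, al, seqChr, params) {
  readLength <- nchar(read)
  if (!nrow(al)) return(list(status = "unmapped"))
  covered <- max(al$read_end - al$read_start)
  single <- covered >= params$minReadCoverage * readLength
  if (nrow(al) < 2L)
    return(list(status = if (single) "single" else "unmapped"))
  if (nrow(al) > 24L) al <- al[seq_len(24L), , drop = FALSE]  # score-sorted
  n <- nrow(al)
  pr <- match(al$category, params$preferenceOrder)
  pr[is.na(pr)] <- length(params$preferenceOrder) + 1L
  rdChars <- strsplit(read, "")[[1L]]
  arm <- lapply(seq_len(n), function(i) list(
    reference_id = al$reference_id[i], category = al$category[i],
    read_start = al$read_start[i], read_end = al$read_end[i],
    ref_start = al$ref_start[i], ref_end = al$ref_end[i],
    strand = al$strand[i], score = al$score[i], identity = al$identity[i],
    rank = pr[i]))

  best <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- arm[[i]]; b <- arm[[j]]
    if (a$read_start > b$read_start) { tmp <- a; a <- b; b <- tmp }
    gap <- b$read_start - a$read_end
    maxOv <- min(params$maxJunctionOverlap,
                 floor(0.6 * min(a$read_end - a$read_start,
                                 b$read_end - b$read_start)))
    if (gap < -maxOv || gap > params$maxGap) next
    if (gap < 0L) {
      sp <- resolveJunction(rdChars, a, b, seqChr)
      a <- sp$a; b <- sp$b
    }
    if (a$read_end - a$read_start < params$minArmLength ||
        b$read_end - b$read_start < params$minArmLength) next
    cov <- (a$read_end - a$read_start) + (b$read_end - b$read_start)
    if (cov < params$minReadCoverage * readLength) next
    # arms mapping to overlapping reference footprints are one region
    if (a$reference_id == b$reference_id &&
        a$ref_start < b$ref_end && b$ref_start < a$ref_end) next
    key <- c(-(a$score + b$score), min(a$rank, b$rank), a$rank + b$rank)
    if (is.null(best) || isKeyLess(key, best$key) ||
        (identical(key, best$key) &&
           paste(a$reference_id, b$reference_id) <
             paste(best$a$reference_id, best$b$reference_id)))
      best <- list(a = a, b = b, i = i, j = j, key = key)
  }
  if (is.null(best))
    return(list(status = if (single) "single" else "unmapped"))
  # ambiguity: equal-score alternative placements for either chosen arm
  for (idx in c(best$i, best$j)) {
    same <- al$read_start == al$read_start[idx] &
      al$read_end == al$read_end[idx] & al$score == al$score[idx]
    if (sum(same) > params$maxPlacements)
      return(list(status = "ambiguous"))
  }
  # canonical order: snoRNA arm first, then category rank, ref id, coordinate
  a <- best$a; b <- best$b
  swap <- b$rank < a$rank ||
    (b$rank == a$rank && (b$reference_id < a$reference_id ||
                            (b$reference_id == a$reference_id &&
                               b$ref_start < a$ref_start)))
  if (swap) { tmp <- a; a <- b; b <- tmp }
  list(status = "hybrid", arm1 = a, arm2 = b)
}

# choose the split of an overlapping arm pair that maximises base matches
# on both sides of the junction (middle of the tie plateau); a precedes b on
# the read and a$read_end > b$read_start
resolveJunction <- function(rdChars, a, b, seqChr) {
  bs <- b$read_start; ae <- a$read_end
  segA <- substr(seqChr[[a$reference_id]], a$ref_start + 1L, a$ref_end)
  if (a$strand == "-") segA <- revComp(segA)
  segB <- substr(seqChr[[b$reference_id]], b$ref_start + 1L, b$ref_end)
  if (b$strand == "-") segB <- revComp(segB)
  chA <- strsplit(segA, "")[[1L]]
  chB <- strsplit(segB, "")[[1L]]
  p <- bs:(ae - 1L)                      # overlap positions, 0-based
  # read-oriented bases, each arm anchored at its reliable outer end (any
  # indels a dilute junction overrun picked up then stay on the far side)
  aIdx <- p - a$read_start
  bIdx <- length(chB) - (b$read_end - p)
  safeMatch <- function(idx, ch) {
    clamped <- pmin(pmax(idx, 0L), length(ch) - 1L)
    idx >= 0L & idx < length(ch) & rdChars[p + 1L] == ch[clamped + 1L]
  }
  m1 <- safeMatch(aIdx, chA)
  m2 <- safeMatch(bIdx, chB)
  w <- length(p)
  scores <- vapply(0:w, function(k)       # split after k overlap bases
    sum(m1[seq_len(k)]) + sum(m2[if (k < w) (k + 1L):w else integer()]),
    numeric(1))
  ties <- which(scores == max(scores))    # plateau of equally good splits
  # a flat plateau means the contested bases match both references; when
  # only one arm matches the whole overlap, the other arm's overrun is a
  # chance extension, so the junction sits at that arm's plateau edge --
  # otherwise take the middle, which bounds the boundary error
  k <- if (all(m1) && !all(m2)) max(ties) - 1L
  else if (all(m2) && !all(m1)) min(ties) - 1L
  else ties[(length(ties) + 1L) %/% 2L] - 1L
  s <- bs + k
  ka <- ae - s; kb <- s - bs
  if (ka > 0L) {              # trim a back to s, measuring from its start
    a$read_end <- s
    if (a$strand == "-") a$ref_start <- a$ref_end - (s - a$read_start) else
      a$ref_end <- a$ref_start + (s - a$read_start)
  }
  if (kb > 0L) {              # trim b forward to s, measuring from its end
    b$read_start <- s
    if (b$strand == "-") b$ref_end <- b$ref_start + (b$read_end - s) else
      b$ref_start <- b$ref_end - (b$read_end - s)
  }
  list(a = a, b = b)
}

#' Call hybrids for a table of processed reads
#'
#' Runs [alignFragments()] and [callChimera()] over collapsed reads and
#' assembles the hybrid table (internal 0-based half-open coordinates;
#' written 1-based inclusive by [writeHybridTable()]).
#'
#' @param processed collapsed reads from [collapseDuplicates()] /
#'   [preprocessReads()].
#' @param refset a [ReferenceSet].
#' @param params a [chimeraParams()].
#' @return list: `hybrids` (hybrid table), `status` (per-read call status).
#' @export
callHybrids <- function(processed, refset, params = chimeraParams()) {
  alns <- alignFragmentsBatch(processed$insert, refset, params)
  seqChr <- setNames(as.character(refSequences(refset)), names(refset))
  status <- character(nrow(processed))
  rows <- vector("list", nrow(processed))
  for (r in seq_len(nrow(processed))) {
    cc <- callChimeraFast(processed$insert[r], alns[[r]], seqChr, params)
    status[r] <- cc$status
    if (cc$status == "hybrid") {
      rows[[r]] <- list(
        read_id = processed$read_id[r], sample = processed$sample_id[r],
        count = processed$duplicate_count[r],
        arm1_ref = cc$arm1$reference_id,
        arm1_read_start = cc$arm1$read_start, arm1_read_end = cc$arm1$read_end,
        arm1_ref_start = cc$arm1$ref_start, arm1_ref_end = cc$arm1$ref_end,
        arm2_ref = cc$arm2$reference_id,
        arm2_read_start = cc$arm2$read_start, arm2_read_end = cc$arm2$read_end,
        arm2_ref_start = cc$arm2$ref_start, arm2_ref_end = cc$arm2$ref_end,
        dG = NA_real_)
    }
  }
  keep <- rows[status == "hybrid"]
  hybrids <- if (length(keep)) {
    cols <- lapply(names(keep[[1L]]), function(cn)
      unlist(lapply(keep, `[[`, cn), use.names = FALSE))
    names(cols) <- names(keep[[1L]])
    as.data.frame(cols, stringsAsFactors = FALSE)
  } else emptyHybridTable()
  rownames(hybrids) <- NULL
  list(hybrids = hybrids, status = status)
}
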