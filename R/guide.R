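#' Methylation-guide classification rule (+5 rule)
#'
#' A box C/D snoRNA guides 2'-O-methylation when an extended duplex
#' (>= `minDuplexLength` bp) with the target reaches the box D (or D')
#' motif, placing the methylated nucleotide opposite the snoRNA base
#' exactly `offsetFromBox` nt upstream of the box. With
#' `requireContiguousToBox` the contiguous helix must include snoRNA
#' positions d-1 ... d-offset (d = first nt of the box).
#'
#' @param offsetFromBox nt upstream of box D/D' paired with the methylated
#'   nucleotide (default 5).
#' @param minDuplexLength minimum contiguous helix length, bp (default 12).
#' @param requireContiguousToBox the helix must reach the box (default TRUE).
#' @param allowGU count GU wobbles as pairing within the helix (default
#'   TRUE; FALSE restricts the helix to Watson-Crick pairs).
#' @return list of class `GuideRule`.
#' @export
guideRule <- function(offsetFromBox = 5L, minDuplexLength = 12L,
                      requireContiguousToBox = TRUE, allowGU = TRUE) {
  stopIfNot(offsetFromBox >= 1L, "offsetFromBox must be >= 1")
  stopIfNot(minDuplexLength >= offsetFromBox,
            "minDuplexLength must be >= offsetFromBox")
  structure(list(offsetFromBox = as.integer(offsetFromBox),
                 minDuplexLength = as.integer(minDuplexLength),
                 requireContiguousToBox = requireContiguousToBox,
                 allowGU = allowGU),
            class = "GuideRule")
}

#' Classify one snoRNA-target hybrid as guide or non-guide
#'
#' For each box present (D, then D'): if the duplex contains a contiguous
#' helix of at least `minDuplexLength` pairs including snoRNA positions
#' d-1 ... d-offset (d = 0-based box start), the target nucleotide paired
#' with snoRNA position d-offset is the predicted methylation position and
#' the call is `guide_D` / `guide_Dprime`. When both boxes validate, a
#' prediction matching an annotated site is preferred, then box D.
#' Otherwise the call is `overlapping_nonguide` if the target arm overlaps
#' any annotated methylation site on that reference, else
#' `nonoverlapping`. An unannotatable snoRNA yields `nonoverlapping` with
#' a warning flag.
#'
#' @param hybrid one-row hybrid table (snoRNA arm first, canonical order).
#' @param boxes one-row box annotation for the snoRNA (record-local
#'   0-based half-open coordinates).
#' @param duplex a [DuplexStructure] of the two arm sequences (pairs in
#'   arm-local coordinates).
#' @param sites methylation-site table (1-based positions).
#' @param rule a [guideRule()].
#' @param recordSeqs optional list of the two full record sequences
#'   (snoRNA record, target record). When supplied, the helix is measured
#'   as the maximal contiguous complementary run, at the pairing register
#'   anchored by the duplex pair of snoRNA position d-offset, over the
#'   record sequences: the guide helix is a property of the snoRNA/target
#'   region, so neither folding-engine boundary trades nor fragment ends
#'   delimit it. Required for `allowGU = FALSE`. Without sequences the
#'   helix is read directly off the duplex pair list.
#' @return one-row data.frame: `hybrid_id`, `classification`,
#'   `predicted_target_position` (1-based, NA unless guide),
#'   `matched_site` (logical), `guide_box`, `warning_flag`.
#' @export
classifyGuide <- function(hybrid, boxes, duplex, sites, rule = guideRule(),
                          recordSeqs = NULL) {
  call0 <- function(cls, pos = NA_integer_, box = NA_character_,
                    matched = NA, warn = FALSE) {
    data.frame(hybrid_id = hybrid$read_id, classification = cls,
               predicted_target_position = pos, matched_site = matched,
               guide_box = box, warning_flag = warn, stringsAsFactors = FALSE)
  }
  targetSites <- sites$position[sites$target_id == hybrid$arm2_ref]
  overlapsSite <- any(targetSites - 1L >= hybrid$arm2_ref_start &
                        targetSites - 1L < hybrid$arm2_ref_end)
  fallback <- if (overlapsSite) "overlapping_nonguide" else "nonoverlapping"

  if (is.null(boxes) || !nrow(boxes) || isTRUE(boxes$unannotatable))
    return(call0("nonoverlapping", warn = TRUE))

  pr <- duplexPairs(duplex)
  if (!nrow(pr)) return(call0(fallback))
  # arm-local -> record-local coordinates (arms are stored sense)
  snoPos <- pr[, "pos1"] + hybrid$arm1_ref_start
  tgtPos <- pr[, "pos2"] + hybrid$arm2_ref_start
  ch1 <- ch2 <- NULL
  if (!is.null(recordSeqs)) {
    ch1 <- strsplit(rnaify(recordSeqs[[1L]]), "")[[1]]
    ch2 <- strsplit(rnaify(recordSeqs[[2L]]), "")[[1]]
  }
  if (!rule$allowGU) {
    stopIfNot(!is.null(recordSeqs),
              "allowGU = FALSE needs recordSeqs to identify wobble pairs")
    keep <- paste0(ch1[snoPos + 1L], ch2[tgtPos + 1L]) %in%
      c("AU", "UA", "CG", "GC")
    snoPos <- snoPos[keep]; tgtPos <- tgtPos[keep]
    pr <- pr[keep, , drop = FALSE]
  }
  if (!nrow(pr)) return(call0(fallback))

  helixId <- cumsum(c(1L, !(diff(pr[, "pos1"]) == 1L &
                              diff(pr[, "pos2"]) == -1L)))
  okPair <- function(b1, b2) {
    pt <- paste0(b1, b2)
    pt %in% (if (rule$allowGU) PAIR_TYPES else c("AU", "UA", "CG", "GC"))
  }
  cand <- list()
  for (box in c("D", "Dprime")) {
    d <- if (box == "D") boxes$boxD_start else boxes$boxDprime_start
    if (is.na(d)) next
    p <- d - rule$offsetFromBox          # snoRNA position paired to the site
    at <- which(snoPos == p)
    if (!length(at)) next
    at <- at[1L]
    need <- (d - rule$offsetFromBox):(d - 1L)  # snoRNA positions required
    if (!is.null(recordSeqs)) {
      # maximal contiguous complementary run through p at the anchored
      # register, over the full record sequences
      reg <- snoPos[at] + tgtPos[at]     # constant along an antiparallel helix
      inRun <- function(q) {
        t <- reg - q
        q >= 0L && q < length(ch1) && t >= 0L && t < length(ch2) &&
          okPair(ch1[q + 1L], ch2[t + 1L])
      }
      if (!inRun(p)) next
      qlo <- p; while (inRun(qlo - 1L)) qlo <- qlo - 1L
      qhi <- p; while (inRun(qhi + 1L)) qhi <- qhi + 1L
      runSno <- qlo:qhi
    } else {
      idx <- which(helixId == helixId[at])
      runSno <- snoPos[idx]
    }
    if (length(runSno) < rule$minDuplexLength) next
    if (rule$requireContiguousToBox && !all(need %in% runSno)) next
    predicted <- tgtPos[at] + 1L  # 1-based target position
    matched <- any(sites$target_id == hybrid$arm2_ref &
                     sites$position == predicted)
    cand[[box]] <- list(box = box, pos = predicted, matched = matched)
  }
  if (!length(cand)) return(call0(fallback))
  pick <- if (length(cand) == 2L) {
    if (cand$Dprime$matched && !cand$D$matched) cand$Dprime else cand$D
  } else cand[[1L]]
  call0(paste0("guide_", pick$box), pick$pos, pick$box, pick$matched)
}

#' Classify every snoRNA-target hybrid in a table
#'
#' Batch driver over [classifyGuide()]: computes each hybrid's duplex (or
#' reuses the `"duplexes"` attribute left by [annotateDuplexes()]), looks
#' up the snoRNA's box annotation in the reference, and classifies.
#' Hybrids whose first arm is not a snoRNA are classified `nonoverlapping`
#' with a warning flag.
#'
#' @param hybrids hybrid table (canonical order: snoRNA arm first).
#' @param refset a [ReferenceSet] with boxes and methylation sites.
#' @param rule a [guideRule()].
#' @param model an [EnergyModel] (used only if duplexes are not attached).
#' @return data.frame of guide calls, one row per hybrid.
#' @export
classifyGuides <- function(hybrids, refset, rule = guideRule(),
                           model = defaultEnergyModel()) {
  if (!nrow(hybrids)) {
    return(data.frame(hybrid_id = character(), classification = character(),
                      predicted_target_position = integer(),
                      matched_site = logical(), guide_box = character(),
                      warning_flag = logical(), stringsAsFactors = FALSE))
  }
  duplexes <- attr(hybrids, "duplexes")
  if (is.null(duplexes)) {
    hybrids <- annotateDuplexes(hybrids, refset, model)
    duplexes <- attr(hybrids, "duplexes")
  }
  boxes <- boxAnnotations(refset)
  sites <- methylationSites(refset)
  cats <- refCategory(refset)
  seqChr <- setNames(as.character(refSequences(refset)), names(refset))
  rows <- vector("list", nrow(hybrids))
  for (r in seq_len(nrow(hybrids))) {
    h <- hybrids[r, ]
    if (cats[[h$arm1_ref]] != "snoRNA") {
      rows[[r]] <- data.frame(hybrid_id = h$read_id,
                              classification = "nonoverlapping",
                              predicted_target_position = NA_integer_,
                              matched_site = NA, guide_box = NA_character_,
                              warning_flag = TRUE, stringsAsFactors = FALSE)
      next
    }
    bx <- boxes[boxes$snorna_id == h$arm1_ref, , drop = FALSE]
    rows[[r]] <- classifyGuide(h, if (nrow(bx)) bx else NULL,
                               duplexes[[r]], sites, rule,
                               list(seqChr[[h$arm1_ref]],
                                    seqChr[[h$arm2_ref]]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-methylation-site tabulation of interactions
#'
#' For each annotated site: the number of non-identical hybrids whose
#' target arm overlaps the site, the number predicted to guide methylation
#' at that exact position, and the interacting snoRNAs (cognate or not).
#' A complementary table summarises interactions not overlapping any
#' annotated site, grouped by snoRNA.
#'
#' @param guideCalls calls from [classifyGuides()].
#' @param hybrids the matching hybrid table (same order).
#' @param sites methylation-site table.
#' @return list: `perSite` (one row per annotated site), `offSite`
#'   (per-snoRNA counts of interactions not overlapping any site).
#' @export
tabulateMethylationSites <- function(guideCalls, hybrids, sites) {
  stopifnot(nrow(guideCalls) == nrow(hybrids))
  overlapsAt <- function(sid, pos)
    hybrids$arm2_ref == sid & hybrids$arm2_ref_start <= pos - 1L &
      hybrids$arm2_ref_end > pos - 1L
  isGuide <- startsWith(guideCalls$classification, "guide_")
  perSite <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
    ov <- overlapsAt(sites$target_id[s], sites$position[s])
    gu <- isGuide & !is.na(guideCalls$predicted_target_position) &
      guideCalls$predicted_target_position == sites$position[s] &
      hybrids$arm2_ref == sites$target_id[s]
    data.frame(target_id = sites$target_id[s], position = sites$position[s],
               guide_snorna = sites$guide_snorna[s],
               n_overlapping = sum(ov), n_guiding = sum(gu),
               interacting_snornas =
                 paste(sort(unique(hybrids$arm1_ref[ov])), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(perSite))
    perSite <- data.frame(target_id = character(), position = integer(),
                          guide_snorna = character(), n_overlapping = integer(),
                          n_guiding = integer(),
                          interacting_snornas = character(),
                          stringsAsFactors = FALSE)
  anyOverlap <- rep(FALSE, nrow(hybrids))
  for (s in seq_len(nrow(sites)))
    anyOverlap <- anyOverlap | overlapsAt(sites$target_id[s], sites$position[s])
  off <- hybrids[!anyOverlap, , drop = FALSE]
  offSite <- if (nrow(off)) {
    agg <- table(off$arm1_ref)
    data.frame(snorna_id = names(agg), n_interactions = as.integer(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(snorna_id = character(), n_interactions = integer(),
               stringsAsFactors = FALSE)
  }
  list(perSite = perSite, offSite = offSite)
}

#' Fraction of site-overlapping hybrids predicted to guide methylation
#'
#' Numerator: guide calls (`guide_D` / `guide_Dprime`). Denominator: all
#' hybrids whose target arm overlaps an annotated methylation site;
#' guide calls count in both. `NA` when the denominator is zero.
#'
#' @inheritParams tabulateMethylationSites
#' @return a single fraction in `[0, 1]`, or `NA`.
#' @export
guideFraction <- function(guideCalls, hybrids, sites) {
  stopifnot(nrow(guideCalls) == nrow(hybrids))
  if (!nrow(hybrids)) return(NA_real_)
  anyOverlap <- rep(FALSE, nrow(hybrids))
  for (s in seq_len(nrow(sites))) {
    anyOverlap <- anyOverlap |
      (hybrids$arm2_ref == sites$target_id[s] &
         hybrids$arm2_ref_start <= sites$position[s] - 1L &
         hybrids$arm2_ref_end > sites$position[s] - 1L)
  }
  isGuide <- startsWith(guideCalls$classification, "guide_")
  denom <- sum(anyOverlap)
  if (denom == 0L) return(NA_real_)
  sum(isGuide & anyOverlap) / denom
}
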