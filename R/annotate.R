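#' Per-nucleotide coverage profile of hybrid arms over a reference
#'
#' Each selected arm adds +1 to every covered position of the window
#' (reference extended by `flank` on both sides); arm positions outside
#' the window are clipped. Hybrids count once each (deduplicated
#' molecules), not once per read duplicate.
#'
#' @param hybrids hybrid table.
#' @param refset a [ReferenceSet].
#' @param referenceId record to profile.
#' @param armSelector which arms to count: "arm2" (target side, default),
#'   "arm1", or "both".
#' @param flank nt added on each side of the record window (profile
#'   coordinates then start at -flank).
#' @return list of class `CoverageProfile`: `reference_id`, `window`
#'   (0-based half-open, relative to the record start), `counts`.
#' @export
coverageProfile <- function(hybrids, refset, referenceId,
                            armSelector = c("arm2", "arm1", "both"),
                            flank = 0L) {
  armSelector <- match.arg(armSelector)
  stopIfNot(referenceId %in% names(refset), "unknown reference '%s'",
            referenceId)
  len <- width(refSequences(refset))[match(referenceId, names(refset))]
  w0 <- -as.integer(flank); w1 <- len + as.integer(flank)
  counts <- integer(w1 - w0)
  addArm <- function(ref, s, e) {
    sel <- ref == referenceId
    s <- pmax(s[sel], w0); e <- pmin(e[sel], w1)
    keep <- s < e
    for (i in which(keep)) {
      idx <- (s[i] - w0 + 1L):(e[i] - w0)
      counts[idx] <<- counts[idx] + 1L
    }
  }
  if (nrow(hybrids)) {
    if (armSelector %in% c("arm1", "both"))
      addArm(hybrids$arm1_ref, hybrids$arm1_ref_start, hybrids$arm1_ref_end)
    if (armSelector %in% c("arm2", "both"))
      addArm(hybrids$arm2_ref, hybrids$arm2_ref_start, hybrids$arm2_ref_end)
  }
  structure(list(reference_id = referenceId, window = c(w0, w1),
                 counts = counts),
            class = "CoverageProfile")
}

#' Write a coverage profile as bedGraph
#' @param profile a `CoverageProfile`.
#' @param path output path.
#' @export
writeBedGraph <- function(profile, path) {
  rle <- rle(profile$counts)
  ends <- cumsum(rle$lengths) + profile$window[1L]
  starts <- ends - rle$lengths
  keep <- rle$values != 0L
  write.table(data.frame(profile$reference_id, starts[keep], ends[keep],
                         rle$values[keep]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Assign mRNA-arm hybrids to gene features
#'
#' Each hybrid whose target arm maps to an mRNA record is assigned the
#' feature (5'UTR, CDS, intron, 3'UTR) containing the arm midpoint. For
#' even-length arms the midpoint index is the downstream of the two
#' central positions, so an arm straddling a boundary goes to the
#' downstream (3') feature. Arms whose midpoint falls outside all
#' annotated features (e.g. in a masked region) are `unclassified` and
#' excluded from the four-way tabulation.
#'
#' @param hybrids hybrid table (target arm = arm2).
#' @param refset a [ReferenceSet] with mRNA feature annotations.
#' @return data.frame: `hybrid_id`, `gene_id`, `feature`.
#' @export
assignMrnaFeatures <- function(hybrids, refset) {
  cats <- refCategory(refset)
  feats <- refFeatures(refset)
  isM <- hybrids$arm2_ref %in% names(cats)[cats == "mRNA"]
  hy <- hybrids[isM, , drop = FALSE]
  if (!nrow(hy)) {
    return(data.frame(hybrid_id = character(), gene_id = character(),
                      feature = character(), stringsAsFactors = FALSE))
  }
  mid <- (hy$arm2_ref_start + hy$arm2_ref_end) %/% 2L
  feature <- vapply(seq_len(nrow(hy)), function(r) {
    f <- feats[feats$ref_id == hy$arm2_ref[r] & feats$kind != "exon", ,
               drop = FALSE]
    hit <- f$kind[f$start <= mid[r] & mid[r] < f$end]
    if (length(hit)) hit[1L] else "unclassified"
  }, character(1))
  data.frame(hybrid_id = hy$read_id, gene_id = hy$arm2_ref,
             feature = feature, stringsAsFactors = FALSE)
}

#' Four-way feature tabulation of snoRNA-mRNA interactions
#'
#' @param assignments output of [assignMrnaFeatures()].
#' @return named integer vector over five_prime_UTR / CDS / intron /
#'   three_prime_UTR (unclassified arms excluded).
#' @export
tabulateFeatures <- function(assignments) {
  lv <- c("five_prime_UTR", "CDS", "intron", "three_prime_UTR")
  tab <- table(factor(assignments$feature[assignments$feature %in% lv],
                      levels = lv))
  setNames(as.integer(tab), lv)
}
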