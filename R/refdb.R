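#' Build the custom CLASH reference from a genome and gene models
#'
#' Constructs one reference record per unspliced gene: the full genomic gene
#' span (introns included), reverse-complemented for minus-strand genes so
#' every record reads 5' to 3'. snoRNA genes are extended by
#' `snornaExtension` nt in each direction (clipped at contig ends), and in
#' any host gene that contains a snoRNA the snoRNA footprint is replaced by
#' N so chimera arms cannot be attributed to the host.
#'
#' The GFF3 is expected to carry `gene` features with `ID` and `biotype`
#' attributes (`snoRNA`, `rRNA`, `mRNA`, anything else mapping to `other`),
#' and optional child features (`five_prime_UTR`, `exon`, `CDS`,
#' `three_prime_UTR`) linked by `Parent`. Introns are derived as gaps
#' between consecutive exons. Stored features are the non-overlapping
#' transcript partition (UTRs, CDS, introns; plain exons only where no CDS
#' is annotated).
#'
#' @param genomeFasta path to the genome FASTA.
#' @param geneModelsGff3 path to the gene-model GFF3.
#' @param snornaExtension nt of flanking sequence added to snoRNA genes
#'   (default 20).
#' @param maskHostGenes replace nested snoRNA footprints with N in their
#'   host genes (default TRUE).
#' @return A [ReferenceSet] (boxes and methylation sites empty; see
#'   [annotateBoxes()] and [loadMethylationSites()]).
#' @export
buildReference <- function(genomeFasta, geneModelsGff3,
                           snornaExtension = 20L, maskHostGenes = TRUE) {
  stopIfNot(snornaExtension >= 0L, "snornaExtension must be >= 0")
  genome <- readDNAStringSet(genomeFasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(geneModelsGff3, format = "gff3")

  isGene <- as.character(gff$type) == "gene"
  genes <- gff[isGene]
  stopIfNot(length(genes) > 0L, "no gene features in %s", geneModelsGff3)
  gid <- as.character(genes$ID)
  biotype <- as.character(genes$biotype %||% rep("other", length(genes)))
  biotype[is.na(biotype)] <- "other"
  category <- ifelse(biotype %in% REF_CATEGORIES, biotype, "other")

  kids <- gff[!isGene & as.character(gff$type) %in%
                c("five_prime_UTR", "exon", "CDS", "three_prime_UTR")]
  kidParent <- vapply(kids$Parent, function(p) as.character(p)[1L], character(1))

  contigLens <- setNames(width(genome), names(genome))

  seqs <- character(length(genes))
  featRows <- vector("list", length(genes))
  span0 <- matrix(0L, length(genes), 2L)  # record genomic span, 0-based h.o.

  for (i in seq_along(genes)) {
    contig <- as.character(GenomicRanges::seqnames(genes)[i])
    stopIfNot(contig %in% names(genome),
              "gene '%s': contig '%s' missing from FASTA", gid[i], contig)
    g0 <- start(genes)[i] - 1L
    g1 <- end(genes)[i]
    o0 <- g0; o1 <- g1
    if (category[i] == "snoRNA") {
      o0 <- max(0L, g0 - snornaExtension)
      o1 <- min(contigLens[[contig]], g1 + snornaExtension)
    }
    span0[i, ] <- c(o0, o1)
    strand <- as.character(GenomicRanges::strand(genes)[i])
    sq <- substr(as.character(genome[[contig]]), o0 + 1L, o1)
    if (strand == "-") sq <- revComp(sq)
    seqs[i] <- sq

    k <- kids[kidParent == gid[i]]
    if (length(k)) {
      ks <- start(k) - 1L; ke <- end(k); kind <- as.character(k$type)
      # derive introns from exon gaps
      ex <- order(ks[kind == "exon"])
      exs <- ks[kind == "exon"][ex]; exe <- ke[kind == "exon"][ex]
      if (length(exs) > 1L) {
        ins <- exe[-length(exe)]; ine <- exs[-1L]
        keep <- ine > ins
        ks <- c(ks, ins[keep]); ke <- c(ke, ine[keep])
        kind <- c(kind, rep("intron", sum(keep)))
      }
      # non-overlapping partition: drop exons when CDS/UTRs present
      if (any(kind %in% c("CDS", "five_prime_UTR", "three_prime_UTR"))) {
        drop <- kind == "exon"
        ks <- ks[!drop]; ke <- ke[!drop]; kind <- kind[!drop]
      }
      if (strand == "-") {
        ls <- o1 - ke; le <- o1 - ks
      } else {
        ls <- ks - o0; le <- ke - o0
      }
      stopIfNot(all(ls >= 0 & le <= o1 - o0),
                "gene '%s': child feature outside gene span", gid[i])
      f <- data.frame(ref_id = gid[i], kind = kind, start = ls, end = le,
                      stringsAsFactors = FALSE)
      f <- f[order(f$start), , drop = FALSE]
      if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
        stop(sprintf("gene '%s': overlapping features", gid[i]), call. = FALSE)
      featRows[[i]] <- f
    }
  }

  # mask nested snoRNA footprints (unextended span) out of host genes
  if (maskHostGenes) {
    contigs <- as.character(GenomicRanges::seqnames(genes))
    strands <- as.character(GenomicRanges::strand(genes))
    for (i in which(category == "snoRNA")) {
      s0 <- start(genes)[i] - 1L; s1 <- end(genes)[i]
      hosts <- which(seq_along(genes) != i &
                       contigs == contigs[i] &
                       span0[, 1L] <= s0 & span0[, 2L] >= s1 &
                       category != "snoRNA")
      for (h in hosts) {
        if (strands[h] == "-") {
          m0 <- span0[h, 2L] - s1; m1 <- span0[h, 2L] - s0
        } else {
          m0 <- s0 - span0[h, 1L]; m1 <- s1 - span0[h, 1L]
        }
        substr(seqs[h], m0 + 1L, m1) <-
          strrep("N", m1 - m0)
      }
    }
  }

  dna <- DNAStringSet(seqs)
  names(dna) <- gid
  feats <- do.call(rbind, c(list(emptyFeatureTable()), featRows))
  rownames(feats) <- NULL
  new("ReferenceSet",
      sequences = dna,
      category = unname(category),
      features = feats,
      boxes = emptyBoxTable(),
      methylationSites = emptyMethylationTable())
}

emptyFeatureTable <- function() {
  data.frame(ref_id = character(), kind = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

emptyBoxTable <- function() {
  data.frame(snorna_id = character(),
             boxC_start = integer(), boxC_end = integer(),
             boxD_start = integer(), boxD_end = integer(),
             boxDprime_start = integer(), boxDprime_end = integer(),
             boxCprime_start = integer(), boxCprime_end = integer(),
             unannotatable = logical(), stringsAsFactors = FALSE)
}

emptyMethylationTable <- function() {
  data.frame(target_id = character(), position = integer(),
             nucleotide = character(), guide_snorna = character(),
             guide_box = character(), stringsAsFactors = FALSE)
}

#' Locate box C/D (and internal C'/D') motifs in a snoRNA sequence
#'
#' Box C (RUGAUGA, R = A or G) is searched with up to `boxCMismatch`
#' mismatches within the first `window5` nt; box D (CUGA) as an exact match
#' within the last `window3` nt. Internal D' (CUGA, <= `dPrimeMismatch`
#' mismatches) and C' (RUGAUGA, <= `cPrimeMismatch`) are searched between
#' box C and box D and reported only when both occur in the order D' < C'.
#' Ties are broken by fewest mismatches, then by proximity to the canonical
#' end (5' terminus for C, 3' terminus for D; D' prefers the 5' side and C'
#' the 3' side of the internal region, mirroring the terminal geometry).
#'
#' If a curated `userAnnotation` is supplied it is validated and returned
#' verbatim; curated coordinates always take precedence over motif search.
#'
#' @param sequence snoRNA sequence (DNA or RNA alphabet), length >= 30.
#' @param userAnnotation optional one-row data.frame in the [boxAnnotations()]
#'   layout (0-based half-open coordinates).
#' @param boxCMismatch,dPrimeMismatch,cPrimeMismatch mismatch allowances.
#' @param window5,window3 terminal search windows, nt.
#' @param snornaId id recorded in the returned row.
#' @return one-row data.frame in the [boxAnnotations()] layout; records with
#'   no box C or no box D are flagged `unannotatable` (never an error).
#' @export
locateBoxes <- function(sequence, userAnnotation = NULL, snornaId = NA_character_,
                        boxCMismatch = 1L, window5 = 30L, window3 = 20L,
                        dPrimeMismatch = 1L, cPrimeMismatch = 2L) {
  seq <- dnaify(sequence)
  n <- nchar(seq)
  stopIfNot(n >= 30L, "snoRNA sequence must be at least 30 nt (got %d)", n)

  if (!is.null(userAnnotation)) {
    validateBoxAnnotation(userAnnotation, n)
    ua <- userAnnotation
    if (!is.na(snornaId)) ua$snorna_id <- snornaId
    return(ua)
  }

  row <- emptyBoxTable()[0, ]
  boxC <- bestMotif(seq, "RTGATGA", 0L, min(window5, n), boxCMismatch,
                    canonical = "left")
  boxD <- bestMotif(seq, "CTGA", max(0L, n - window3), n, 0L,
                    canonical = "right")
  if (is.null(boxC) || is.null(boxD) || boxC$end > boxD$start) {
    return(data.frame(snorna_id = snornaId,
                      boxC_start = NA_integer_, boxC_end = NA_integer_,
                      boxD_start = NA_integer_, boxD_end = NA_integer_,
                      boxDprime_start = NA_integer_, boxDprime_end = NA_integer_,
                      boxCprime_start = NA_integer_, boxCprime_end = NA_integer_,
                      unannotatable = TRUE, stringsAsFactors = FALSE))
  }

  # internal region strictly between box C and box D
  i0 <- boxC$end; i1 <- boxD$start
  dp <- cp <- NULL
  if (i1 - i0 >= 11L) {
    dCand <- allMotifs(seq, "CTGA", i0, i1, dPrimeMismatch)
    cCand <- allMotifs(seq, "RTGATGA", i0, i1, cPrimeMismatch)
    if (length(dCand) && length(cCand)) {
      best <- NULL
      for (d in dCand) for (cc in cCand) {
        if (d$end > cc$start) next
        key <- c(d$mm + cc$mm, d$start, -cc$start)  # D' toward 5', C' toward 3'
        if (is.null(best) || isKeyLess(key, best$key))
          best <- list(d = d, c = cc, key = key)
      }
      if (!is.null(best)) { dp <- best$d; cp <- best$c }
    }
  }

  data.frame(snorna_id = snornaId,
             boxC_start = boxC$start, boxC_end = boxC$end,
             boxD_start = boxD$start, boxD_end = boxD$end,
             boxDprime_start = if (is.null(dp)) NA_integer_ else dp$start,
             boxDprime_end = if (is.null(dp)) NA_integer_ else dp$end,
             boxCprime_start = if (is.null(cp)) NA_integer_ else cp$start,
             boxCprime_end = if (is.null(cp)) NA_integer_ else cp$end,
             unannotatable = FALSE, stringsAsFactors = FALSE)
}

isKeyLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# all motif occurrences with <= maxMm mismatches in [from, to) (0-based h.o.)
allMotifs <- function(seq, pattern, from, to, maxMm) {
  k <- nchar(pattern)
  if (to - from < k) return(list())
  windowSeq <- substr(seq, from + 1L, to)
  mm <- motifMismatches(windowSeq, pattern)
  hits <- which(mm <= maxMm)
  lapply(hits, function(h)
    list(start = from + h - 1L, end = from + h - 1L + k, mm = mm[h]))
}

# single best occurrence; tie-break fewest mismatches then canonical proximity
bestMotif <- function(seq, pattern, from, to, maxMm, canonical) {
  cand <- allMotifs(seq, pattern, from, to, maxMm)
  if (!length(cand)) return(NULL)
  mm <- vapply(cand, `[[`, integer(1), "mm")
  st <- vapply(cand, `[[`, integer(1), "start")
  ord <- order(mm, if (canonical == "left") st else -st)
  cand[[ord[1L]]]
}

validateBoxAnnotation <- function(ann, seqLen) {
  need <- c("boxC_start", "boxC_end", "boxD_start", "boxD_end")
  stopIfNot(all(need %in% names(ann)), "box annotation missing %s",
            paste(setdiff(need, names(ann)), collapse = ", "))
  stopIfNot(nrow(ann) == 1L, "box annotation must be a single row")
  with(ann, {
    stopIfNot(boxC_start >= 0 && boxD_end <= seqLen,
              "box coordinates outside sequence")
    stopIfNot(boxC_end <= boxD_start, "box C must precede box D")
    if (!is.na(ann$boxDprime_start %||% NA) &&
        !is.na(ann$boxCprime_start %||% NA)) {
      stopIfNot(ann$boxDprime_end <= ann$boxCprime_start,
                "box D' must precede box C'")
      stopIfNot(ann$boxDprime_start >= boxC_end &&
                  ann$boxCprime_end <= boxD_start,
                "internal boxes must lie strictly between box C and box D")
    }
  })
  invisible(TRUE)
}

#' Annotate all snoRNA records of a ReferenceSet with box positions
#'
#' Runs [locateBoxes()] over every snoRNA record (curated rows in
#' `userBoxes`, matched by `snorna_id`, take precedence) and returns the
#' updated `ReferenceSet`.
#'
#' @param refset a [ReferenceSet].
#' @param userBoxes optional curated box table in the [boxAnnotations()]
#'   layout.
#' @param extension nt of mapping flank carried by the snoRNA records
#'   (the motif search runs on the mature span between the flanks; box
#'   coordinates are reported record-local).
#' @param ... passed to [locateBoxes()].
#' @export
annotateBoxes <- function(refset, userBoxes = NULL, extension = 0L, ...) {
  snos <- names(refset)[refCategory(refset) == "snoRNA"]
  rows <- lapply(snos, function(id) {
    ua <- NULL
    if (!is.null(userBoxes) && id %in% userBoxes$snorna_id)
      ua <- userBoxes[userBoxes$snorna_id == id, , drop = FALSE]
    sq <- as.character(refSequences(refset)[[id]])
    if (is.null(ua) && extension > 0L)
      sq <- substr(sq, extension + 1L, nchar(sq) - extension)
    row <- locateBoxes(sq, userAnnotation = ua, snornaId = id, ...)
    if (is.null(ua) && extension > 0L) {
      for (col in grep("_(start|end)$", names(row), value = TRUE))
        row[[col]] <- row[[col]] + as.integer(extension)
    }
    row
  })
  refset@boxes <- do.call(rbind, c(list(emptyBoxTable()), rows))
  validObject(refset)
  refset
}

#' Load and validate a table of known 2'-O-methylation sites
#'
#' Reads a snoRNA-orthology-style TSV with columns `target_id`, `position`
#' (1-based), `nucleotide`, `guide_snorna`, `guide_box` (D or Dprime) and
#' validates every row against the reference sequences. Round-trips
#' losslessly through [writeMethylationSites()].
#'
#' @param tsv path to the TSV (or a data.frame already in that layout).
#' @param refset a [ReferenceSet] used for validation.
#' @return validated data.frame of methylation sites.
#' @export
loadMethylationSites <- function(tsv, refset) {
  ms <- if (is.data.frame(tsv)) tsv else
    read.delim(tsv, stringsAsFactors = FALSE,
               colClasses = c(position = "integer"))
  need <- c("target_id", "position", "nucleotide", "guide_snorna", "guide_box")
  stopIfNot(all(need %in% names(ms)), "methylation table missing column(s): %s",
            paste(setdiff(need, names(ms)), collapse = ", "))
  ms <- ms[, need, drop = FALSE]
  if (!nrow(ms)) return(emptyMethylationTable())
  ids <- names(refset)
  for (r in seq_len(nrow(ms))) {
    tid <- ms$target_id[r]
    stopIfNot(tid %in% ids, "methylation row %d: unknown target '%s'", r, tid)
    len <- width(refSequences(refset))[match(tid, ids)]
    p <- ms$position[r]
    stopIfNot(!is.na(p) && p >= 1L && p <= len,
              "methylation row %d: position %s outside [1, %d]", r, p, len)
    refBase <- substr(as.character(refSequences(refset)[[tid]]), p, p)
    stopIfNot(dnaify(ms$nucleotide[r]) == refBase,
              "methylation row %d: nucleotide '%s' does not match reference '%s'",
              r, ms$nucleotide[r], refBase)
    stopIfNot(ms$guide_box[r] %in% c("D", "Dprime"),
              "methylation row %d: guide_box must be D or Dprime", r)
  }
  ms
}

#' @rdname loadMethylationSites
#' @param sites a methylation-site data.frame.
#' @param path output TSV path.
#' @export
writeMethylationSites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a methylation-site table to a ReferenceSet
#' @inheritParams loadMethylationSites
#' @export
addMethylationSites <- function(refset, tsv) {
  refset@methylationSites <- loadMethylationSites(tsv, refset)
  validObject(refset)
  refset
}

#' Write / read a reference bundle directory
#'
#' The bundle is a FASTA of record sequences plus TSV sidecars
#' (`records.tsv`, `features.tsv`, `boxes.tsv`, `methylation.tsv`).
#' Interval columns in the TSVs are 1-based inclusive; the reader restores
#' the internal 0-based half-open convention. Output is deterministic given
#' the `ReferenceSet`.
#'
#' @param refset a [ReferenceSet].
#' @param dir bundle directory (created if absent).
#' @export
writeReferenceBundle <- function(refset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(refSequences(refset), file.path(dir, "records.fa"))
  write.table(data.frame(id = names(refset), category = refCategory(refset)),
              file.path(dir, "records.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ft <- refFeatures(refset)
  c1 <- toOneBased(ft$start, ft$end)
  write.table(data.frame(ref_id = ft$ref_id, kind = ft$kind,
                         start = c1$start, end = c1$end),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bx <- boxAnnotations(refset)
  bx1 <- bx
  for (col in grep("_start$", names(bx), value = TRUE))
    bx1[[col]] <- bx[[col]] + 1L
  write.table(bx1, file.path(dir, "boxes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeMethylationSites(methylationSites(refset),
                        file.path(dir, "methylation.tsv"))
  invisible(dir)
}

#' @rdname writeReferenceBundle
#' @export
readReferenceBundle <- function(dir) {
  seqs <- readDNAStringSet(file.path(dir, "records.fa"))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  rec <- read.delim(file.path(dir, "records.tsv"), stringsAsFactors = FALSE)
  ft1 <- read.delim(file.path(dir, "features.tsv"), stringsAsFactors = FALSE)
  ft <- if (nrow(ft1)) {
    c0 <- toZeroBased(ft1$start, ft1$end)
    data.frame(ref_id = ft1$ref_id, kind = ft1$kind,
               start = c0$start, end = c0$end, stringsAsFactors = FALSE)
  } else emptyFeatureTable()
  bx <- read.delim(file.path(dir, "boxes.tsv"), stringsAsFactors = FALSE)
  if (nrow(bx)) {
    for (col in grep("_start$", names(bx), value = TRUE))
      bx[[col]] <- bx[[col]] - 1L
  } else bx <- emptyBoxTable()
  ms <- read.delim(file.path(dir, "methylation.tsv"), stringsAsFactors = FALSE)
  if (!nrow(ms)) ms <- emptyMethylationTable()
  rs <- new("ReferenceSet", sequences = seqs,
            category = rec$category[match(names(seqs), rec$id)],
            features = ft, boxes = bx, methylationSites = ms)
  validObject(rs)
  rs
}
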