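#' Simulation configuration for synthetic CLASH libraries
#'
#' Returns a validated configuration for [simulateReference()] and
#' [simulateReads()]. Defaults describe a desk-scale library: 12 box C/D
#' snoRNAs, 50 mRNAs, a 6 kb mock rDNA with 20 planted 2'-O-methylation
#' sites, 20,000 unique molecules, PCR duplication with mean 3 copies and a
#' 0.2% substitution error rate. The class mix covers cognate +5-rule guide
#' chimeras, non-guide "blocking" chimeras overlapping methylation sites,
#' snoRNA-snoRNA and snoRNA-mRNA chimeras, single-fragment reads and
#' unmappable noise.
#'
#' @param seed integer master seed; every downstream draw derives from it.
#' @param n_snorna,n_mrna,rdna_length,n_methylation_sites reference sizes.
#' @param n_reads number of unique molecules (truth rows); FASTQ record
#'   count is the sum of PCR duplicate counts.
#' @param class_mix named proportions over the six read classes (must sum
#'   to 1). When `n_methylation_sites = 0` the `cognate_guide` share is
#'   reassigned to `snorna_snorna`.
#' @param pcr_duplication_mean mean PCR copies per molecule (>= 1; copies
#'   are 1 + geometric).
#' @param substitution_error_rate per-base i.i.d. substitution rate.
#' @param arm_length_range length-2 integer range of arm lengths, nt.
#' @param barcode_set data.frame `sample_id`, `barcode`; defaults to the
#'   ten 5' linker barcodes of the library design (see [defaultBarcodes()]).
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, n_snorna = 12L, n_mrna = 50L,
                      rdna_length = 6000L, n_methylation_sites = 20L,
                      n_reads = 20000L,
                      class_mix = c(cognate_guide = 0.45, blocking = 0.15,
                                    snorna_snorna = 0.10, snorna_mrna = 0.10,
                                    single_fragment = 0.15, noise = 0.05),
                      pcr_duplication_mean = 3, substitution_error_rate = 0.002,
                      arm_length_range = c(18L, 40L),
                      barcode_set = defaultBarcodes()) {
  classes <- c("cognate_guide", "blocking", "snorna_snorna", "snorna_mrna",
               "single_fragment", "noise")
  stopIfNot(setequal(names(class_mix), classes),
            "class_mix must be named over the six read classes")
  class_mix <- class_mix[classes]
  stopIfNot(abs(sum(class_mix) - 1) < 1e-8, "class_mix must sum to 1")
  stopIfNot(all(class_mix >= 0 & class_mix <= 1), "class_mix entries in [0,1]")
  stopIfNot(pcr_duplication_mean >= 1, "pcr_duplication_mean must be >= 1")
  stopIfNot(substitution_error_rate >= 0 && substitution_error_rate <= 1,
            "substitution_error_rate must be in [0,1]")
  stopIfNot(length(arm_length_range) == 2L &&
              arm_length_range[1] <= arm_length_range[2] &&
              arm_length_range[1] >= 12L,
            "arm_length_range must be an increasing pair >= 12")
  stopIfNot(n_snorna >= 1L && rdna_length >= 1000L, "reference too small")
  if (n_methylation_sites == 0L) {
    # no sites -> nothing to guide or block; fold both into snoRNA-snoRNA
    class_mix[["snorna_snorna"]] <- class_mix[["snorna_snorna"]] +
      class_mix[["cognate_guide"]] + class_mix[["blocking"]]
    class_mix[["cognate_guide"]] <- 0
    class_mix[["blocking"]] <- 0
  }
  stopIfNot(n_methylation_sites <= 2L * n_snorna,
            "n_methylation_sites must be <= 2 * n_snorna")
  structure(list(seed = as.integer(seed), n_snorna = as.integer(n_snorna),
                 n_mrna = as.integer(n_mrna),
                 rdna_length = as.integer(rdna_length),
                 n_methylation_sites = as.integer(n_methylation_sites),
                 n_reads = as.integer(n_reads), class_mix = class_mix,
                 pcr_duplication_mean = pcr_duplication_mean,
                 substitution_error_rate = substitution_error_rate,
                 arm_length_range = as.integer(arm_length_range),
                 barcode_set = barcode_set),
            class = "SimConfig")
}

#' The ten 5' linker barcodes of the CLASH library design
#'
#' DNA-alphabet barcodes read at offset 3 of each read (after the 3-nt
#' random tag), as used on the multiplexed 5' linkers.
#' @return data.frame with columns `sample_id`, `barcode`.
#' @export
defaultBarcodes <- function() {
  data.frame(
    sample_id = c("Aa", "Ab", "Ac", "Bb", "Bc", "Bd",
                  "Ca", "Cb", "Cc", "Cd"),
    barcode = c("TAAGC", "ATTAGC", "GCGCAGC", "GTGAGC", "CACTAGC",
                "TCTCTAGC", "CTAGC", "GGAGC", "ACTCAGC", "GACTTAGC"),
    stringsAsFactors = FALSE
  )
}

#' The miRCat-33 3' adapter sequence
#' @export
MIRCAT33_ADAPTER <- "TGGAATTCTCGGGTGCCAAG"

SNO_EXTENSION <- 20L  # flank carried by simulated snoRNA records

# reject target windows whose reverse complement would plant a spurious
# box motif inside a synthetic snoRNA
windowClean <- function(rc) {
  !grepl("CTGA", rc, fixed = TRUE) &&
    !grepl("[AG]TGATGA", rc)
}

# reject guide sites whose neighbourhood could base-pair the fixed box
# C/C' core (UGAUGA) of the carrying snoRNA: such chance complementarity
# can out-fold the planted guide helix and break the +5 geometry
regionClean <- function(region) {
  !grepl("TCATCA", region, fixed = TRUE)
}

#' Simulate a reference with planted methylation-guide geometry
#'
#' Builds a mock genome (one rDNA gene, `n_snorna` box C/D snoRNAs of which
#' two are hosted inside mRNA introns, and `n_mrna` mRNAs with
#' 5'UTR/exon-intron/CDS/3'UTR structure), writes it as FASTA + GFF3, and
#' runs [buildReference()] on it so extension and host-gene masking are
#' exercised. Each methylation site is assigned a guide snoRNA carrying a
#' 12-14 nt antisense element perfectly complementary to the target window,
#' positioned so the methylated nucleotide pairs the snoRNA base exactly
#' 5 nt upstream of box D (or box D'). Every snoRNA additionally carries a
#' 14 nt "blocking" element, complementary to a window overlapping a
#' non-cognate site but far from any box, so the +5 geometry fails.
#'
#' Spacer and terminal segments of synthetic snoRNAs are drawn from an
#' {A,C} alphabet and planted windows are rejection-sampled so their
#' reverse complements contain no spurious CUGA/RUGAUGA, making motif-based
#' box recovery exact on error-free sequences.
#'
#' @param config a [simConfig()].
#' @param dir optional directory for the genome FASTA/GFF3 and reference
#'   bundle (a temporary directory by default).
#' @return list of class `SimReference`: `refset` (a [ReferenceSet] with
#'   boxes and methylation sites attached), `plants` (planted element
#'   table, record-local 0-based half-open coordinates), `paths`, `config`.
#' @export
simulateReference <- function(config = simConfig(), dir = tempfile("simref")) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(deriveSeed(config$seed, 101L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  nSites <- config$n_methylation_sites
  nSno <- config$n_snorna

  # --- rDNA with sanitized site windows ----------------------------------
  rdnaLen <- config$rdna_length
  rdna <- randomDNA(1L, rdnaLen)
  helixLen <- if (nSites) sample(12:14, nSites, replace = TRUE) else integer()
  sitePos <- integer(nSites)  # 1-based
  if (nSites) {
    taken <- integer()
    for (s in seq_len(nSites)) {
      repeat {
        m <- sample(60:(rdnaLen - 60L), 1L)
        if (length(taken) && min(abs(taken - m)) < 45L) next
        L <- helixLen[s]
        guideRC <- revComp(substr(rdna, m - 4L, m + L - 5L))
        blockRC <- revComp(substr(rdna, m - 10L, m + 3L))
        if (windowClean(guideRC) && windowClean(blockRC) &&
            regionClean(substr(rdna, m - 25L, m + 25L))) break
      }
      sitePos[s] <- m
      taken <- c(taken, m)
    }
  }

  # site -> guide snoRNA assignment: one D guide per snoRNA first, then D'
  siteSno <- siteBox <- character(nSites)
  if (nSites) {
    for (s in seq_len(nSites)) {
      if (s <= nSno) {
        siteSno[s] <- sprintf("snoR%02d", s); siteBox[s] <- "D"
      } else {
        siteSno[s] <- sprintf("snoR%02d", s - nSno); siteBox[s] <- "Dprime"
      }
    }
  }

  # --- snoRNA gene sequences (gene-local layout) -------------------------
  AC <- c("A", "C")
  snoIds <- sprintf("snoR%02d", seq_len(nSno))
  snoSeq <- character(nSno)
  boxRows <- vector("list", nSno)
  plantRows <- list()
  for (i in seq_len(nSno)) {
    dSite <- if (nSites) which(siteSno == snoIds[i] & siteBox == "D") else integer()
    pSite <- if (nSites) which(siteSno == snoIds[i] & siteBox == "Dprime") else integer()
    blockOf <- if (nSites) sitePos[(i %% nSites) + 1L] else NA_integer_

    lead <- randomDNA(1L, 4L, AC)
    boxC <- paste0(sample(c("A", "G"), 1L), "TGATGA")
    sp1 <- randomDNA(1L, 5L, AC)
    blk <- if (!is.na(blockOf))
      revComp(substr(rdna, blockOf - 10L, blockOf + 3L)) else randomDNA(1L, 14L, AC)
    sp2 <- randomDNA(1L, 4L, AC)
    segs <- c(lead, boxC, sp1, blk, sp2)
    cassette <- length(pSite) == 1L
    if (cassette) {
      Lp <- helixLen[pSite]
      antiDp <- revComp(substr(rdna, sitePos[pSite] - 4L,
                               sitePos[pSite] + Lp - 5L))
      sp3 <- randomDNA(1L, 5L, AC)
      boxCp <- paste0(sample(c("A", "G"), 1L), "TGATGA")
      sp4 <- randomDNA(1L, 4L, AC)
      segs <- c(segs, antiDp, "CTGA", sp3, boxCp, sp4)
    }
    if (length(dSite) == 1L) {
      Ld <- helixLen[dSite]
      antiD <- revComp(substr(rdna, sitePos[dSite] - 4L,
                              sitePos[dSite] + Ld - 5L))
    } else {
      antiD <- randomDNA(1L, 13L, AC)
    }
    segs <- c(segs, antiD, "CTGA", randomDNA(1L, 8L, AC))
    snoSeq[i] <- paste(segs, collapse = "")

    # gene-local 0-based segment starts
    off <- cumsum(c(0L, nchar(segs)))
    ext <- SNO_EXTENSION
    bCs <- off[2L]; dIdx <- length(segs) - 1L
    bDs <- off[dIdx]
    bDps <- bCps <- NA_integer_
    if (cassette) {
      bDps <- off[7L]          # after lead,boxC,sp1,blk,sp2,antiDp
      bCps <- off[9L]          # after ...,boxDp,sp3
    }
    boxRows[[i]] <- data.frame(
      snorna_id = snoIds[i],
      boxC_start = bCs + ext, boxC_end = bCs + 7L + ext,
      boxD_start = bDs + ext, boxD_end = bDs + 4L + ext,
      boxDprime_start = bDps + ext, boxDprime_end = bDps + 4L + ext,
      boxCprime_start = bCps + ext, boxCprime_end = bCps + 7L + ext,
      unannotatable = FALSE, stringsAsFactors = FALSE)

    # windowStart0/windowEnd0: target window, 0-based half-open
    addPlant <- function(kind, elementStart, elementLen, site,
                         windowStart0, windowEnd0) {
      plantRows[[length(plantRows) + 1L]] <<- data.frame(
        snorna_id = snoIds[i], kind = kind,
        element_start = elementStart + ext,
        element_end = elementStart + elementLen + ext,
        target_id = "RDN37",
        window_start = windowStart0, window_end = windowEnd0,
        site_position = site, stringsAsFactors = FALSE)
    }
    if (length(dSite) == 1L) {
      m <- sitePos[dSite]; L <- helixLen[dSite]
      addPlant("guide_D", bDs - L, L, m, m - 5L, m - 5L + L)
    }
    if (cassette) {
      m <- sitePos[pSite]; L <- helixLen[pSite]
      addPlant("guide_Dprime", bDps - L, L, m, m - 5L, m - 5L + L)
    }
    if (!is.na(blockOf))
      addPlant("blocking", off[4L], 14L, blockOf, blockOf - 11L, blockOf + 3L)
  }

  # --- mRNA genes --------------------------------------------------------
  nM <- config$n_mrna
  mIds <- sprintf("mRNA%03d", seq_len(nM))
  hosts <- if (nM >= 2L && nSno >= 2L) 1:2 else integer()
  hosted <- if (length(hosts)) (nSno - length(hosts) + 1L):nSno else integer()
  mSeq <- character(nM)
  mFeat <- vector("list", nM)
  hostedLocal <- list()  # gene-local snoRNA span within host
  for (j in seq_len(nM)) {
    u5 <- sample(50:80, 1L); e1 <- sample(120:200, 1L)
    e2 <- sample(120:200, 1L); u3 <- sample(50:90, 1L)
    if (j %in% hosts) {
      k <- hosted[match(j, hosts)]
      snoLen <- nchar(snoSeq[k])
      intronSeq <- paste0(randomDNA(1L, 15L), randomDNA(1L, SNO_EXTENSION, AC),
                          snoSeq[k], randomDNA(1L, SNO_EXTENSION, AC),
                          randomDNA(1L, 15L))
      hostedLocal[[mIds[j]]] <-
        c(id = snoIds[k], offset = u5 + e1 + 15L + SNO_EXTENSION)
      intr <- nchar(intronSeq)
    } else {
      intr <- sample(60:120, 1L)
      intronSeq <- randomDNA(1L, intr)
    }
    body <- paste0(randomDNA(1L, u5), randomDNA(1L, e1), intronSeq,
                   randomDNA(1L, e2), randomDNA(1L, u3))
    mSeq[j] <- body
    tot <- nchar(body)
    mFeat[[j]] <- data.frame(
      ref_id = mIds[j],
      kind = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR"),
      start = c(0L, u5, u5 + e1, u5 + e1 + intr, tot - u3),
      end = c(u5, u5 + e1, u5 + e1 + intr, tot - u3, tot),
      stringsAsFactors = FALSE)
  }

  # --- assemble contigs, FASTA + GFF3 ------------------------------------
  genes <- list()  # contig, start0, end0, strand, id, biotype
  addGene <- function(contig, start0, len, strand, id, biotype)
    genes[[length(genes) + 1L]] <<- data.frame(
      contig = contig, start0 = start0, end0 = start0 + len,
      strand = strand, id = id, biotype = biotype, stringsAsFactors = FALSE)

  chrR <- paste0(randomDNA(1L, 150L), rdna, randomDNA(1L, 150L))
  addGene("chrR", 150L, rdnaLen, "+", "RDN37", "rRNA")

  standalone <- setdiff(seq_len(nSno), hosted)
  snoStrand <- rep(c("+", "-"), length.out = length(standalone))
  parts <- character(); pos <- 0L
  for (t in seq_along(standalone)) {
    i <- standalone[t]
    sp <- randomDNA(1L, 40L, AC)
    parts <- c(parts, sp); pos <- pos + 40L
    sq <- snoSeq[i]
    placed <- if (snoStrand[t] == "-") revComp(sq) else sq
    addGene("chrS", pos, nchar(sq), snoStrand[t], snoIds[i], "snoRNA")
    parts <- c(parts, placed); pos <- pos + nchar(sq)
  }
  parts <- c(parts, randomDNA(1L, 40L, AC))
  chrS <- paste(parts, collapse = "")

  mStrand <- rep(c("+", "-"), length.out = nM)
  mStrand[hosts] <- "+"
  parts <- character(); pos <- 0L
  mGenomic <- integer(nM)
  for (j in seq_len(nM)) {
    sp <- randomDNA(1L, 50L)
    parts <- c(parts, sp); pos <- pos + 50L
    mGenomic[j] <- pos
    placed <- if (mStrand[j] == "-") revComp(mSeq[j]) else mSeq[j]
    addGene("chrM", pos, nchar(mSeq[j]), mStrand[j], mIds[j], "mRNA")
    parts <- c(parts, placed); pos <- pos + nchar(mSeq[j])
  }
  parts <- c(parts, randomDNA(1L, 50L))
  chrM <- paste(parts, collapse = "")

  # hosted snoRNA genes (inside host introns, plus strand)
  for (h in seq_along(hosts)) {
    j <- hosts[h]; k <- hosted[h]
    off <- as.integer(hostedLocal[[mIds[j]]][["offset"]])
    addGene("chrM", mGenomic[j] + off, nchar(snoSeq[k]), "+",
            snoIds[k], "snoRNA")
  }

  genome <- DNAStringSet(c(chrR = chrR, chrS = chrS, chrM = chrM))
  fastaPath <- file.path(dir, "genome.fa")
  writeXStringSet(genome, fastaPath)

  gtab <- do.call(rbind, genes)
  gffPath <- file.path(dir, "genes.gff3")
  writeSimGff3(gffPath, gtab, mFeat, mIds, mStrand, mGenomic,
               vapply(mSeq, nchar, integer(1)))

  refset <- buildReference(fastaPath, gffPath,
                           snornaExtension = SNO_EXTENSION,
                           maskHostGenes = TRUE)
  boxes <- do.call(rbind, boxRows)
  refset@boxes <- boxes
  ms <- if (nSites) data.frame(
    target_id = "RDN37", position = sitePos,
    nucleotide = vapply(sitePos, function(m) substr(rdna, m, m), character(1)),
    guide_snorna = siteSno, guide_box = siteBox, stringsAsFactors = FALSE
  ) else emptyMethylationTable()
  refset@methylationSites <- ms
  validObject(refset)

  plants <- if (length(plantRows)) do.call(rbind, plantRows) else
    data.frame(snorna_id = character(), kind = character(),
               element_start = integer(), element_end = integer(),
               target_id = character(), window_start = integer(),
               window_end = integer(), site_position = integer())

  bundleDir <- file.path(dir, "bundle")
  writeReferenceBundle(refset, bundleDir)
  structure(list(refset = refset, plants = plants, config = config,
                 paths = list(fasta = fastaPath, gff3 = gffPath,
                              bundle = bundleDir)),
            class = "SimReference")
}

writeSimGff3 <- function(path, gtab, mFeat, mIds, mStrand, mGenomic, mLens) {
  lines <- "##gff-version 3"
  for (r in seq_len(nrow(gtab))) {
    g <- gtab[r, ]
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
      g$contig, g$start0 + 1L, g$end0, g$strand, g$id, g$biotype))
    j <- match(g$id, mIds)
    if (!is.na(j)) {
      f <- mFeat[[j]]
      # exons flank the intron; the reference builder re-derives the intron
      # from the exon gap
      intr <- f[f$kind == "intron", ]
      f <- rbind(f,
                 data.frame(ref_id = f$ref_id[1], kind = "exon",
                            start = c(0L, intr$end),
                            end = c(intr$start, mLens[j]),
                            stringsAsFactors = FALSE))
      for (q in seq_len(nrow(f))) {
        if (f$kind[q] == "intron") next  # introns derived from exon gaps
        if (mStrand[j] == "-") {
          gs <- mGenomic[j] + (mLens[j] - f$end[q])
          ge <- mGenomic[j] + (mLens[j] - f$start[q])
        } else {
          gs <- mGenomic[j] + f$start[q]
          ge <- mGenomic[j] + f$end[q]
        }
        lines <- c(lines, sprintf(
          "%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tID=%s.%s%d;Parent=%s",
          g$contig, f$kind[q], gs + 1L, ge, mStrand[j],
          g$id, substr(f$kind[q], 1, 1), q, g$id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate CLASH FASTQ reads with ground truth
#'
#' Each unique molecule is `NNN` (random 3-nt tag) + sample barcode + arm1 +
#' arm2 + the miRCat-33 3' adapter. Molecules receive 1 + geometric PCR
#' copies (mean `pcr_duplication_mean`) and i.i.d. substitution errors per
#' emitted copy. The (sample, tag, insert) triple is unique across
#' molecules by rejection sampling, so error-free PCR collapse recovers the
#' truth-molecule count exactly. The truth table lists one row per unique
#' molecule with arm coordinates (record-local, 0-based half-open in
#' memory; 1-based inclusive on disk) and, for cognate guides, the planted
#' snoRNA/box/target position.
#'
#' @param simref a `SimReference` from [simulateReference()].
#' @param config a [simConfig()] (defaults to the one inside `simref`).
#' @param fastqPath,truthPath optional output paths (FASTQ and TSV).
#' @return list: `reads` (data.frame id, sequence in FASTQ order), `truth`
#'   (data.frame, one row per molecule), plus the paths if written.
#' @export
simulateReads <- function(simref, config = simref$config,
                          fastqPath = NULL, truthPath = NULL) {
  stopifnot(inherits(simref, "SimReference"))
  set.seed(deriveSeed(config$seed, 202L))
  refset <- simref$refset
  plants <- simref$plants
  seqs <- refSequences(refset)
  seqChr <- setNames(as.character(seqs), names(seqs))
  lens <- setNames(width(seqs), names(seqs))
  cats <- refCategory(refset)
  ext <- SNO_EXTENSION
  lo <- config$arm_length_range[1]; hi <- config$arm_length_range[2]
  bc <- config$barcode_set
  stopIfNot(!anyDuplicated(bc$sample_id), "duplicate sample_ids in barcode_set")

  snoIds <- names(refset)[cats == "snoRNA"]
  mIds <- names(refset)[cats == "mRNA"]
  # exclude snoRNA-hosting mRNAs from target-arm sampling (masked introns)
  hostIds <- unique(unlist(lapply(mIds, function(id) {
    if (grepl("N", seqChr[[id]], fixed = TRUE)) id else NULL
  })))
  mFree <- setdiff(mIds, hostIds)
  featTab <- refFeatures(refset)
  guidePlants <- plants[plants$kind %in% c("guide_D", "guide_Dprime"), ,
                        drop = FALSE]
  blockPlants <- plants[plants$kind == "blocking", , drop = FALSE]

  classes <- names(config$class_mix)
  n <- config$n_reads
  cls <- sample(classes, n, replace = TRUE, prob = config$class_mix)
  sampleIds <- sample(bc$sample_id, n, replace = TRUE)
  barcodes <- bc$barcode[match(sampleIds, bc$sample_id)]

  # sample an arm of length in [lo,hi] containing [es,ee) plus >= 3 nt of
  # flank on each side (recovered fragments extend past the duplex), within
  # [0,len)
  armAround <- function(es, ee, len) {
    core <- ee - es + 6L
    armLen <- sample(max(lo, core):hi, 1L)
    extra <- armLen - core
    left <- 3L + sample(0:extra, 1L)
    s <- max(0L, es - left)
    e <- min(len, s + armLen)
    s <- max(0L, e - armLen)
    c(s, e)
  }
  # random arm within a gene body [ext, len-ext) for snoRNAs, else [0,len)
  armWithin <- function(id) {
    isS <- cats[match(id, names(refset))] == "snoRNA"
    b0 <- if (isS) ext else 0L
    b1 <- if (isS) lens[[id]] - ext else lens[[id]]
    armLen <- sample(lo:min(hi, b1 - b0), 1L)
    s <- sample(b0:(b1 - armLen), 1L)
    c(s, s + armLen)
  }

  truth <- vector("list", n)
  inserts <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  umis <- character(n)
  for (r in seq_len(n)) {
    repeat {
      a1 <- a2 <- c(NA_integer_, NA_integer_)
      r1 <- r2 <- NA_character_
      gSno <- gBox <- NA_character_; gPos <- NA_integer_
      feat <- NA_character_
      cl <- cls[r]
      if (cl == "cognate_guide") {
        p <- guidePlants[sample(nrow(guidePlants), 1L), ]
        r1 <- p$snorna_id; r2 <- p$target_id
        a1 <- armAround(p$element_start, p$element_end, lens[[r1]])
        a2 <- armAround(p$window_start, p$window_end, lens[[r2]])
        gSno <- r1; gBox <- sub("guide_", "", p$kind); gPos <- p$site_position
      } else if (cl == "blocking") {
        p <- blockPlants[sample(nrow(blockPlants), 1L), ]
        r1 <- p$snorna_id; r2 <- p$target_id
        a1 <- armAround(p$element_start, p$element_end, lens[[r1]])
        a2 <- armAround(p$window_start, p$window_end, lens[[r2]])
      } else if (cl == "snorna_snorna") {
        pick <- sample(snoIds, 2L)
        r1 <- pick[1]; r2 <- pick[2]
        a1 <- armWithin(r1); a2 <- armWithin(r2)
      } else if (cl == "snorna_mrna") {
        r1 <- sample(snoIds, 1L)
        a1 <- armWithin(r1)
        repeat {
          r2 <- sample(mFree, 1L)
          f <- featTab[featTab$ref_id == r2, , drop = FALSE]
          f <- f[f$kind != "exon", , drop = FALSE]
          f <- f[f$end - f$start >= lo, , drop = FALSE]
          if (nrow(f)) break
        }
        fr <- f[sample(nrow(f), 1L), ]
        armLen <- sample(lo:min(hi, fr$end - fr$start), 1L)
        s <- sample(fr$start:(fr$end - armLen), 1L)
        a2 <- c(s, s + armLen)
        feat <- fr$kind
      } else if (cl == "single_fragment") {
        r1 <- sample(names(refset), 1L)
        a1 <- armWithin(r1)
      } else {  # noise
        r1 <- NA_character_
      }

      if (cl == "noise") {
        insert <- randomDNA(1L, sample(25:45, 1L))
      } else if (cl == "single_fragment") {
        insert <- substr(seqChr[[r1]], a1[1] + 1L, a1[2])
      } else {
        s1 <- substr(seqChr[[r1]], a1[1] + 1L, a1[2])
        s2 <- substr(seqChr[[r2]], a2[1] + 1L, a2[2])
        if (runif(1) < 0.5) {  # ligation order is random
          tmp <- list(r1, a1, s1)
          r1 <- r2; a1 <- a2; s1 <- s2
          r2 <- tmp[[1]]; a2 <- tmp[[2]]; s2 <- tmp[[3]]
        }
        insert <- paste0(s1, s2)
      }
      umi <- randomDNA(1L, 3L)
      key <- paste(sampleIds[r], umi, insert, sep = "|")
      ok <- FALSE
      for (att in 1:24) {
        if (is.null(seen[[key]])) { ok <- TRUE; break }
        umi <- randomDNA(1L, 3L)
        key <- paste(sampleIds[r], umi, insert, sep = "|")
      }
      if (!ok) next  # resample the molecule itself
      seen[[key]] <- TRUE
      umis[r] <- umi
      inserts[r] <- insert
      truth[[r]] <- data.frame(
        read_id = sprintf("mol%06d", r), sample_id = sampleIds[r], class = cl,
        arm1_ref = r1, arm1_start = a1[1], arm1_end = a1[2],
        arm2_ref = r2, arm2_start = a2[1], arm2_end = a2[2],
        guide_snorna = gSno, guide_box = gBox, target_position = gPos,
        mrna_feature = feat, umi = umi, stringsAsFactors = FALSE)
      break
    }
  }
  truth <- do.call(rbind, truth)

  # PCR duplication + substitution errors
  p <- 1 / config$pcr_duplication_mean
  copies <- 1L + rgeom(n, p)
  full <- paste0(umis, barcodes, inserts, MIRCAT33_ADAPTER)
  idx <- rep.int(seq_len(n), copies)
  reads <- full[idx]
  ids <- sprintf("%s.c%d", truth$read_id[idx],
                 sequence(copies))
  rate <- config$substitution_error_rate
  if (rate > 0) {
    lensR <- nchar(reads)
    nerr <- rbinom(length(reads), lensR, rate)
    for (w in which(nerr > 0L)) {
      posns <- sample.int(lensR[w], nerr[w])
      for (pp in posns) {
        old <- substr(reads[w], pp, pp)
        substr(reads[w], pp, pp) <- sample(setdiff(DNA_BASES, old), 1L)
      }
    }
  }
  out <- list(reads = data.frame(id = ids, sequence = reads,
                                 stringsAsFactors = FALSE),
              truth = truth)
  if (!is.null(fastqPath)) {
    writeSimpleFastq(out$reads, fastqPath)
    out$fastqPath <- fastqPath
  }
  if (!is.null(truthPath)) {
    tr <- truth
    tr$arm1_start <- tr$arm1_start + 1L  # 1-based inclusive on disk
    tr$arm2_start <- tr$arm2_start + 1L
    write.table(tr, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
    out$truthPath <- truthPath
  }
  out
}

# constant-Q40 FASTQ writer (the pipeline does not use qualities)
writeSimpleFastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    strrep("I", nchar(reads$sequence))), con, sep = "\n")
  invisible(path)
}

#' Simulate a differential-expression table with enriched CLASH targets
#'
#' Synthetic gene universe for the over-representation tests: every gene
#' gets an adjusted p-value; genes in `targetGenes` are differentially
#' expressed at `fold` times the background rate.
#'
#' @param nGenes universe size.
#' @param targetGenes character vector of target gene ids (subset of the
#'   generated universe `gene00001...`).
#' @param baseRate background DE probability.
#' @param fold enrichment factor for targets.
#' @param seed integer seed.
#' @return data.frame `gene_id`, `log2_fold_change`, `p_adjusted`.
#' @export
simulateDETable <- function(nGenes = 5000L, targetGenes = character(),
                            baseRate = 0.05, fold = 3, seed = 1L) {
  set.seed(deriveSeed(seed, 303L))
  ids <- sprintf("gene%05d", seq_len(nGenes))
  rate <- ifelse(ids %in% targetGenes, pmin(1, baseRate * fold), baseRate)
  de <- runif(nGenes) < rate
  padj <- ifelse(de, runif(nGenes, 0, 0.049), runif(nGenes, 0.05, 1))
  data.frame(gene_id = ids,
             log2_fold_change = stats::rnorm(nGenes, ifelse(de, 1.5, 0), 0.5),
             p_adjusted = padj, stringsAsFactors = FALSE)
}
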