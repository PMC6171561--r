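test_that("snoRNA records get extended, clipped and host genes masked", {
  set.seed(1)
  chr <- randomSeq(1200)
  chrSmall <- randomSeq(130)
  tg <- writeTinyGenome(
    c(chr1 = chr, chr2 = chrSmall),
    list(list(contig = "chr1", start1 = 501, end1 = 600, strand = "+",
              id = "snoA", biotype = "snoRNA"),
         list(contig = "chr1", start1 = 1, end1 = 1000, strand = "+",
              id = "host", biotype = "mRNA"),
         list(contig = "chr2", start1 = 6, end1 = 100, strand = "+",
              id = "snoB", biotype = "snoRNA")))
  rs <- buildReference(tg$fasta, tg$gff3, snornaExtension = 20L)

  # interior snoRNA: gene +/- 20 nt
  expect_equal(seqLen(rs, "snoA"), 140L)
  expect_equal(as.character(refSequences(rs)[["snoA"]]),
               substr(chr, 481, 620))
  # left-clipped snoRNA at the contig start: [5,100) 0-based -> [0,120)
  expect_equal(seqLen(rs, "snoB"), 120L)
  expect_equal(as.character(refSequences(rs)[["snoB"]]),
               substr(chrSmall, 1, 120))
  # host gene: snoRNA footprint replaced by N, length conserved
  host <- as.character(refSequences(rs)[["host"]])
  expect_equal(nchar(host), 1000L)
  expect_equal(substr(host, 501, 600), strrep("N", 100))
  expect_equal(substr(host, 1, 500), substr(chr, 1, 500))
  # snoRNA record itself is unmasked
  expect_false(grepl("N", as.character(refSequences(rs)[["snoA"]])))
})

test_that("missing contigs and overlapping features are hard errors", {
  tg <- writeTinyGenome(
    c(chr1 = randomSeq(500)),
    list(list(contig = "chrX", start1 = 10, end1 = 90, strand = "+",
              id = "g1", biotype = "mRNA")))
  expect_error(buildReference(tg$fasta, tg$gff3), "g1.*chrX")

  tg2 <- writeTinyGenome(
    c(chr1 = randomSeq(500)),
    list(list(contig = "chr1", start1 = 1, end1 = 400, strand = "+",
              id = "g2", biotype = "mRNA")),
    list(list(contig = "chr1", type = "CDS", start1 = 1, end1 = 200,
              strand = "+", id = "c1", parent = "g2"),
         list(contig = "chr1", type = "CDS", start1 = 150, end1 = 400,
              strand = "+", id = "c2", parent = "g2")))
  expect_error(buildReference(tg2$fasta, tg2$gff3), "overlapping")
})

test_that("minus-strand genes are stored 5'->3' with flipped features", {
  set.seed(2)
  chr <- randomSeq(600)
  tg <- writeTinyGenome(
    c(chr1 = chr),
    list(list(contig = "chr1", start1 = 101, end1 = 400, strand = "-",
              id = "gm", biotype = "mRNA")),
    list(list(contig = "chr1", type = "five_prime_UTR", start1 = 351,
              end1 = 400, strand = "-", id = "u5", parent = "gm"),
         list(contig = "chr1", type = "CDS", start1 = 101, end1 = 350,
              strand = "-", id = "cd", parent = "gm")))
  rs <- buildReference(tg$fasta, tg$gff3)
  sq <- as.character(refSequences(rs)[["gm"]])
  expect_equal(sq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(chr, 101, 400)))[[1]]))
  ft <- refFeatures(rs)
  # genomic [350,400) on minus = transcript-local [0,50)
  expect_equal(ft$start[ft$kind == "five_prime_UTR"], 0L)
  expect_equal(ft$end[ft$kind == "five_prime_UTR"], 50L)
  expect_equal(ft$start[ft$kind == "CDS"], 50L)
  expect_equal(ft$end[ft$kind == "CDS"], 300L)
})

test_that("locateBoxes finds planted terminal motifs and validates curation", {
  lead <- strrep("AC", 2)
  seqv <- paste0(lead, "ATGATGA", strrep("CA", 29), "CTGA",
                 paste(rep("A", 7), collapse = ""))
  expect_equal(nchar(seqv), 80L)
  bx <- locateBoxes(seqv)
  expect_false(bx$unannotatable)
  expect_equal(c(bx$boxC_start, bx$boxC_end), c(4L, 11L))
  expect_equal(c(bx$boxD_start, bx$boxD_end), c(69L, 73L))

  # curated annotation is returned verbatim, but invalid order is rejected
  ua <- bx
  expect_identical(locateBoxes(seqv, userAnnotation = ua)$boxC_start, 4L)
  bad <- bx
  bad$boxC_start <- 69L; bad$boxC_end <- 76L
  bad$boxD_start <- 4L; bad$boxD_end <- 8L
  expect_error(locateBoxes(seqv, userAnnotation = bad), "precede")

  # no CUGA in the last 20 nt -> unannotatable, not an error
  set.seed(3)
  noD <- paste0("ATGATGA", randomSeq(53), strrep("A", 20))
  expect_true(locateBoxes(noD)$unannotatable)
})

test_that("simulator-planted boxes are recovered exactly (error-free)", {
  simref <- fixtureRef()
  planted <- boxAnnotations(simref$refset)
  found <- boxAnnotations(annotateBoxes(simref$refset, extension = 20L))
  found <- found[match(planted$snorna_id, found$snorna_id), ]
  for (col in c("boxC_start", "boxC_end", "boxD_start", "boxD_end"))
    expect_equal(found[[col]], planted[[col]], info = col)
  has <- !is.na(planted$boxDprime_start)
  expect_gt(sum(has), 0L)
  for (col in c("boxDprime_start", "boxDprime_end",
                "boxCprime_start", "boxCprime_end"))
    expect_equal(found[[col]][has], planted[[col]][has], info = col)
})

test_that("methylation-site tables validate, count and round-trip", {
  simref <- fixtureRef()
  ms <- methylationSites(simref$refset)
  expect_gt(nrow(ms), 0L)
  # round-trip through writer
  path <- tempfile(fileext = ".tsv")
  writeMethylationSites(ms, path)
  back <- loadMethylationSites(path, simref$refset)
  expect_equal(back, ms)
  # empty table -> empty list
  writeMethylationSites(ms[0, ], path)
  expect_equal(nrow(loadMethylationSites(path, simref$refset)), 0L)
  # nucleotide disagreeing with the reference -> error naming the row
  bad <- ms
  ref <- substr(as.character(refSequences(simref$refset)[[bad$target_id[2]]]),
                bad$position[2], bad$position[2])
  bad$nucleotide[2] <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(loadMethylationSites(bad, simref$refset), "row 2")
  # out-of-range position
  bad2 <- ms
  bad2$position[1] <- 10^7L
  expect_error(loadMethylationSites(bad2, simref$refset), "row 1")
})

test_that("reference bundles round-trip losslessly", {
  simref <- fixtureRef()
  dir <- tempfile("bundle")
  writeReferenceBundle(simref$refset, dir)
  back <- readReferenceBundle(dir)
  expect_equal(names(back), names(simref$refset))
  expect_equal(as.character(refSequences(back)),
               as.character(refSequences(simref$refset)))
  expect_equal(refCategory(back), refCategory(simref$refset))
  expect_equal(refFeatures(back), refFeatures(simref$refset))
  expect_equal(methylationSites(back), methylationSites(simref$refset))
  expect_equal(boxAnnotations(back)$boxD_start,
               boxAnnotations(simref$refset)$boxD_start)
})
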