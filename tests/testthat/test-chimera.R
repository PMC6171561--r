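# small hand-built reference for alignment unit tests
chimeraRefset <- function() {
  memo("chimref", function() {
    set.seed(42)
    shared <- randomSeq(30)   # duplicated verbatim in rRNA and snoRNA records
    sno <- paste0(randomSeq(40), shared, randomSeq(40))
    rrna <- paste0(randomSeq(200), shared, randomSeq(200))
    mrna <- randomSeq(300)
    new("ReferenceSet",
        sequences = Biostrings::DNAStringSet(
          c(RDNA = rrna, SNO1 = sno, M1 = mrna)),
        category = c("rRNA", "snoRNA", "mRNA"),
        features = data.frame(ref_id = character(), kind = character(),
                              start = integer(), end = integer()),
        boxes = data.frame(), methylationSites = data.frame())
  })
}

test_that("an exact substring aligns once at full identity over the read", {
  rs <- chimeraRefset()
  read <- substr(as.character(refSequences(rs)[["M1"]]), 101, 130)
  al <- alignFragments(read, rs)
  expect_gte(nrow(al), 1L)
  top <- al[1, ]
  expect_equal(top$reference_id, "M1")
  expect_equal(c(top$read_start, top$read_end), c(0L, 30L))
  expect_equal(c(top$ref_start, top$ref_end), c(100L, 130L))
  expect_equal(top$identity, 1.0)
  expect_equal(top$score, 60L)
})

test_that("reads sharing no seed k-mer with the reference align nowhere", {
  rs <- chimeraRefset()
  refs <- as.character(refSequences(rs))
  refsAll <- c(refs, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(refs))))
  hasSharedKmer <- function(read, k = 11L) {
    kmers <- unique(substring(read, 1:(nchar(read) - k + 1L),
                              k:nchar(read)))
    any(vapply(kmers, function(km)
      any(grepl(km, refsAll, fixed = TRUE)), logical(1)))
  }
  set.seed(99)
  tested <- 0L
  while (tested < 20L) {
    read <- randomSeq(30)
    if (hasSharedKmer(read)) next   # exhaustive substring check as the oracle
    tested <- tested + 1L
    expect_equal(nrow(alignFragments(read, rs)), 0L)
  }
})

test_that("two-arm reads yield hybrids with the constructed intervals", {
  rs <- chimeraRefset()
  refs <- as.character(refSequences(rs))
  read <- paste0(substr(refs[["RDNA"]], 101, 130),  # [100,130)
                 substr(refs[["M1"]], 51, 75))      # [50,75)
  al <- alignFragments(read, rs)
  cc <- callChimera(read, al, rs)
  expect_equal(cc$status, "hybrid")
  arms <- list(cc$arm1, cc$arm2)
  ids <- vapply(arms, `[[`, character(1), "reference_id")
  expect_setequal(ids, c("RDNA", "M1"))
  rd <- arms[[which(ids == "RDNA")]]
  m1 <- arms[[which(ids == "M1")]]
  expect_equal(c(rd$ref_start, rd$ref_end), c(100L, 130L))
  expect_equal(c(m1$ref_start, m1$ref_end), c(50L, 75L))
})

test_that("reads within a single record are 'single', junk is 'unmapped'", {
  rs <- chimeraRefset()
  read <- substr(as.character(refSequences(rs)[["RDNA"]]), 201, 245)
  expect_equal(callChimera(read, alignFragments(read, rs), rs)$status,
               "single")
  set.seed(5)
  junk <- randomSeq(40, alphabet = c("A", "T"))  # AT-only, matches nothing
  expect_equal(callChimera(junk, alignFragments(junk, rs), rs)$status,
               "unmapped")
})

test_that("score-tied arms prefer the snoRNA record and order it first", {
  rs <- chimeraRefset()
  refs <- as.character(refSequences(rs))
  shared <- substr(refs[["SNO1"]], 41, 70)   # identical in RDNA and SNO1
  read <- paste0(shared, substr(refs[["M1"]], 201, 230))
  al <- alignFragments(read, rs)
  # the shared arm truly ties between the two records
  sharedHits <- al[al$read_start <= 2, ]
  expect_setequal(unique(sharedHits$reference_id), c("RDNA", "SNO1"))
  cc <- callChimera(read, al, rs)
  expect_equal(cc$status, "hybrid")
  expect_equal(cc$arm1$reference_id, "SNO1")
  expect_equal(cc$arm2$reference_id, "M1")
})

test_that("chimera calling is deterministic and arms cover >= 90% of the read", {
  fx <- fixtureClean()
  again <- callHybrids(fx$pp$processed, fx$simref$refset)
  expect_identical(again$hybrids, fx$ch$hybrids)
  expect_identical(again$status, fx$ch$status)
  hy <- fx$ch$hybrids
  insLen <- nchar(fx$pp$processed$insert[match(hy$read_id,
                                               fx$pp$processed$read_id)])
  cov <- (hy$arm1_read_end - hy$arm1_read_start) +
    (hy$arm2_read_end - hy$arm2_read_start)
  expect_true(all(cov >= 0.9 * insLen))
})

test_that("canonical order puts the snoRNA arm first on simulated hybrids", {
  fx <- fixtureClean()
  hy <- fx$ch$hybrids
  cats <- refCategory(fx$simref$refset)
  arm1Sno <- cats[hy$arm1_ref] == "snoRNA"
  arm2Sno <- cats[hy$arm2_ref] == "snoRNA"
  # wherever exactly one arm is a snoRNA, it is arm1
  expect_true(all(arm1Sno[!arm2Sno]))
})
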