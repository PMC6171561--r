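test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 21L, n_snorna = 6L, n_mrna = 10L,
                   rdna_length = 2000L, n_methylation_sites = 8L,
                   n_reads = 150L)
  a <- simulateReference(cfg, dir = tempfile())
  b <- simulateReference(cfg, dir = tempfile())
  expect_identical(as.character(refSequences(a$refset)),
                   as.character(refSequences(b$refset)))
  expect_identical(a$plants, b$plants)
  ra <- simulateReads(a, cfg)
  rb <- simulateReads(b, cfg)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$truth, rb$truth)
})

test_that("planted +5 geometry: snoRNA base 5 nt upstream of the box pairs the site", {
  simref <- fixtureRef()
  bx <- boxAnnotations(simref$refset)
  pl <- simref$plants
  guides <- pl[pl$kind %in% c("guide_D", "guide_Dprime"), ]
  expect_gt(nrow(guides), 0L)
  for (r in seq_len(nrow(guides))) {
    g <- guides[r, ]
    b <- bx[bx$snorna_id == g$snorna_id, ]
    d0 <- if (g$kind == "guide_D") b$boxD_start else b$boxDprime_start
    sno <- as.character(refSequences(simref$refset)[[g$snorna_id]])
    tgt <- as.character(refSequences(simref$refset)[[g$target_id]])
    # element abuts the box and spans 12-14 nt
    expect_equal(g$element_end, d0)
    expect_true(g$element_end - g$element_start >= 12)
    # full element is the reverse complement of the target window
    expect_equal(substr(sno, g$element_start + 1, g$element_end),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAStringSet(substr(tgt, g$window_start + 1,
                                                   g$window_end)))[[1]]))
    # +5: snoRNA base at d-5 complements the methylated nucleotide
    snoBase <- substr(sno, d0 - 4, d0 - 4)
    siteBase <- substr(tgt, g$site_position, g$site_position)
    expect_equal(snoBase, chartr("ACGT", "TGCA", siteBase))
  }
})

test_that("zero methylation sites disables guide and blocking classes", {
  cfg <- simConfig(seed = 4L, n_methylation_sites = 0L, n_reads = 60L,
                   n_snorna = 4L, n_mrna = 8L, rdna_length = 1500L)
  expect_equal(unname(cfg$class_mix[["cognate_guide"]]), 0)
  expect_equal(unname(cfg$class_mix[["blocking"]]), 0)
  simref <- simulateReference(cfg, dir = tempfile())
  expect_equal(nrow(methylationSites(simref$refset)), 0L)
  sim <- simulateReads(simref, cfg)
  expect_false(any(sim$truth$class %in% c("cognate_guide", "blocking")))
})

test_that("error-free reads reconstruct exactly from the truth intervals", {
  fx <- fixtureClean()
  tr <- fx$sim$truth
  seqs <- setNames(as.character(refSequences(fx$simref$refset)),
                   names(fx$simref$refset))
  bc <- defaultBarcodes()
  reads <- fx$sim$reads
  # no duplication, no errors: one FASTQ record per truth row
  expect_equal(nrow(reads), nrow(tr))
  idx <- match(moleculeId(reads$id), tr$read_id)
  expect_false(anyNA(idx))
  for (r in sample(seq_len(nrow(tr)), 150L)) {
    t <- tr[idx[r], ]
    if (t$class == "noise") next
    arm1 <- substr(seqs[[t$arm1_ref]], t$arm1_start + 1, t$arm1_end)
    arm2 <- if (!is.na(t$arm2_ref))
      substr(seqs[[t$arm2_ref]], t$arm2_start + 1, t$arm2_end) else ""
    barcode <- bc$barcode[bc$sample_id == t$sample_id]
    expect_equal(reads$sequence[r],
                 paste0(t$umi, barcode, arm1, arm2, MIRCAT33_ADAPTER))
  }
})

test_that("truth guide fields are present iff the class is cognate_guide", {
  fx <- fixtureClean()
  tr <- fx$sim$truth
  cg <- tr$class == "cognate_guide"
  expect_true(all(!is.na(tr$guide_snorna[cg])))
  expect_true(all(!is.na(tr$target_position[cg])))
  expect_true(all(is.na(tr$guide_snorna[!cg])))
  expect_true(all(is.na(tr$target_position[!cg])))
})

test_that("FASTQ output matches the in-memory reads and gzips identically", {
  cfg <- simConfig(seed = 7L, n_reads = 40L, n_snorna = 4L, n_mrna = 8L,
                   rdna_length = 1500L, n_methylation_sites = 6L)
  simref <- simulateReference(cfg, dir = tempfile())
  fq <- tempfile(fileext = ".fastq")
  sim <- simulateReads(simref, cfg, fastqPath = fq,
                       truthPath = tempfile(fileext = ".tsv"))
  parsed <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(as.character(unname(parsed)), sim$reads$sequence)
  expect_equal(sub("\\s.*$", "", names(parsed)), sim$reads$id)
})
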