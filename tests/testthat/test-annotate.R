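test_that("coverage profiles count each covered position once per hybrid", {
  fx <- fixtureClean()
  rs <- fx$simref$refset
  hy <- data.frame(read_id = "h1", sample = "Aa", count = 3L,
                   arm1_ref = "snoR01", arm1_read_start = 0L,
                   arm1_read_end = 10L, arm1_ref_start = 5L,
                   arm1_ref_end = 15L,
                   arm2_ref = "RDN37", arm2_read_start = 10L,
                   arm2_read_end = 20L, arm2_ref_start = 10L,
                   arm2_ref_end = 20L, dG = -15, stringsAsFactors = FALSE)
  pf <- coverageProfile(hy, rs, "RDN37")
  expect_equal(sum(pf$counts), 10L)            # one arm of 10 nt, count 1 each
  expect_equal(pf$counts[11:20], rep(1L, 10))  # positions 10..19
  expect_equal(pf$counts[1:10], rep(0L, 10))
  # empty set -> all zero
  expect_true(all(coverageProfile(hy[0, ], rs, "RDN37")$counts == 0L))
  # unknown reference is a hard error
  expect_error(coverageProfile(hy, rs, "nope"), "unknown reference")
})

test_that("profile mass equals summed clipped arm lengths; profiles are additive", {
  fx <- fixtureClean()
  rs <- fx$simref$refset
  hy <- fx$hybrids
  onR <- hy[hy$arm2_ref == "RDN37", ]
  pf <- coverageProfile(onR, rs, "RDN37")
  rdnaLen <- seqLen(rs, "RDN37")
  clipped <- pmin(onR$arm2_ref_end, rdnaLen) - pmax(onR$arm2_ref_start, 0L)
  expect_equal(sum(pf$counts), sum(clipped))
  # additivity over a disjoint split
  half <- seq_len(nrow(onR) %/% 2)
  pA <- coverageProfile(onR[half, ], rs, "RDN37")
  pB <- coverageProfile(onR[-half, ], rs, "RDN37")
  expect_equal(pA$counts + pB$counts, pf$counts)
  # flanked windows shift coordinates but conserve interior mass
  pfF <- coverageProfile(onR, rs, "RDN37", flank = 100L)
  expect_equal(length(pfF$counts), rdnaLen + 200L)
  expect_equal(sum(pfF$counts), sum(pf$counts))  # no arm reaches the flanks
})

test_that("midpoint rule assigns features, boundaries going downstream", {
  rs <- fixtureRef()$refset
  feats <- refFeatures(rs)
  gene <- feats[feats$ref_id == "mRNA010" & feats$kind != "exon", ]
  gene <- gene[order(gene$start), ]
  cds1End <- gene$end[gene$kind == "CDS"][1]       # CDS | intron boundary
  u5End <- gene$end[gene$kind == "five_prime_UTR"]
  mk <- function(s, e) data.frame(
    read_id = "h", sample = "Aa", count = 1L,
    arm1_ref = "snoR01", arm1_read_start = 0L, arm1_read_end = 20L,
    arm1_ref_start = 30L, arm1_ref_end = 50L,
    arm2_ref = "mRNA010", arm2_read_start = 20L, arm2_read_end = 40L,
    arm2_ref_start = s, arm2_ref_end = e, dG = -15, stringsAsFactors = FALSE)
  # arm wholly within the first CDS
  fa <- assignMrnaFeatures(mk(u5End + 2L, u5End + 22L), rs)
  expect_equal(fa$feature, "CDS")
  # arm spanning the 5'UTR/CDS junction with its midpoint in the UTR
  fa2 <- assignMrnaFeatures(mk(u5End - 15L, u5End + 5L), rs)
  expect_equal(fa2$feature, "five_prime_UTR")
  # even-length arm centred on the CDS|intron boundary: midpoint index is
  # the downstream of the two central positions -> intron
  fa3 <- assignMrnaFeatures(mk(cds1End - 10L, cds1End + 10L), rs)
  expect_equal(fa3$feature, "intron")
})

test_that("per-feature counts on simulated mRNA hybrids match the planted truth", {
  fx <- fixtureClean()
  hy <- fx$hybrids
  tr <- fx$sim$truth
  m <- match(moleculeId(hy$read_id), tr$read_id)
  sm <- which(!is.na(m) & tr$class[m] == "snorna_mrna")
  fa <- assignMrnaFeatures(hy[sm, ], fx$simref$refset)
  expect_equal(nrow(fa), length(sm))
  counts <- tabulateFeatures(fa)
  planted <- table(factor(tr$mrna_feature[m[sm]],
                          levels = names(counts)))
  expect_equal(unname(counts), as.integer(planted))
  # feature counts sum to the number of classified hybrids
  expect_equal(sum(counts), sum(fa$feature != "unclassified"))
})
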