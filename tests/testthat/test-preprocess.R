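test_that("demultiplex routes by exact barcode at offset 3 and records the UMI", {
  insert <- strrep("ACGT", 8)
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    sequence = c(paste0("ACG", "TAAGC", insert),      # L5Aa barcode
                 paste0("TTT", "GACTTAGC", insert),   # L5Cd (longest)
                 paste0("AAA", "TTTTTTTT", insert)),  # matches nothing
    stringsAsFactors = FALSE)
  dm <- demultiplex(reads)
  expect_equal(dm$sample_id, c("Aa", "Cd", "unassigned"))
  expect_equal(dm$umi, c("ACG", "TTT", NA))
  expect_equal(dm$sequence[1], insert)
  expect_equal(dm$sequence[2], insert)
  expect_equal(dm$sequence[3], reads$sequence[3])  # unassigned untouched
})

test_that("sample sheets must be prefix-free with unique ids", {
  sheet <- data.frame(sample_id = c("s1", "s2"),
                      barcode = c("CTAGC", "CTAGCA"))
  reads <- data.frame(id = "r", sequence = strrep("A", 40))
  expect_error(demultiplex(reads, sheet), "prefix-free")
  dup <- data.frame(sample_id = c("s1", "s1"),
                    barcode = c("CTAGC", "GGAGC"))
  expect_error(demultiplex(reads, dup), "duplicate")
})

test_that("adapter trimming handles full, partial, mismatched and absent adapters", {
  insert <- strrep("GATC", 6)
  expect_equal(trimAdapter(paste0(insert, MIRCAT33_ADAPTER)), insert)
  # no adapter -> unchanged
  expect_equal(trimAdapter(insert), insert)
  # pure adapter -> dropped (length 0 < 16)
  expect_true(is.na(trimAdapter(MIRCAT33_ADAPTER)))
  # 6-nt adapter prefix at the 3' end
  expect_equal(trimAdapter(paste0(insert, substr(MIRCAT33_ADAPTER, 1, 6))),
               insert)
  # 5-nt prefix is below minOverlap -> kept
  short <- paste0(insert, substr(MIRCAT33_ADAPTER, 1, 5))
  expect_equal(trimAdapter(short), short)
  # full-length adapter with one substitution is still removed
  mm <- MIRCAT33_ADAPTER
  substr(mm, 10, 10) <- "A"
  expect_equal(trimAdapter(paste0(insert, mm)), insert)
})

test_that("duplicate collapsing is exact, UMI-aware and idempotent", {
  reads <- data.frame(
    id = sprintf("r%d", 1:5),
    sample_id = c("Aa", "Aa", "Aa", "Aa", "Bb"),
    umi = c("ACG", "ACG", "TTT", "ACG", "ACG"),
    sequence = c("AAACCCGGGTTTAAACCC", "AAACCCGGGTTTAAACCC",
                 "AAACCCGGGTTTAAACCC", "CCCGGGTTTAAACCCAAA",
                 "AAACCCGGGTTTAAACCC"),
    stringsAsFactors = FALSE)
  col <- collapseDuplicates(reads)
  expect_equal(nrow(col), 4L)  # same insert+umi collapses only within sample
  expect_equal(col$duplicate_count[col$umi == "ACG" &
                                     col$sample_id == "Aa" &
                                     col$insert == "AAACCCGGGTTTAAACCC"], 2L)
  expect_equal(sum(col$duplicate_count), nrow(reads))
  # idempotence
  again <- collapseDuplicates(data.frame(id = col$read_id,
                                         sample_id = col$sample_id,
                                         umi = col$umi,
                                         sequence = col$insert,
                                         stringsAsFactors = FALSE))
  expect_equal(again$insert, col$insert)
  expect_true(all(again$duplicate_count == 1L))
})

test_that("preprocessing conserves reads and collapses to the truth count", {
  fx <- fixtureClean()
  st <- fx$pp$stats
  expect_equal(unname(st[["assigned"]] + st[["unassigned"]]),
               unname(st[["input"]]))
  expect_equal(sum(fx$pp$processed$duplicate_count),
               unname(st[["assigned"]] - st[["dropped_short"]]))
  # error-free, duplication mean 1: collapse yields exactly the truth rows
  expect_equal(nrow(fx$pp$processed), nrow(fx$sim$truth))
})

test_that("PCR duplicates collapse to the exact truth-molecule count", {
  simref <- fixtureRef()
  cfg <- simConfig(seed = 31L, n_reads = 600L,
                   substitution_error_rate = 0, pcr_duplication_mean = 3)
  sim <- simulateReads(simref, cfg)
  expect_gt(nrow(sim$reads), nrow(sim$truth))
  pp <- preprocessReads(sim$reads)
  expect_equal(nrow(pp$processed), nrow(sim$truth))
  expect_equal(sum(pp$processed$duplicate_count), nrow(sim$reads))
})
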