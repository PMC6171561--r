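test_that("the energy filter keeps dG <= -12 inclusively, preserving order", {
  hy <- randomHybrids(50)
  hy$dG[1:2] <- c(-12.0, -11.9)
  kept <- filterEnergy(hy)
  expect_true("h0001" %in% kept$read_id)    # -12.0 retained (inclusive)
  expect_false("h0002" %in% kept$read_id)   # -11.9 removed
  # set-comprehension oracle + order preservation
  expect_equal(kept$read_id, hy$read_id[hy$dG <= -12])
  # empty input, empty output
  expect_equal(nrow(filterEnergy(hy[0, ])), 0L)
  # unannotated dG is a hard error
  bad <- hy
  bad$dG[5] <- NA
  expect_error(filterEnergy(bad), "annotated")
})

test_that("singletons are unreproducible; mutual overlaps merge into one site", {
  one <- randomHybrids(1)
  cl1 <- clusterAndSupport(one)
  expect_equal(cl1$sites$support, 1L)
  expect_false(cl1$hybrids$reproducible)

  # three mutually overlapping hybrids on the same reference pair
  hy <- data.frame(
    read_id = c("a", "b", "c"), sample = "Aa", count = 1L,
    arm1_ref = "r1", arm1_read_start = 0L, arm1_read_end = 20L,
    arm1_ref_start = c(100L, 110L, 105L), arm1_ref_end = c(130L, 140L, 135L),
    arm2_ref = "r2", arm2_read_start = 20L, arm2_read_end = 40L,
    arm2_ref_start = c(50L, 60L, 55L), arm2_ref_end = c(80L, 90L, 85L),
    dG = -20, stringsAsFactors = FALSE)
  cl <- clusterAndSupport(hy)
  expect_equal(nrow(cl$sites), 1L)
  expect_equal(cl$sites$support, 3L)
  expect_equal(c(cl$sites$ref1_start, cl$sites$ref1_end), c(100L, 140L))
  expect_equal(c(cl$sites$ref2_start, cl$sites$ref2_end), c(50L, 90L))
  expect_true(all(cl$hybrids$reproducible))
})

test_that("both arms must overlap for hybrids to cluster together", {
  hy <- data.frame(
    read_id = c("a", "b"), sample = "Aa", count = 1L,
    arm1_ref = "r1", arm1_read_start = 0L, arm1_read_end = 20L,
    arm1_ref_start = c(100L, 110L), arm1_ref_end = c(130L, 140L),
    arm2_ref = "r2", arm2_read_start = 20L, arm2_read_end = 40L,
    arm2_ref_start = c(50L, 500L), arm2_ref_end = c(80L, 530L),
    dG = -20, stringsAsFactors = FALSE)
  cl <- clusterAndSupport(hy)   # arm1 overlaps, arm2 does not
  expect_equal(nrow(cl$sites), 2L)
  expect_false(any(cl$hybrids$reproducible))
})

test_that("clustering equals brute-force connected components on random sets", {
  set.seed(77)
  hy <- randomHybrids(400, refs = c("r1", "r2"), span = 250L)
  cl <- clusterAndSupport(hy)
  oracle <- bruteClusters(hy)
  expect_true(samePartition(cl$hybrids$cluster_id, oracle))
  # support conservation: cluster sizes sum to the number of hybrids
  expect_equal(sum(cl$sites$support), nrow(hy))
  # reproducibility flag equals cluster-size >= 2 under the oracle
  sz <- table(oracle)[as.character(oracle)]
  expect_equal(cl$hybrids$reproducible, as.logical(sz >= 2))
})

test_that("clustering is invariant under input permutation", {
  set.seed(78)
  hy <- randomHybrids(120, refs = c("r1", "r2"), span = 150L)
  cl <- clusterAndSupport(hy)
  perm <- sample(nrow(hy))
  clP <- clusterAndSupport(hy[perm, ])
  rep1 <- cl$hybrids$read_id[cl$hybrids$reproducible]
  rep2 <- clP$hybrids$read_id[clP$hybrids$reproducible]
  expect_setequal(rep1, rep2)
  # site tables agree up to row identity
  expect_setequal(cl$sites$member_ids, clP$sites$member_ids)
})

test_that("single-linkage chains merge non-adjacent hybrids through a bridge", {
  # a and c do not overlap each other, but both overlap b
  hy <- data.frame(
    read_id = c("a", "b", "c"), sample = "Aa", count = 1L,
    arm1_ref = "r1", arm1_read_start = 0L, arm1_read_end = 20L,
    arm1_ref_start = c(100L, 118L, 136L), arm1_ref_end = c(120L, 138L, 156L),
    arm2_ref = "r2", arm2_read_start = 20L, arm2_read_end = 40L,
    arm2_ref_start = c(200L, 218L, 236L), arm2_ref_end = c(220L, 238L, 256L),
    dG = -20, stringsAsFactors = FALSE)
  cl <- clusterAndSupport(hy)
  expect_equal(nrow(cl$sites), 1L)
  expect_equal(cl$sites$support, 3L)
})
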