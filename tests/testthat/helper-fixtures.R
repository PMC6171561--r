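# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# small simulated reference shared across module tests
fixtureRef <- function() {
  memo("ref", function() {
    simulateReference(simConfig(seed = 11L), dir = tempfile("fxref"))
  })
}

# clean library: no errors, no PCR duplication (800 molecules)
fixtureClean <- function() {
  memo("clean", function() {
    simref <- fixtureRef()
    cfg <- simConfig(seed = 11L, n_reads = 800L,
                     substitution_error_rate = 0, pcr_duplication_mean = 1)
    sim <- simulateReads(simref, cfg)
    pp <- preprocessReads(sim$reads)
    ch <- callHybrids(pp$processed, simref$refset)
    hy <- annotateDuplexes(ch$hybrids, simref$refset)
    list(simref = simref, sim = sim, pp = pp, ch = ch, hybrids = hy)
  })
}

# strip the PCR-copy suffix from hybrid read ids -> truth molecule ids
moleculeId <- function(readId) sub("[.]c[0-9]+$", "", readId)

# tiny hand-built genome + gene models written as FASTA/GFF3
writeTinyGenome <- function(contigs, genes, children = NULL) {
  dir <- tempfile("tiny")
  dir.create(dir)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fa)
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf("%s\tt\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                              g$contig, g$start1, g$end1, g$strand, g$id,
                              g$biotype))
  }
  for (ch in children %||% list()) {
    lines <- c(lines, sprintf("%s\tt\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              ch$contig, ch$type, ch$start1, ch$end1,
                              ch$strand, ch$id, ch$parent))
  }
  gff <- file.path(dir, "genes.gff3")
  writeLines(lines, gff)
  list(fasta = fa, gff3 = gff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random hybrid table for clustering/filter oracles
randomHybrids <- function(n, refs = c("r1", "r2", "r3"), span = 300L) {
  s1 <- sample.int(span, n, replace = TRUE)
  s2 <- sample.int(span, n, replace = TRUE)
  data.frame(
    read_id = sprintf("h%04d", seq_len(n)),
    sample = sample(c("A", "B"), n, replace = TRUE),
    count = sample(1:4, n, replace = TRUE),
    arm1_ref = sample(refs, n, replace = TRUE),
    arm1_read_start = 0L, arm1_read_end = 20L,
    arm1_ref_start = s1, arm1_ref_end = s1 + sample(15:35, n, replace = TRUE),
    arm2_ref = sample(refs, n, replace = TRUE),
    arm2_read_start = 20L, arm2_read_end = 40L,
    arm2_ref_start = s2, arm2_ref_end = s2 + sample(15:35, n, replace = TRUE),
    dG = round(stats::runif(n, -30, -5), 2),
    stringsAsFactors = FALSE
  )
}

# O(n^2) brute-force single-linkage clustering oracle for hybrids
bruteClusters <- function(hy, minOverlap = 1L) {
  n <- nrow(hy)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hy$arm1_ref[i] != hy$arm1_ref[j] || hy$arm2_ref[i] != hy$arm2_ref[j])
      next
    ov1 <- min(hy$arm1_ref_end[i], hy$arm1_ref_end[j]) -
      max(hy$arm1_ref_start[i], hy$arm1_ref_start[j])
    ov2 <- min(hy$arm2_ref_end[i], hy$arm2_ref_end[j]) -
      max(hy$arm2_ref_start[i], hy$arm2_ref_start[j])
    if (ov1 >= minOverlap && ov2 >= minOverlap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# partition equality up to relabelling
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# record length without relying on attached Bioconductor generics
seqLen <- function(rs, id) nchar(as.character(refSequences(rs)[[id]]))

# independent oracle: two-sided Fisher p by full hypergeometric enumeration
enumFisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(N, c1)
  pObs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}


CHIMERA_CLASSES <- c("cognate_guide", "blocking", "snorna_snorna",
                     "snorna_mrna")

# per-truth-molecule recovery (arm boundaries within +/- tol) and the
# spurious-hybrid rate among called hybrids
recoveryStats <- function(hybrids, truth, tol = 2L) {
  chim <- truth[truth$class %in% CHIMERA_CLASSES, , drop = FALSE]
  hid <- moleculeId(hybrids$read_id)
  m <- match(hid, chim$read_id)
  spurious <- mean(is.na(m))
  within <- function(x, y) abs(x - y) <= tol
  okRow <- function(i) {
    t <- chim[m[i], ]; h <- hybrids[i, ]
    fwd <- h$arm1_ref == t$arm1_ref && h$arm2_ref == t$arm2_ref &&
      within(h$arm1_ref_start, t$arm1_start) &&
      within(h$arm1_ref_end, t$arm1_end) &&
      within(h$arm2_ref_start, t$arm2_start) &&
      within(h$arm2_ref_end, t$arm2_end)
    rev <- h$arm1_ref == t$arm2_ref && h$arm2_ref == t$arm1_ref &&
      within(h$arm1_ref_start, t$arm2_start) &&
      within(h$arm1_ref_end, t$arm2_end) &&
      within(h$arm2_ref_start, t$arm1_start) &&
      within(h$arm2_ref_end, t$arm1_end)
    fwd || rev
  }
  good <- vapply(which(!is.na(m)), okRow, logical(1))
  recoveredIds <- unique(hid[which(!is.na(m))[good]])
  list(recovery = length(recoveredIds) / nrow(chim),
       spurious = spurious,
       n_truth = nrow(chim), n_hybrids = nrow(hybrids))
}

# full error-bearing 20k-molecule simulation used by the acceptance suite
fixtureBig <- function() {
  memo("big", function() {
    simref <- fixtureRef()
    cfg <- simConfig(seed = 101L, n_reads = 20000L)
    sim <- simulateReads(simref, cfg)
    pp <- preprocessReads(sim$reads)
    ch <- callHybrids(pp$processed, simref$refset)
    list(cfg = cfg, sim = sim, pp = pp, ch = ch)
  })
}
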