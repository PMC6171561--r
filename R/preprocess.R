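#' Demultiplex CLASH reads by 5' barcode
#'
#' The library structure puts a random 3-nt tag at the read 5' end followed
#' by the sample barcode; the first 3 nt are recorded as the UMI and the
#' barcode is matched as an exact prefix at offset 3 (longest barcode tried
#' first). Reads matching no barcode go to the `"unassigned"` stream.
#' Barcodes must be prefix-free; matching is exact (no mismatches), since
#' the barcodes are short and unambiguous.
#'
#' @param reads data.frame with columns `id`, `sequence`, or a FASTQ path.
#' @param sampleSheet data.frame `sample_id`, `barcode` (DNA, length 5-8);
#'   defaults to the ten 5' linker barcodes.
#' @return data.frame `id`, `sample_id` (`"unassigned"` where unmatched),
#'   `umi`, `sequence` (barcode and tag stripped for assigned reads;
#'   untouched for unassigned).
#' @export
demultiplex <- function(reads, sampleSheet = defaultBarcodes()) {
  if (is.character(reads)) reads <- readFastqReads(reads)
  stopIfNot(!anyDuplicated(sampleSheet$sample_id),
            "duplicate sample_ids in sample sheet")
  bcs <- sampleSheet$barcode
  stopIfNot(all(nchar(bcs) >= 5L & nchar(bcs) <= 8L),
            "barcodes must be 5-8 nt")
  for (i in seq_along(bcs)) for (j in seq_along(bcs)) {
    if (i != j && startsWith(bcs[j], bcs[i]))
      stop(sprintf("sample sheet is not prefix-free: '%s' is a prefix of '%s'",
                   bcs[i], bcs[j]), call. = FALSE)
  }
  stopIfNot(all(nchar(reads$sequence) >= 3L + max(nchar(bcs)) + 1L),
            "reads must be at least 3 + max barcode length + 1 nt")

  umi <- substr(reads$sequence, 1L, 3L)
  rest <- substr(reads$sequence, 4L, nchar(reads$sequence))
  sampleId <- rep("unassigned", nrow(reads))
  consumed <- rep(0L, nrow(reads))
  for (i in order(nchar(bcs), decreasing = TRUE)) {   # longest barcode first
    hit <- sampleId == "unassigned" & startsWith(rest, bcs[i])
    sampleId[hit] <- sampleSheet$sample_id[i]
    consumed[hit] <- nchar(bcs[i])
  }
  out <- data.frame(id = reads$id, sample_id = sampleId, umi = umi,
                    sequence = ifelse(sampleId == "unassigned",
                                      reads$sequence,
                                      substr(rest, consumed + 1L, nchar(rest))),
                    stringsAsFactors = FALSE)
  out$umi[out$sample_id == "unassigned"] <- NA_character_
  out
}

readFastqReads <- function(path) {
  sq <- readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(sq)), sequence = as.character(sq),
             stringsAsFactors = FALSE)
}

#' Trim the 3' sequencing adapter
#'
#' Removes the adapter (miRCat-33 by default) from the read 3' end: the
#' leftmost position where a prefix of the adapter of length >=
#' `minOverlap` matches exactly through to the read end, or where the
#' full-length adapter matches with at most one mismatch. Reads shorter
#' than `minLength` after trimming are dropped.
#'
#' @param sequences character vector of read sequences.
#' @param adapter adapter sequence (default [MIRCAT33_ADAPTER]).
#' @param minOverlap minimum adapter prefix length at the read end.
#' @param minLength minimum insert length retained after trimming.
#' @return character vector of trimmed sequences, `NA` for dropped reads.
#' @export
trimAdapter <- function(sequences, adapter = MIRCAT33_ADAPTER,
                        minOverlap = 6L, minLength = 16L) {
  .trim_adapter_cpp(sequences, adapter, as.integer(minOverlap),
                    as.integer(minLength))
}

#' Collapse PCR duplicates
#'
#' Reads identical over (UMI, insert) within a sample collapse to a single
#' record whose `duplicate_count` is the multiplicity — the random 3-nt tag
#' distinguishes independent molecules with identical inserts. Output order
#' is deterministic (sample, then lexicographic by UMI + insert).
#'
#' @param reads data.frame with columns `id`, `sample_id`, `umi`,
#'   `sequence` (demultiplexed, adapter-trimmed).
#' @return data.frame `read_id` (the first contributing read), `sample_id`,
#'   `umi`, `insert`, `duplicate_count`.
#' @export
collapseDuplicates <- function(reads) {
  reads <- reads[!is.na(reads$sequence) & reads$sample_id != "unassigned", ,
                 drop = FALSE]
  if (!nrow(reads)) {
    return(data.frame(read_id = character(), sample_id = character(),
                      umi = character(), insert = character(),
                      duplicate_count = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(reads$sample_id, reads$umi, reads$sequence, sep = "\r")
  ord <- order(key, reads$id, method = "radix")
  reads <- reads[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  out <- data.frame(read_id = reads$id[first],
                    sample_id = reads$sample_id[first],
                    umi = reads$umi[first],
                    insert = reads$sequence[first],
                    duplicate_count = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full preprocessing stage
#'
#' Demultiplex, trim the 3' adapter, drop short inserts and collapse PCR
#' duplicates. Adapter trimming runs before collapsing so adapter-length
#' variation cannot split true duplicates.
#'
#' @inheritParams demultiplex
#' @inheritParams trimAdapter
#' @return list: `processed` (collapsed reads, see [collapseDuplicates()]),
#'   `stats` (input / assigned / unassigned / dropped counts).
#' @export
preprocessReads <- function(reads, sampleSheet = defaultBarcodes(),
                            adapter = MIRCAT33_ADAPTER, minOverlap = 6L,
                            minLength = 16L) {
  if (is.character(reads)) reads <- readFastqReads(reads)
  dm <- demultiplex(reads, sampleSheet)
  assigned <- dm$sample_id != "unassigned"
  dm$sequence[assigned] <- trimAdapter(dm$sequence[assigned], adapter,
                                       minOverlap, minLength)
  collapsed <- collapseDuplicates(dm)
  list(processed = collapsed,
       stats = c(input = nrow(reads), assigned = sum(assigned),
                 unassigned = sum(!assigned),
                 dropped_short = sum(assigned & is.na(dm$sequence)),
                 unique_molecules = nrow(collapsed)))
}
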