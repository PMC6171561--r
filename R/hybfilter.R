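#' Stability / reproducibility filter configuration
#'
#' `dgThreshold` keeps hybrids with a predicted duplex free energy at or
#' below the threshold (inclusive; -12 kcal/mol by default).
#' `minSupport` is the minimum number of independent (post-deduplication)
#' hybrids whose two arms both overlap for an interaction to count as
#' reproducible; `minArmOverlap` is the overlap required on each arm, nt.
#'
#' @param dgThreshold kcal/mol, keep `dG <= dgThreshold` (default -12).
#' @param minSupport minimum cluster size for reproducibility (default 2).
#' @param minArmOverlap minimum per-arm overlap in nt (default 1).
#' @return list of class `FilterConfig`.
#' @export
filterConfig <- function(dgThreshold = -12.0, minSupport = 2L,
                         minArmOverlap = 1L) {
  stopIfNot(minSupport >= 1L, "minSupport must be >= 1")
  stopIfNot(minArmOverlap >= 1L, "minArmOverlap must be >= 1")
  structure(list(dgThreshold = dgThreshold, minSupport = as.integer(minSupport),
                 minArmOverlap = as.integer(minArmOverlap)),
            class = "FilterConfig")
}

#' Energy filter: retain stable hybrids
#'
#' Keeps hybrids whose predicted duplex free energy is at or below the
#' threshold (`dG <= dgThreshold`), preserving input order.
#'
#' @param hybrids annotated hybrid table (`dG` column filled).
#' @param config a [filterConfig()].
#' @return the filtered hybrid table.
#' @export
filterEnergy <- function(hybrids, config = filterConfig()) {
  if (!nrow(hybrids)) return(hybrids)
  stopIfNot(!anyNA(hybrids$dG), "hybrids must be dG-annotated (see annotateDuplexes)")
  out <- hybrids[hybrids$dG <= config$dgThreshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster hybrids into interaction sites and flag reproducible ones
#'
#' Two hybrids demonstrate independent recovery of the same interaction
#' when they involve the same (reference1, reference2) pair and both their
#' arm1 and arm2 intervals overlap by at least `minArmOverlap` nt.
#' Connected components of that relation (single linkage) are the
#' interaction clusters; a hybrid is reproducible iff its cluster holds at
#' least `minSupport` distinct post-deduplication members. Support is
#' computed on the pooled set across samples, with sample provenance kept
#' on the member hybrids.
#'
#' @param hybrids canonically ordered hybrid table.
#' @param config a [filterConfig()].
#' @return list: `sites` (one row per cluster: `site_id`, `ref1_id`,
#'   union `ref1_start`/`ref1_end`, same for ref2, `support`,
#'   `member_ids`), `hybrids` (input plus `cluster_id` and `reproducible`
#'   columns).
#' @export
clusterAndSupport <- function(hybrids, config = filterConfig()) {
  n <- nrow(hybrids)
  if (!n) {
    sites <- data.frame(site_id = character(), ref1_id = character(),
                        ref1_start = integer(), ref1_end = integer(),
                        ref2_id = character(), ref2_start = integer(),
                        ref2_end = integer(), support = integer(),
                        member_ids = character(), stringsAsFactors = FALSE)
    hy <- hybrids
    hy$cluster_id <- character()
    hy$reproducible <- logical()
    return(list(sites = sites, hybrids = hy))
  }
  pairKey <- paste(hybrids$arm1_ref, hybrids$arm2_ref, sep = "\r")
  comp <- integer(n)
  nextComp <- 0L
  for (grpIdx in split(seq_len(n), pairKey)) {
    # edges where both arms overlap by >= minArmOverlap
    ir1 <- IRanges(hybrids$arm1_ref_start[grpIdx] + 1L,
                   hybrids$arm1_ref_end[grpIdx])
    ir2 <- IRanges(hybrids$arm2_ref_start[grpIdx] + 1L,
                   hybrids$arm2_ref_end[grpIdx])
    ov1 <- findOverlaps(ir1, minoverlap = config$minArmOverlap,
                        drop.self = TRUE, drop.redundant = TRUE)
    ov2 <- findOverlaps(ir2, minoverlap = config$minArmOverlap,
                        drop.self = TRUE, drop.redundant = TRUE)
    k1 <- paste(queryHits(ov1), subjectHits(ov1))
    k2 <- paste(queryHits(ov2), subjectHits(ov2))
    shared <- intersect(k1, k2)
    g <- igraph::make_empty_graph(n = length(grpIdx), directed = FALSE)
    if (length(shared)) {
      em <- do.call(rbind, lapply(strsplit(shared, " "), as.integer))
      g <- igraph::add_edges(g, t(em))
    }
    cmp <- igraph::components(g)$membership
    comp[grpIdx] <- cmp + nextComp
    nextComp <- nextComp + max(cmp)
  }
  # stable site ids, ordered by (ref pair, leftmost arm1 interval)
  sizes <- as.integer(table(comp)[as.character(comp)])
  siteRows <- lapply(split(seq_len(n), comp), function(members) {
    data.frame(
      ref1_id = hybrids$arm1_ref[members[1L]],
      ref1_start = min(hybrids$arm1_ref_start[members]),
      ref1_end = max(hybrids$arm1_ref_end[members]),
      ref2_id = hybrids$arm2_ref[members[1L]],
      ref2_start = min(hybrids$arm2_ref_start[members]),
      ref2_end = max(hybrids$arm2_ref_end[members]),
      support = length(members),
      member_ids = paste(sort(hybrids$read_id[members]), collapse = ","),
      stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, siteRows)
  ord <- order(sites$ref1_id, sites$ref2_id, sites$ref1_start, sites$ref2_start,
               sites$member_ids)
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  sites <- sites[, c("site_id", "ref1_id", "ref1_start", "ref1_end",
                     "ref2_id", "ref2_start", "ref2_end", "support",
                     "member_ids")]
  rownames(sites) <- NULL
  compNames <- names(split(seq_len(n), comp))[ord]
  hy <- hybrids
  hy$cluster_id <- sites$site_id[match(as.character(comp), compNames)]
  hy$reproducible <- sizes >= config$minSupport
  list(sites = sites, hybrids = hy)
}

#' Write an interaction-site table (1-based inclusive intervals)
#' @param sites site table from [clusterAndSupport()].
#' @param path output TSV path.
#' @export
writeSiteTable <- function(sites, path) {
  out <- sites
  for (col in c("ref1_start", "ref2_start")) out[[col]] <- out[[col]] + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
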