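PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

.modelCache <- new.env(parent = emptyenv())

#' The shipped nearest-neighbour duplex energy model
#'
#' Loads the Turner-2004-style parameter set shipped with the package
#' (Watson-Crick stacks from Xia et al. 1998, published GU stacks,
#' Jacobson-Stockmayer log extrapolation for loop penalties; 37 degrees C).
#' Initiation penalty +4.09 kcal/mol and +0.45 per AU/GU helix end.
#'
#' @param maxLoop maximum unpaired length on either side of an interior
#'   loop (default 15).
#' @return an [EnergyModel].
#' @export
defaultEnergyModel <- function(maxLoop = 15L) {
  key <- paste0("m", maxLoop)
  if (!is.null(.modelCache[[key]])) return(.modelCache[[key]])
  st <- read.delim(system.file("extdata", "nn_stack_dg37.tsv",
                               package = "snoclash"),
                   stringsAsFactors = FALSE)
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  m[cbind(match(st$pair1, PAIR_TYPES), match(st$pair2, PAIR_TYPES))] <- st$dg
  lo <- read.delim(system.file("extdata", "nn_loop_dg37.tsv",
                               package = "snoclash"),
                   stringsAsFactors = FALSE)
  mod <- new("EnergyModel", stack = m, bulge = lo$bulge, internal = lo$internal,
             initiation = 4.09, terminalAU = 0.45, maxLoop = as.integer(maxLoop))
  validObject(mod)
  .modelCache[[key]] <- mod
  mod
}

pairTypeOf <- function(b1, b2) {
  pt <- paste0(b1, b2)
  ifelse(pt %in% PAIR_TYPES, pt, NA_character_)
}

#' Minimum-free-energy intermolecular duplex of two RNA fragments
#'
#' Dynamic program over antiparallel, non-crossing pairings of the two
#' sequences with nearest-neighbour stacking, bulge and internal-loop
#' transitions (loop sides bounded by the model's `maxLoop`), a duplex
#' initiation penalty and a terminal AU/GU penalty at both helix ends.
#' Only the intermolecular duplex is folded: no intramolecular structure,
#' dangles or coaxial stacking. If no admissible structure with
#' free energy <= 0 exists, the no-duplex sentinel (`deltaG = Inf`, empty
#' pairing) is returned.
#'
#' @param seq1,seq2 sequences over A/C/G/U (T accepted and treated as U),
#'   length >= 4.
#' @param model an [EnergyModel] (default [defaultEnergyModel()]).
#' @return a [DuplexStructure].
#' @examples
#' deltaG(duplexMFE("GGGGG", "CCCCC"))
#' duplexMFE("AAAA", "CCCC")  # no admissible pair -> sentinel
#' @export
duplexMFE <- function(seq1, seq2, model = defaultEnergyModel()) {
  stopIfNot(nchar(seq1) >= 4L && nchar(seq2) >= 4L,
            "sequences must be at least 4 nt")
  res <- .duplex_mfe_cpp(rnaify(seq1), rnaify(seq2), model@stack,
                         model@bulge, model@internal, model@initiation,
                         model@terminalAU, model@maxLoop)
  pairs <- res$pairs
  colnames(pairs) <- c("pos1", "pos2")
  new("DuplexStructure", deltaG = res$deltaG, pairs = pairs,
      longestHelix = longestRun(pairs))
}

# longest contiguous helix (consecutive in pos1 and pos2) of a pair matrix
longestRun <- function(pairs) {
  if (!nrow(pairs)) return(0L)
  d1 <- diff(pairs[, 1L]); d2 <- diff(pairs[, 2L])
  stacked <- d1 == 1L & d2 == -1L
  best <- run <- 1L
  for (s in stacked) {
    run <- if (s) run + 1L else 1L
    best <- max(best, run)
  }
  as.integer(best)
}

#' Free energy of an explicit duplex pairing (reference scorer)
#'
#' Scores a given antiparallel non-crossing pairing under the model:
#' initiation + terminal AU/GU penalties + stack/bulge/internal-loop
#' terms between consecutive pairs. Independent of the dynamic program in
#' [duplexMFE()]; used by [enumerateDuplexes()].
#'
#' @param pairs integer matrix (`pos1`, `pos2`), 0-based, pos1 strictly
#'   increasing, pos2 strictly decreasing.
#' @inheritParams duplexMFE
#' @return free energy in kcal/mol (`Inf` if the pairing is inadmissible).
#' @export
duplexEnergy <- function(pairs, seq1, seq2, model = defaultEnergyModel()) {
  if (!nrow(pairs)) return(Inf)
  c1 <- strsplit(rnaify(seq1), "")[[1]]
  c2 <- strsplit(rnaify(seq2), "")[[1]]
  pt <- pairTypeOf(c1[pairs[, 1L] + 1L], c2[pairs[, 2L] + 1L])
  if (anyNA(pt)) return(Inf)
  wob <- pt %in% c("AU", "UA", "GU", "UG")
  e <- model@initiation + model@terminalAU * (wob[1L] + wob[length(wob)])
  if (nrow(pairs) > 1L) {
    for (t in seq_len(nrow(pairs) - 1L)) {
      a <- pairs[t + 1L, 1L] - pairs[t, 1L] - 1L
      b <- pairs[t, 2L] - pairs[t + 1L, 2L] - 1L
      if (a < 0L || b < 0L || a > model@maxLoop || b > model@maxLoop)
        return(Inf)
      if (a == 0L && b == 0L) {
        e <- e + model@stack[pt[t], pt[t + 1L]]
      } else {
        len <- a + b
        if (len > length(model@bulge)) return(Inf)
        pen <- if (a == 0L || b == 0L) model@bulge[len] else model@internal[len]
        if (is.na(pen)) return(Inf)
        e <- e + pen
      }
    }
  }
  e
}

#' Exhaustive duplex enumeration (test oracle)
#'
#' Enumerates every antiparallel non-crossing pairing of the two sequences,
#' scores each with [duplexEnergy()] and returns the minimum. Intended as
#' the independent oracle for [duplexMFE()]; guarded to short inputs.
#'
#' @inheritParams duplexMFE
#' @param maxTotal size guard on `nchar(seq1) + nchar(seq2)` (default 16).
#' @return a [DuplexStructure] (same sentinel convention as [duplexMFE()]).
#' @export
enumerateDuplexes <- function(seq1, seq2, model = defaultEnergyModel(),
                              maxTotal = 16L) {
  n <- nchar(seq1); m <- nchar(seq2)
  stopIfNot(n + m <= maxTotal,
            "enumerateDuplexes is a test oracle; len(seq1)+len(seq2) <= %d",
            maxTotal)
  c1 <- strsplit(rnaify(seq1), "")[[1]]
  c2 <- strsplit(rnaify(seq2), "")[[1]]
  cand <- which(outer(c1, c2, function(a, b)
    !is.na(pairTypeOf(a, b))), arr.ind = TRUE) - 1L
  best <- list(e = Inf, pairs = matrix(integer(), 0, 2))
  if (nrow(cand)) {
    ord <- order(cand[, 1L], -cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    chain <- matrix(integer(), 0, 2)
    recurse <- function(startIdx, chain) {
      if (nrow(chain)) {
        e <- duplexEnergy(chain, seq1, seq2, model)
        if (e < best$e) best <<- list(e = e, pairs = chain)
      }
      for (t in startIdx:nrow(cand)) {
        if (t > nrow(cand)) break
        p <- cand[t, , drop = FALSE]
        if (nrow(chain) &&
            (p[1L] <= chain[nrow(chain), 1L] ||
             p[2L] >= chain[nrow(chain), 2L])) next
        recurse(t + 1L, rbind(chain, p))
      }
    }
    recurse(1L, chain)
  }
  if (!is.finite(best$e) || best$e > 0) {
    new("DuplexStructure", deltaG = Inf,
        pairs = matrix(integer(), 0, 2,
                       dimnames = list(NULL, c("pos1", "pos2"))),
        longestHelix = 0L)
  } else {
    pr <- best$pairs
    dimnames(pr) <- list(NULL, c("pos1", "pos2"))
    new("DuplexStructure", deltaG = best$e, pairs = pr,
        longestHelix = longestRun(pr))
  }
}

#' Annotate a hybrid table with duplex folding energies
#'
#' Computes [duplexMFE()] for the two arm sequences of every hybrid and
#' fills the `dG` column. The per-hybrid pair lists are returned as an
#' attribute `"duplexes"` (a list of [DuplexStructure]) for downstream
#' guide classification.
#'
#' @param hybrids hybrid table (see [writeHybridTable()] for the dialect).
#' @param refset the [ReferenceSet] the arms were aligned to.
#' @param model an [EnergyModel].
#' @return the hybrid table with `dG` filled and a `"duplexes"` attribute.
#' @export
annotateDuplexes <- function(hybrids, refset, model = defaultEnergyModel()) {
  seqs <- setNames(as.character(refSequences(refset)), names(refset))
  duplexes <- vector("list", nrow(hybrids))
  dg <- rep(NA_real_, nrow(hybrids))
  for (r in seq_len(nrow(hybrids))) {
    h <- hybrids[r, ]
    s1 <- substr(seqs[[h$arm1_ref]], h$arm1_ref_start + 1L, h$arm1_ref_end)
    s2 <- substr(seqs[[h$arm2_ref]], h$arm2_ref_start + 1L, h$arm2_ref_end)
    dx <- duplexMFE(s1, s2, model)
    duplexes[[r]] <- dx
    dg[r] <- deltaG(dx)
  }
  hybrids$dG <- dg
  attr(hybrids, "duplexes") <- duplexes
  hybrids
}
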