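#' @import methods
#' @importFrom Biostrings DNAStringSet
NULL

FEATURE_KINDS <- c("five_prime_UTR", "exon", "CDS", "intron", "three_prime_UTR")
REF_CATEGORIES <- c("snoRNA", "rRNA", "mRNA", "other")

#' ReferenceSet: sequences, gene models, snoRNA boxes and methylation sites
#'
#' Container for the custom CLASH reference: one record per unspliced gene
#' (snoRNA records carry their +/- extension flanks; host genes have nested
#' snoRNA footprints replaced by N), together with transcript-local feature
#' intervals, box C/D annotations and known 2'-O-methylation sites.
#'
#' All internal coordinates are 0-based half-open; file writers emit 1-based
#' inclusive coordinates.
#'
#' @slot sequences [Biostrings::DNAStringSet] one entry per reference record.
#' @slot category character vector parallel to `sequences`, each one of
#'   `"snoRNA"`, `"rRNA"`, `"mRNA"`, `"other"`.
#' @slot features data.frame with columns `ref_id`, `kind`
#'   (five_prime_UTR/exon/CDS/intron/three_prime_UTR), `start`, `end`
#'   (0-based half-open, transcript-local).
#' @slot boxes data.frame of box annotations (see [locateBoxes()]), columns
#'   `snorna_id`, `boxC_start`, `boxC_end`, `boxD_start`, `boxD_end`,
#'   `boxDprime_start`, `boxDprime_end`, `boxCprime_start`, `boxCprime_end`
#'   (NA where absent), `unannotatable` (logical).
#' @slot methylationSites data.frame with columns `target_id`, `position`
#'   (1-based), `nucleotide`, `guide_snorna`, `guide_box` ("D" or "Dprime").
#'
#' @seealso [buildReference()], [simulateReference()]
#' @export
setClass("ReferenceSet",
  representation(
    sequences = "DNAStringSet",
    category = "character",
    features = "data.frame",
    boxes = "data.frame",
    methylationSites = "data.frame"
  )
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequences must have unique names")
  if (length(object@category) != length(object@sequences))
    msg <- c(msg, "category must be parallel to sequences")
  if (!all(object@category %in% REF_CATEGORIES))
    msg <- c(msg, sprintf("category values must be in {%s}",
                          paste(REF_CATEGORIES, collapse = ", ")))
  ft <- object@features
  if (nrow(ft)) {
    if (!all(c("ref_id", "kind", "start", "end") %in% names(ft)))
      msg <- c(msg, "features needs columns ref_id, kind, start, end")
    else {
      if (!all(ft$ref_id %in% ids))
        msg <- c(msg, "features reference unknown records")
      if (!all(ft$kind %in% FEATURE_KINDS))
        msg <- c(msg, "unknown feature kind")
      lens <- width(object@sequences)[match(ft$ref_id, ids)]
      if (any(ft$start < 0 | ft$end > lens | ft$start >= ft$end))
        msg <- c(msg, "feature intervals must lie within [0, len)")
      # same-transcript features must not overlap
      for (id in unique(ft$ref_id)) {
        f <- ft[ft$ref_id == id, , drop = FALSE]
        f <- f[order(f$start), , drop = FALSE]
        if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)])) {
          msg <- c(msg, sprintf("overlapping features in record '%s'", id))
          break
        }
      }
    }
  }
  ms <- object@methylationSites
  if (nrow(ms)) {
    if (!all(ms$target_id %in% ids))
      msg <- c(msg, "methylation sites reference unknown records")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceSet number of reference records
#' @param x,object a `ReferenceSet`
#' @export
setMethod("length", "ReferenceSet", function(x) length(x@sequences))

#' @describeIn ReferenceSet record identifiers
#' @export
setMethod("names", "ReferenceSet", function(x) names(x@sequences))

setMethod("show", "ReferenceSet", function(object) {
  tab <- table(factor(object@category, levels = REF_CATEGORIES))
  cat(sprintf("ReferenceSet with %d records (%s)\n", length(object),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d feature intervals, %d box annotations, %d methylation sites\n",
              nrow(object@features), nrow(object@boxes),
              nrow(object@methylationSites)))
})

#' @rdname ReferenceSet
#' @export
refSequences <- function(x) x@sequences

#' @rdname ReferenceSet
#' @export
refCategory <- function(x) stats::setNames(x@category, names(x@sequences))

#' @rdname ReferenceSet
#' @export
refFeatures <- function(x) x@features

#' @rdname ReferenceSet
#' @export
boxAnnotations <- function(x) x@boxes

#' @rdname ReferenceSet
#' @export
methylationSites <- function(x) x@methylationSites

#' EnergyModel: nearest-neighbour duplex folding parameters at 37 degrees C
#'
#' Stacking free energies for the six canonical pair types (AU, UA, CG, GC,
#' GU, UG), loop/bulge penalties by length, duplex initiation penalty and a
#' terminal AU/GU helix-end penalty. Shipped defaults are a Turner-2004-style
#' set (Watson-Crick stacks from Xia et al. with published GU stacks and
#' Jacobson-Stockmayer loop extrapolation); see [defaultEnergyModel()].
#'
#' @slot stack 6x6 numeric matrix, rows = 5' pair, cols = 3' pair, kcal/mol.
#' @slot bulge numeric vector of bulge-loop penalties by total loop length.
#' @slot internal numeric vector of internal-loop penalties by total length
#'   (entry 1 is NA: an internal loop has at least one unpaired base per side).
#' @slot initiation duplex initiation penalty, kcal/mol.
#' @slot terminalAU penalty per AU/GU helix end, kcal/mol.
#' @slot maxLoop maximum unpaired length on either side of an interior gap.
#' @export
setClass("EnergyModel",
  representation(
    stack = "matrix",
    bulge = "numeric",
    internal = "numeric",
    initiation = "numeric",
    terminalAU = "numeric",
    maxLoop = "integer"
  )
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  pr <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (!identical(dim(object@stack), c(6L, 6L)) ||
      !identical(rownames(object@stack), pr) ||
      !identical(colnames(object@stack), pr))
    msg <- c(msg, "stack must be a 6x6 matrix with AU/UA/CG/GC/GU/UG dimnames")
  wc <- c("CG", "GC")
  if (!length(msg) && any(object@stack[wc, wc] >= 0))
    msg <- c(msg, "Watson-Crick stack energies must be negative")
  if (any(object@bulge < 0, na.rm = TRUE) ||
      any(object@internal < 0, na.rm = TRUE))
    msg <- c(msg, "loop penalties must be >= 0")
  if (object@maxLoop < 1L) msg <- c(msg, "maxLoop must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf(paste0("EnergyModel (37 C): %d stacks, loops to length %d ",
                     "(max side %d), initiation %+.2f, terminal AU/GU %+.2f\n"),
              sum(!is.na(object@stack)), length(object@bulge), object@maxLoop,
              object@initiation, object@terminalAU))
})

#' DuplexStructure: an intermolecular RNA duplex and its folding energy
#'
#' Result of [duplexMFE()]. `pairs` holds the base pairs as 0-based indices,
#' strictly increasing on the first sequence and strictly decreasing on the
#' second (antiparallel, non-crossing). A structure with no admissible pair
#' is represented by `deltaG = Inf` and an empty pair matrix (the no-duplex
#' sentinel).
#'
#' @slot deltaG folding free energy, kcal/mol (<= 0 for any reported duplex;
#'   `Inf` = no duplex).
#' @slot pairs integer matrix with columns `pos1`, `pos2` (0-based).
#' @slot longestHelix length of the longest contiguous helix.
#' @export
setClass("DuplexStructure",
  representation(deltaG = "numeric", pairs = "matrix",
                 longestHelix = "integer")
)

setValidity("DuplexStructure", function(object) {
  p <- object@pairs
  if (nrow(p)) {
    if (is.unsorted(p[, 1L], strictly = TRUE) ||
        is.unsorted(rev(p[, 2L]), strictly = TRUE))
      return("pairs must be strictly increasing in pos1, decreasing in pos2")
    if (object@deltaG > 0)
      return("a reported duplex must have deltaG <= 0")
  } else if (is.finite(object@deltaG)) {
    return("empty pairing must carry the Inf sentinel")
  }
  TRUE
})

setMethod("show", "DuplexStructure", function(object) {
  if (!is.finite(object@deltaG)) {
    cat("DuplexStructure: no duplex\n")
  } else {
    cat(sprintf("DuplexStructure: dG = %.2f kcal/mol, %d pairs, longest helix %d\n",
                object@deltaG, nrow(object@pairs), object@longestHelix))
  }
})

#' @rdname DuplexStructure
#' @param x a `DuplexStructure`
#' @export
deltaG <- function(x) x@deltaG

#' @rdname DuplexStructure
#' @export
duplexPairs <- function(x) x@pairs

#' @rdname DuplexStructure
#' @export
longestHelix <- function(x) x@longestHelix
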