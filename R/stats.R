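#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (the convention of `stats::fisher.test`, which
#' performs the computation). A table with a zero margin carries no
#' information and returns p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative counts (rows: DE yes/no, columns:
#'   CLASH target yes/no).
#' @return two-sided p-value.
#' @export
fisherExact <- function(tab) {
  tab <- validate2x2(tab)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-square test for a 2x2 table
#'
#' Chi-square with Yates continuity correction by default (the 2x2 default
#' of `stats::chisq.test`), df = 1. A zero expected cell yields NA with a
#' warning.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates apply the continuity correction (default TRUE).
#' @return list: `statistic`, `p_value`.
#' @export
chiSquare <- function(tab, yates = TRUE) {
  tab <- validate2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    warning("zero expected cell; chi-square undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

validate2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopIfNot(identical(dim(tab), c(2L, 2L)), "need a 2x2 table")
  stopIfNot(all(tab >= 0) && sum(tab) >= 1, "counts must be non-negative, N >= 1")
  tab
}

#' Over-representation of CLASH targets among differentially expressed genes
#'
#' Builds the 2x2 table (DE yes/no x CLASH target yes/no) over the gene
#' universe of the DE table, where DE means adjusted p below `alpha`, and
#' reports both the Fisher exact and chi-square tests, plus the per-gene
#' annotation used for volcano-style plots (target flags on the DE table).
#'
#' @param deTable data.frame `gene_id`, `log2_fold_change`, `p_adjusted`.
#' @param targetGenes character vector of CLASH target gene ids (subset of
#'   the universe).
#' @param alpha DE significance threshold on adjusted p (default 0.05).
#' @return list: `table` (2x2 matrix), `fisher_p`, `chisq_p`,
#'   `chisq_statistic`, `genes` (DE table + `is_target`, `is_de`).
#' @export
targetEnrichment <- function(deTable, targetGenes, alpha = 0.05) {
  need <- c("gene_id", "log2_fold_change", "p_adjusted")
  stopIfNot(all(need %in% names(deTable)), "DE table missing column(s): %s",
            paste(setdiff(need, names(deTable)), collapse = ", "))
  stopIfNot(all(deTable$p_adjusted >= 0 & deTable$p_adjusted <= 1),
            "p_adjusted must be in [0,1]")
  extra <- setdiff(targetGenes, deTable$gene_id)
  stopIfNot(!length(extra), "target genes absent from the DE universe: %s",
            paste(utils::head(extra, 3), collapse = ", "))
  if (!length(targetGenes)) warning("empty target set; p = 1")
  isTarget <- deTable$gene_id %in% targetGenes
  isDe <- deTable$p_adjusted < alpha
  tab <- matrix(c(sum(isDe & isTarget), sum(isDe & !isTarget),
                  sum(!isDe & isTarget), sum(!isDe & !isTarget)),
                2L, 2L, byrow = TRUE,
                dimnames = list(DE = c("yes", "no"),
                                target = c("yes", "no")))
  cs <- if (length(targetGenes)) chiSquare(tab) else
    list(statistic = NA_real_, p_value = 1)
  genes <- deTable
  genes$is_target <- isTarget
  genes$is_de <- isDe
  list(table = tab,
       fisher_p = if (length(targetGenes)) fisherExact(tab) else 1,
       chisq_p = cs$p_value, chisq_statistic = cs$statistic,
       genes = genes)
}

#' Read a differential-expression table (TSV)
#'
#' Expected columns `gene_id`, `log2_fold_change` (accepts `log2FC`),
#' `p_adjusted` (accepts `padj`).
#' @param path TSV path.
#' @export
readDETable <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  names(de)[names(de) == "log2FC"] <- "log2_fold_change"
  names(de)[names(de) == "padj"] <- "p_adjusted"
  need <- c("gene_id", "log2_fold_change", "p_adjusted")
  stopIfNot(all(need %in% names(de)), "DE table missing column(s): %s",
            paste(setdiff(need, names(de)), collapse = ", "))
  de
}
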