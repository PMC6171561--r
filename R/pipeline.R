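#' Write / read the hybrid table (TSV dialect)
#'
#' The hybrid table has columns `read_id`, `sample`, `count`, `arm1_ref`,
#' `arm1_read_start`, `arm1_read_end`, `arm1_ref_start`, `arm1_ref_end`,
#' the same four for arm2, and `dG`. Coordinates are 1-based inclusive in
#' the file (0-based half-open in memory); unknown extra columns are
#' preserved. Gzip-compressed files are accepted transparently.
#'
#' @param hybrids hybrid table (internal coordinates).
#' @param path TSV path (`.gz` for compressed output).
#' @export
writeHybridTable <- function(hybrids, path) {
  out <- hybrids
  for (col in grep("_(read|ref)_start$", names(out), value = TRUE))
    out[[col]] <- out[[col]] + 1L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHybridTable
#' @export
readHybridTable <- function(path) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop(sprintf("malformed hybrid table '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  missing <- setdiff(HYBRID_COLS, names(tab))
  stopIfNot(!length(missing), "hybrid table missing column(s): %s",
            paste(missing, collapse = ", "))
  startCols <- grep("_(read|ref)_start$", names(tab), value = TRUE)
  for (col in startCols) {
    bad <- which(tab[[col]] < 1L)
    if (length(bad))
      stop(sprintf(paste0("hybrid table '%s' line %d: %s = %d; file ",
                          "coordinates are 1-based inclusive (0 suggests a ",
                          "0-based file)"),
                   path, bad[1L] + 1L, col, tab[[col]][bad[1L]]),
           call. = FALSE)
    tab[[col]] <- tab[[col]] - 1L
  }
  nonNum <- !vapply(tab[startCols], is.numeric, logical(1))
  stopIfNot(!any(nonNum), "hybrid table '%s': non-numeric coordinates", path)
  tab
}

#' Pipeline configuration
#'
#' Bundles paths and stage parameters for [runAll()]. Round-trips through
#' YAML ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param fastq path to the input FASTQ (plain or gzip).
#' @param referenceBundle path to a reference bundle directory
#'   (see [writeReferenceBundle()]).
#' @param outputDir run output directory.
#' @param sampleSheet data.frame `sample_id`, `barcode`.
#' @param methylationTable optional methylation-site TSV (else the bundle's).
#' @param deTable optional DE-results TSV for enrichment.
#' @param filter a [filterConfig()].
#' @param rule a [guideRule()].
#' @param chimera a [chimeraParams()].
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(fastq, referenceBundle, outputDir,
                           sampleSheet = defaultBarcodes(),
                           methylationTable = NULL, deTable = NULL,
                           filter = filterConfig(), rule = guideRule(),
                           chimera = chimeraParams()) {
  structure(list(fastq = fastq, referenceBundle = referenceBundle,
                 outputDir = outputDir, sampleSheet = sampleSheet,
                 methylationTable = methylationTable, deTable = deTable,
                 filter = filter, rule = rule, chimera = chimera),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path YAML path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pipelineConfig(
    fastq = y$fastq, referenceBundle = y$referenceBundle,
    outputDir = y$outputDir,
    sampleSheet = as.data.frame(y$sampleSheet, stringsAsFactors = FALSE),
    methylationTable = y$methylationTable, deTable = y$deTable,
    filter = do.call(filterConfig, y$filter),
    rule = do.call(guideRule, y$rule),
    chimera = do.call(chimeraParams, y$chimera))
}

#' Run the CLASH analysis pipeline end-to-end
#'
#' Stages: preprocess (demultiplex, trim, collapse) -> chimera calling ->
#' duplex folding -> energy + reproducibility filtering with site
#' clustering -> guide classification -> positional / feature annotation
#' -> optional target-enrichment test. All tables are written under
#' `outputDir` together with a run manifest (input checksums, parameters)
#' and a summary JSON. Reruns with the same inputs are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with the main in-memory results: `processed`,
#'   `hybrids` (dG-annotated), `filtered`, `sites`, `guideCalls`,
#'   `summary`.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$outputDir, name)
  logmsg <- function(fmt, ...)
    message(sprintf(paste0("[snoclash] ", fmt), ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  refset <- stage("reference", readReferenceBundle(config$referenceBundle))
  if (!is.null(config$methylationTable))
    refset <- stage("reference",
                    addMethylationSites(refset, config$methylationTable))

  pp <- stage("preprocess",
              preprocessReads(config$fastq, config$sampleSheet))
  logmsg("preprocess: %d reads -> %d unique molecules",
         pp$stats[["input"]], pp$stats[["unique_molecules"]])

  ch <- stage("chimera", callHybrids(pp$processed, refset, config$chimera))
  logmsg("chimera: %d hybrids (%d single, %d unmapped, %d ambiguous)",
         nrow(ch$hybrids), sum(ch$status == "single"),
         sum(ch$status == "unmapped"), sum(ch$status == "ambiguous"))

  hybrids <- stage("duplex", annotateDuplexes(ch$hybrids, refset))
  kept <- stage("filter", filterEnergy(hybrids, config$filter))
  cl <- stage("filter", clusterAndSupport(kept, config$filter))
  reproducible <- cl$hybrids[cl$hybrids$reproducible, , drop = FALSE]
  logmsg("filter: %d stable, %d reproducible, %d interaction sites",
         nrow(kept), nrow(reproducible), nrow(cl$sites))

  calls <- stage("classify", classifyGuides(hybrids, refset, config$rule))
  fa <- stage("annotate", assignMrnaFeatures(hybrids, refset))

  enrich <- NULL
  if (!is.null(config$deTable)) {
    de <- stage("enrich", readDETable(config$deTable))
    targets <- intersect(unique(hybrids$arm2_ref), de$gene_id)
    enrich <- stage("enrich", targetEnrichment(de, targets))
  }

  # --- outputs -----------------------------------------------------------
  writeHybridTable(hybrids, outfile("hybrids.tsv"))
  writeHybridTable(cl$hybrids, outfile("hybrids_filtered.tsv"))
  writeSiteTable(cl$sites, outfile("interaction_sites.tsv"))
  write.table(calls, outfile("guide_calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fa, outfile("mrna_features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  cats <- refCategory(refset)
  repCat <- table(factor(unname(cats[reproducible$arm2_ref]),
                         levels = REF_CATEGORIES))
  catPct <- if (nrow(reproducible))
    100 * as.numeric(repCat) / nrow(reproducible) else rep(0, 4L)
  gf <- guideFraction(calls, hybrids, methylationSites(refset))
  summary <- list(
    reads_input = unname(pp$stats[["input"]]),
    unique_molecules = unname(pp$stats[["unique_molecules"]]),
    hybrids_called = nrow(hybrids),
    hybrids_stable = nrow(kept),
    hybrids_reproducible = nrow(reproducible),
    interaction_sites = nrow(cl$sites),
    target_category_percent = setNames(as.list(catPct), REF_CATEGORIES),
    guide_fraction = if (is.na(gf)) NULL else gf,
    guide_calls = as.list(table(calls$classification)),
    mrna_feature_counts = as.list(tabulateFeatures(fa)),
    enrichment = if (!is.null(enrich))
      list(fisher_p = enrich$fisher_p, chisq_p = enrich$chisq_p) else NULL)
  jsonlite::write_json(summary, outfile("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  inputs <- c(config$fastq,
              list.files(config$referenceBundle, full.names = TRUE),
              config$methylationTable, config$deTable)
  manifest <- list(
    package_version = as.character(utils::packageVersion("snoclash")),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))),
    parameters = list(filter = unclass(config$filter),
                      rule = unclass(config$rule),
                      chimera = unclass(config$chimera)))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(processed = pp$processed, status = ch$status,
                 hybrids = hybrids, filtered = cl$hybrids, sites = cl$sites,
                 guideCalls = calls, features = fa, enrichment = enrich,
                 summary = summary))
}
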