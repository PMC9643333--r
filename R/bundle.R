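#' Write a StudyBundle to a directory of plain-text files
#'
#' Writes every on-disk format the pipeline reads: the known library and the
#' per-line predicted motifs as JASPAR text, per-line peaks as BED, modules,
#' PPI edges, gene annotation and gene-GO map as TSV, and the anchor motif
#' ids, planted truth and generating config as JSON.
#'
#' @param bundle a [StudyBundle-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readStudyBundle()]
#' @export
writeStudyBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeJaspar(knownLibrary(bundle), file.path(dir, "known_library.jaspar"))
  for (line in cellLines(bundle)) {
    writeJaspar(perLineMotifs(bundle)[[line]],
                file.path(dir, sprintf("motifs_%s.jaspar", line)))
    pk <- studyPeaks(bundle)
    writePeaksBed(pk[pk$cell_line == line],
                  file.path(dir, sprintf("peaks_%s.bed", line)))
  }
  writeMotifModules(studyModules(bundle), file.path(dir, "modules.tsv"))
  writePpiEdges(studyPpi(bundle), file.path(dir, "ppi.tsv"))
  writeGeneAnnotation(geneAnnotation(bundle), file.path(dir, "annotation.tsv"))
  writeGeneGo(geneGoMap(bundle), file.path(dir, "gene2go.tsv"))
  jsonlite::write_json(anchorMotifIds(bundle), file.path(dir, "anchors.json"),
                       auto_unbox = FALSE)
  jsonlite::write_json(studyTruth(bundle), file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(bundle@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a StudyBundle from a directory written by [writeStudyBundle()]
#'
#' @param dir the bundle directory.
#' @return a [StudyBundle-class].
#' @export
readStudyBundle <- function(dir) {
  lib <- readJaspar(file.path(dir, "known_library.jaspar"), source = "known")
  names(lib) <- vapply(lib, function(m) tfNames(m)[1], "")
  motifFiles <- sort(list.files(dir, pattern = "^motifs_.*\\.jaspar$"))
  lines <- sub("^motifs_(.*)\\.jaspar$", "\\1", motifFiles)
  perLine <- list(); pk <- list()
  for (line in lines) {
    ms <- readJaspar(file.path(dir, sprintf("motifs_%s.jaspar", line)),
                     source = "predicted")
    names(ms) <- vapply(ms, motifID, "")
    perLine[[line]] <- ms
    pk[[line]] <- readPeaksBed(file.path(dir, sprintf("peaks_%s.bed", line)),
                               cellLine = line)
  }
  anchors <- jsonlite::read_json(file.path(dir, "anchors.json"),
                                 simplifyVector = TRUE)
  anchors <- lapply(anchors, as.character)
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else list()
  if (!is.null(truth$interactingPairs))
    truth$interactingPairs <- as.data.frame(truth$interactingPairs,
                                            stringsAsFactors = FALSE)
  cfgPath <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfgPath))
    jsonlite::read_json(cfgPath, simplifyVector = TRUE) else list()
  new("StudyBundle", knownLibrary = lib, perLineMotifs = perLine,
      modules = readMotifModules(file.path(dir, "modules.tsv")),
      anchorMotifIds = anchors,
      peaks = suppressWarnings(do.call(c, unname(pk))),
      ppi = readPpiEdges(file.path(dir, "ppi.tsv")),
      annotation = readGeneAnnotation(file.path(dir, "annotation.tsv")),
      gene2go = readGeneGo(file.path(dir, "gene2go.tsv")),
      truth = if (is.list(truth)) truth else list(),
      config = if (is.list(cfg)) cfg else list())
}
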