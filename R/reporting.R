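#' Column means of a study summary table
#'
#' Given one summary row per cell line, computes the arithmetic mean of every
#' percentage column across cell lines, rounded half-up to one decimal --
#' the way study tables print their column averages. Full precision is kept
#' in the returned rows; rounding is presentation-only.
#'
#' @param rows data.frame with one row per cell line and columns
#'   \code{cell_line}, \code{n_peaks}, \code{n_motifs},
#'   \code{pct_known_strict}, \code{pct_known_relaxed}, \code{pct_conserved},
#'   \code{pct_peak_overlap} (percentage columns in [0, 100]; extra columns
#'   are ignored).
#' @return list with \code{rows} (unchanged) and \code{columnMeans} (named
#'   numeric, one decimal).
#' @examples
#' rows <- data.frame(cell_line = c("A", "B"), n_peaks = c(10, 20),
#'                    n_motifs = c(5, 5), pct_known_strict = c(60, 70),
#'                    pct_known_relaxed = c(80, 90), pct_conserved = c(90, 95),
#'                    pct_peak_overlap = c(50, 60))
#' studySummary(rows)$columnMeans
#' @export
studySummary <- function(rows) {
  pctCols <- c("pct_known_strict", "pct_known_relaxed", "pct_conserved",
               "pct_peak_overlap")
  miss <- setdiff(c("cell_line", pctCols), names(rows))
  if (length(miss))
    stop("summary rows missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in pctCols)
    if (any(rows[[cc]] < 0 | rows[[cc]] > 100))
      stop(sprintf("column %s has values outside [0, 100]", cc), call. = FALSE)
  means <- vapply(pctCols, function(cc) roundHalfUp(mean(rows[[cc]]), 1L), 0)
  list(rows = rows, columnMeans = means)
}

#' Per-cell-line summary of a study bundle
#'
#' Builds the per-line summary table: peak and motif counts, the percentage
#' of predicted motifs similar to a known motif at the strict and relaxed
#' E-value thresholds, the percentage of motifs conserved in other cell
#' lines, and the percentage of peaks overlapping another line's peaks.
#'
#' @param bundle a [StudyBundle-class].
#' @param calib [NullCalibration-class] for the known library.
#' @param thetaKnown strict known-motif threshold (default 1e-5).
#' @param thetaRelaxed relaxed known-motif threshold (default 1e-4).
#' @param thetaCross cross-line similarity threshold (default 1e-8).
#' @param method E-value method (default \code{"tail"}).
#' @param simRel optional precomputed [crossLineSimilarity()].
#' @return list with \code{rows} and \code{columnMeans}, as [studySummary()].
#' @export
summarizeStudy <- function(bundle, calib, thetaKnown = 1e-5,
                           thetaRelaxed = 1e-4, thetaCross = 1e-8,
                           method = "tail", simRel = NULL) {
  lines <- cellLines(bundle)
  lib <- knownLibrary(bundle)
  cons <- motifConservation(perLineMotifs(bundle), calib,
                            thetaCross = thetaCross, method = method,
                            simRel = simRel)
  pk <- studyPeaks(bundle)
  libStats <- lapply(lib, .pwmStats)
  rows <- lapply(lines, function(line) {
    motifs <- perLineMotifs(bundle)[[line]]
    bestE <- vapply(motifs, function(m) {
      hit <- matchKnown(m, lib, calib, maxK = 1L, filter = FALSE,
                        method = method, libStats = libStats)
      hit$evalue[1L]
    }, 0)
    own <- pk[pk$cell_line == line]
    others <- pk[pk$cell_line != line]
    data.frame(cell_line = line,
               n_peaks = length(own),
               n_motifs = length(motifs),
               pct_known_strict = 100 * mean(bestE < thetaKnown),
               pct_known_relaxed = 100 * mean(bestE < thetaRelaxed),
               pct_conserved = 100 * cons[[line]],
               pct_peak_overlap = overlapFraction(own, others),
               stringsAsFactors = FALSE)
  })
  studySummary(do.call(rbind, rows))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full cofactor-discovery pipeline
#'
#' Orchestrates simulate (or load) -> calibrate -> match -> conserve ->
#' infer -> annotate -> diverge -> summarize, and writes all artifacts to
#' \code{outDir}: \code{summary.tsv}, \code{summary.json},
#' \code{ranked_cofactors.tsv}, \code{enrichment.json},
#' \code{conservation.json}, \code{targets.tsv}, \code{divergence.json} and
#' \code{run.log}. Reruns with the same configuration and seed produce
#' byte-identical \code{summary.json}.
#'
#' @param config one of: a [syntheticConfig()]; a list with element
#'   \code{synthetic} (arguments to [syntheticConfig()]) and optionally
#'   \code{thresholds} (overriding the threshold arguments below); a path to
#'   a YAML file with that structure; or a list with element
#'   \code{bundleDir} naming a directory written by [writeStudyBundle()].
#' @param outDir output directory (created if needed).
#' @param mode cofactor assignment mode, \code{"top5"} or \code{"top1"}.
#' @param interaction PPI class tested, \code{"direct"}, \code{"indirect"} or
#'   \code{"either"}.
#' @param thetaKnown,thetaRelaxed,thetaCross E-value thresholds (defaults
#'   1e-5, 1e-4, 1e-8).
#' @param tau ranking score cutoff (default 15).
#' @param alpha GO enrichment q threshold (default 0.05).
#' @param minLen minimum peak length for extension (default 800).
#' @param nullReps replicates for the random-module null (default 199).
#' @param nNull null scores for E-value calibration (default 2000).
#' @param dropOverlapConfounded if TRUE, drop motifs whose source modules
#'   derive exclusively from cross-line-overlapping peaks before measuring
#'   conservation; requires module-to-peak provenance, which the bundle
#'   formats do not carry, so the step is skipped with a warning.
#' @return invisibly, a list with every intermediate result (bundle, calib,
#'   assignments, conservation, null, enrichment, ranked, recovery, targets,
#'   divergence, summary).
#' @export
runPipeline <- function(config, outDir, mode = "top5", interaction = "direct",
                        thetaKnown = 1e-5, thetaRelaxed = 1e-4,
                        thetaCross = 1e-8, tau = 15, alpha = 0.05,
                        minLen = 800L, nullReps = 199L, nNull = 2000L,
                        dropOverlapConfounded = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  bundle <- NULL
  if (inherits(config, "SyntheticConfig")) {
    cfg <- config
  } else if (!is.null(config$bundleDir)) {
    if (!dir.exists(config$bundleDir))
      stop(sprintf("bundle directory not found: %s", config$bundleDir),
           call. = FALSE)
    bundle <- .stage("load", readStudyBundle(config$bundleDir))
    cfg <- NULL
  } else {
    cfg <- do.call(syntheticConfig, config$synthetic %||% list())
    th <- config$thresholds %||% list()
    thetaKnown <- th$thetaKnown %||% thetaKnown
    thetaRelaxed <- th$thetaRelaxed %||% thetaRelaxed
    thetaCross <- th$thetaCross %||% thetaCross
    tau <- th$tau %||% tau
    mode <- th$mode %||% mode
    interaction <- th$interaction %||% interaction
  }
  if (is.null(bundle))
    bundle <- .stage("simulate", simulateStudy(cfg))
  seed <- (bundle@config$seed %||% 1L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  lib <- knownLibrary(bundle)
  calib <- .stage("calibrate",
                  calibrateNull(lib, nNull = nNull, seed = fanSeed(seed, 101L)))
  assignments <- .stage("match",
    assignCofactors(perLineMotifs(bundle), lib, calib, mode = mode,
                    cutoff = thetaKnown))

  if (dropOverlapConfounded)
    warning("module-to-peak provenance not available in bundle formats; ",
            "overlap-confound filter skipped")
  simRel <- .stage("conserve",
    crossLineSimilarity(perLineMotifs(bundle), calib, thetaCross))
  lines <- cellLines(bundle)
  modules <- studyModules(bundle)
  perLinePairs <- lapply(lines, function(line)
    modulePairs(modules$motif_ids[modules$cell_line == line]))
  names(perLinePairs) <- lines
  consMotif <- motifConservation(perLineMotifs(bundle), simRel = simRel)
  consPair <- pairConservation(perLinePairs, simRel)
  pairNull <- .stage("null",
    randomPairNull(modules, perLineMotifs(bundle), R = nullReps,
                   seed = fanSeed(seed, 102L), simRel = simRel))

  split <- splitDirectIndirect(studyPpi(bundle))
  known <- switch(interaction,
                  direct = split$direct,
                  indirect = split$indirect,
                  either = unique(rbind(split$direct, split$indirect)))
  N <- sum(ppiTfFlags(studyPpi(bundle)))
  enrichment <- .stage("infer", lapply(lines, function(line) {
    pp <- cofactorPairs(perLinePairs[[line]],
                        assignments[assignments$cell_line == line, ])
    suppressWarnings(pairEnrichment(pp, known, N, interaction))
  }))
  names(enrichment) <- lines
  studyEnrichmentP <- fisherCombine(vapply(enrichment, `[[`, 0, "pValue"))
  ranked <- rankCofactors(assignments, tau = tau)
  cofs <- anchorCofactors(modules, assignments, anchorMotifIds(bundle))
  ## per-line cofactor sets for the divergence analysis: every TF assigned in
  ## the line (all predicted motifs derive from the anchor ChIP peaks); the
  ## anchor-module co-occurrence restriction applies to ranking/recovery only
  perLineCofs <- lapply(lines, function(line)
    sort(unique(assignments$tf_name[assignments$cell_line == line])))
  names(perLineCofs) <- lines
  truth <- studyTruth(bundle)
  recovery <- if (length(truth$cofactors %||% character()))
    recoveryStats(cofs, truth$cofactors) else NULL

  chromSizes <- unlist(truth$chromSizes %||% list())
  if (!length(chromSizes)) {
    pk <- studyPeaks(bundle)
    chromSizes <- tapply(GenomicRanges::end(pk),
                         as.character(GenomicRanges::seqnames(pk)), max)
  }
  extended <- .stage("annotate",
    extendPeaks(studyPeaks(bundle), minLen = minLen, chromSizes = chromSizes))
  targets <- nearestTss(extended, geneAnnotation(bundle))
  targets$cell_line <- extended$cell_line

  universe <- geneAnnotation(bundle)$gene_id
  perLineTerms <- .stage("diverge", lapply(lines, function(line) {
    genes <- unique(targets$gene_id[targets$cell_line == line])
    enr <- goEnrichment(genes, geneGoMap(bundle), universe, alpha = alpha)
    enr$term_id[enr$enriched]
  }))
  names(perLineTerms) <- lines
  divergence <- divergenceRegression(perLineCofs, perLineTerms)

  summary <- .stage("summarize",
    summarizeStudy(bundle, calib, thetaKnown, thetaRelaxed, thetaCross,
                   simRel = simRel))

  ## artifacts
  utils::write.table(summary$rows, file.path(outDir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(rows = summary$rows, columnMeans = as.list(summary$columnMeans),
         recovery = recovery[c("hits", "total", "percent")],
         seed = seed),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(ranked, file.path(outDir, "ranked_cofactors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(enrichment, list(study_p = studyEnrichmentP)),
                       file.path(outDir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(perLineMotifFraction = as.list(consMotif),
         perLinePairFraction = as.list(consPair$perLine),
         overallPairFraction = consPair$overall, theta = thetaCross,
         null = pairNull[c("observed", "pEmpirical", "pNormal", "seed")]),
    file.path(outDir, "conservation.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(targets, file.path(outDir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(points = divergence$points, perLineR2 = as.list(divergence$perLineR2),
         meanR2 = divergence$meanR2),
    file.path(outDir, "divergence.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("cofactorScope %s", as.character(utils::packageVersion("cofactorScope"))),
    sprintf("seed: %d", seed),
    sprintf("thresholds: thetaKnown=%g thetaRelaxed=%g thetaCross=%g tau=%g minLen=%d",
            thetaKnown, thetaRelaxed, thetaCross, tau, as.integer(minLen)),
    sprintf("mode: %s, interaction: %s, nullReps: %d, nNull: %d",
            mode, interaction, as.integer(nullReps), as.integer(nNull)),
    "stages: simulate calibrate match conserve null infer annotate diverge summarize"),
    file.path(outDir, "run.log"))

  invisible(list(bundle = bundle, calib = calib, assignments = assignments,
                 simRel = simRel, motifConservation = consMotif,
                 pairConservation = consPair, pairNull = pairNull,
                 enrichment = enrichment, studyEnrichmentP = studyEnrichmentP,
                 ranked = ranked,
                 anchorCofactors = cofs, perLineCofactors = perLineCofs,
                 recovery = recovery, targets = targets,
                 perLineTerms = perLineTerms, divergence = divergence,
                 summary = summary))
}
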