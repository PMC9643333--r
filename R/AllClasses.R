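#' MotifMatrix: a position weight matrix with provenance
#'
#' A position weight matrix (PWM) describing a transcription factor binding
#' preference as per-position nucleotide probabilities. The matrix is stored
#' with 4 rows in alphabet order A, C, G, T and one column per motif position.
#'
#' @slot motifID single character identifier.
#' @slot tfNames character vector of TF names associated with the motif
#'   (may be empty for de novo predicted motifs).
#' @slot profile numeric matrix, 4 x width, rows named A,C,G,T; every column
#'   sums to 1 (tolerance 1e-6) and all entries lie in [0, 1]. Width >= 4.
#' @slot source either \code{"predicted"} or \code{"known"}.
#'
#' @seealso [MotifMatrix()] for the constructor, [readJaspar()] to parse
#'   JASPAR-format files.
#' @export
setClass("MotifMatrix",
  slots = c(
    motifID = "character",
    tfNames = "character",
    profile = "matrix",
    source  = "character"
  )
)

setValidity("MotifMatrix", function(object) {
  m <- object@profile
  msgs <- character()
  if (length(object@motifID) != 1L || is.na(object@motifID) || !nzchar(object@motifID))
    msgs <- c(msgs, "motifID must be a single non-empty string")
  if (!is.numeric(m) || nrow(m) != 4L)
    msgs <- c(msgs, "profile must be a numeric matrix with 4 rows (A,C,G,T)")
  else {
    if (ncol(m) < 4L)
      msgs <- c(msgs, "motif width must be >= 4")
    if (!identical(rownames(m), DNA_BASES))
      msgs <- c(msgs, "profile rows must be named A,C,G,T in order")
    if (any(m < -1e-12 | m > 1 + 1e-12))
      msgs <- c(msgs, "all profile entries must lie in [0, 1]")
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-6))
      msgs <- c(msgs, sprintf("profile columns must sum to 1 (worst deviation %.3g)",
                              max(abs(cs - 1))))
  }
  if (length(object@source) != 1L || !object@source %in% c("predicted", "known"))
    msgs <- c(msgs, "source must be 'predicted' or 'known'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MotifMatrix
#'
#' @param motifID motif identifier.
#' @param profile 4 x width numeric matrix of probabilities (rows A,C,G,T) or
#'   counts; counts are normalised per column. Rows are named A,C,G,T if
#'   unnamed.
#' @param tfNames character vector of TF names (default empty).
#' @param source \code{"predicted"} or \code{"known"}.
#' @param normalize if \code{TRUE} (default) columns are rescaled to sum to 1,
#'   so count matrices are accepted.
#' @return a [MotifMatrix-class] object.
#' @examples
#' m <- MotifMatrix("m1", matrix(c(4, 0, 0, 0), 4, 5), source = "known")
#' motifWidth(m)
#' @export
MotifMatrix <- function(motifID, profile, tfNames = character(), source = "predicted",
                        normalize = TRUE) {
  profile <- as.matrix(profile)
  storage.mode(profile) <- "double"
  if (is.null(rownames(profile))) rownames(profile) <- DNA_BASES
  colnames(profile) <- NULL
  if (normalize) {
    cs <- colSums(profile)
    if (any(cs <= 0))
      stop(sprintf("motif '%s': column(s) %s sum to zero and cannot be normalised",
                   motifID, paste(which(cs <= 0), collapse = ",")), call. = FALSE)
    profile <- sweep(profile, 2L, cs, "/")
  }
  new("MotifMatrix", motifID = as.character(motifID),
      tfNames = as.character(tfNames), profile = profile,
      source = source)
}

#' NullCalibration: empirical null for motif-similarity E-values
#'
#' Holds the sorted null alignment-score sample used to convert an alignment
#' score into an E-value against a motif library, together with a Gaussian fit
#' to the null used for tail extrapolation beyond the empirical resolution.
#'
#' @slot nullScores sorted (ascending) numeric vector of null alignment scores.
#' @slot nNull number of null scores (>= 1000).
#' @slot librarySize size of the motif library the calibration refers to.
#' @slot seed integer seed used to generate the null sample.
#' @slot mu,sigma mean and standard deviation of the Gaussian fitted to the
#'   null scores (used by the \code{"tail"} E-value method).
#' @seealso [calibrateNull()], [motifEvalue()]
#' @export
setClass("NullCalibration",
  slots = c(
    nullScores = "numeric",
    nNull = "integer",
    librarySize = "integer",
    seed = "integer",
    mu = "numeric",
    sigma = "numeric"
  )
)

setValidity("NullCalibration", function(object) {
  msgs <- character()
  if (object@nNull < 1000L)
    msgs <- c(msgs, "nNull must be >= 1000")
  if (length(object@nullScores) != object@nNull)
    msgs <- c(msgs, "length(nullScores) must equal nNull")
  if (is.unsorted(object@nullScores))
    msgs <- c(msgs, "nullScores must be sorted ascending")
  if (object@librarySize < 2L)
    msgs <- c(msgs, "librarySize must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' PPINetwork: a protein-protein interaction edge list with TF flags
#'
#' Undirected, deduplicated protein-protein interaction edges plus a flag per
#' protein marking whether it is a transcription factor. Self-edges are never
#' stored.
#'
#' @slot edges data.frame with character columns \code{a}, \code{b}; each row
#'   an unordered edge stored with \code{a < b}.
#' @slot tfFlags named logical vector covering every edge endpoint.
#' @seealso [PPINetwork()], [readPpiEdges()], [splitDirectIndirect()]
#' @export
setClass("PPINetwork",
  slots = c(edges = "data.frame", tfFlags = "logical")
)

setValidity("PPINetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("a", "b") %in% names(e)))
    return("edges must have columns 'a' and 'b'")
  if (nrow(e)) {
    if (any(e$a == e$b)) msgs <- c(msgs, "self-edges are not allowed")
    if (any(e$a > e$b)) msgs <- c(msgs, "edges must be stored with a < b")
    if (anyDuplicated(pairKey(e$a, e$b))) msgs <- c(msgs, "duplicate edges")
    miss <- setdiff(unique(c(e$a, e$b)), names(object@tfFlags))
    if (length(miss))
      msgs <- c(msgs, sprintf("endpoints missing from tfFlags: %s",
                              paste(head(miss, 3L), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PPINetwork
#'
#' Edges are deduplicated as unordered pairs; self-edges are dropped with a
#' warning reporting how many were removed.
#'
#' @param a,b character vectors of interacting protein ids (parallel).
#' @param tfFlags named logical vector: is each protein a transcription
#'   factor? Must cover every endpoint; proteins absent from \code{a}/\code{b}
#'   may also be present (they enlarge the universe).
#' @return a [PPINetwork-class].
#' @export
PPINetwork <- function(a, b, tfFlags) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-edge(s)", sum(self)))
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(pairKey(lo, hi))
  edges <- data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
  new("PPINetwork", edges = edges, tfFlags = tfFlags)
}

#' StudyBundle: one complete (synthetic) cofactor study
#'
#' Container for everything one study carries: the known-motif library, the
#' per-cell-line predicted motifs and motif modules, anchor motif ids, peaks,
#' the PPI network, gene annotation, gene-to-GO mapping, and -- for synthetic
#' studies -- the planted ground truth used by recovery tests.
#'
#' @slot knownLibrary list of [MotifMatrix-class] (the known-TF library).
#' @slot perLineMotifs named list (by cell line) of lists of MotifMatrix.
#' @slot modules data.frame with columns \code{module_id}, \code{cell_line},
#'   \code{support} and list-column \code{motif_ids}.
#' @slot anchorMotifIds named list (by cell line) of character vectors of
#'   motif ids planted/identified as the anchor TF's motif.
#' @slot peaks a [GenomicRanges::GRanges] with metadata columns
#'   \code{cell_line} and \code{peak_id} (1-based closed coordinates as usual
#'   for GRanges; file I/O converts from/to 0-based half-open BED).
#' @slot ppi a [PPINetwork-class].
#' @slot annotation data.frame: \code{gene_id}, \code{chrom}, \code{tss}
#'   (0-based), \code{strand}.
#' @slot gene2go data.frame: \code{gene_id}, \code{term_id}.
#' @slot truth list of planted ground truth (empty for real studies).
#' @slot config list: the [syntheticConfig()] that generated the bundle, if any.
#' @seealso [simulateStudy()], [writeStudyBundle()], [readStudyBundle()]
#' @export
setClass("StudyBundle",
  slots = c(
    knownLibrary = "list",
    perLineMotifs = "list",
    modules = "data.frame",
    anchorMotifIds = "list",
    peaks = "ANY",
    ppi = "PPINetwork",
    annotation = "data.frame",
    gene2go = "data.frame",
    truth = "list",
    config = "list"
  )
)

setValidity("StudyBundle", function(object) {
  msgs <- character()
  for (line in names(object@perLineMotifs)) {
    ids <- vapply(object@perLineMotifs[[line]], motifID, character(1))
    mods <- object@modules[object@modules$cell_line == line, , drop = FALSE]
    bad <- setdiff(unique(unlist(mods$motif_ids)), ids)
    if (length(bad))
      msgs <- c(msgs, sprintf("cell line %s: module motif id(s) %s not in its motif list",
                              line, paste(head(bad, 3L), collapse = ", ")))
  }
  tr <- object@truth
  if (length(tr) && !is.null(tr$cofactors) && !is.null(tr$motifSource)) {
    carried <- unique(unlist(lapply(tr$motifSource, function(x) unname(x))))
    miss <- setdiff(tr$cofactors, carried)
    if (length(miss))
      msgs <- c(msgs, sprintf("planted cofactor(s) with no motif in any line: %s",
                              paste(miss, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})
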