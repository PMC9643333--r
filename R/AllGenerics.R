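#' @name MotifMatrix-accessors
#' @title Accessors for MotifMatrix objects
#' @param x a [MotifMatrix-class].
#' @return \code{motifID}: the id; \code{tfNames}: TF names;
#'   \code{motifProfile}: the 4 x width probability matrix;
#'   \code{motifWidth}: number of positions; \code{motifSource}: provenance.
NULL

#' @rdname MotifMatrix-accessors
#' @export
setGeneric("motifID", function(x) standardGeneric("motifID"))
#' @rdname MotifMatrix-accessors
#' @export
setGeneric("tfNames", function(x) standardGeneric("tfNames"))
#' @rdname MotifMatrix-accessors
#' @export
setGeneric("motifProfile", function(x) standardGeneric("motifProfile"))
#' @rdname MotifMatrix-accessors
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))
#' @rdname MotifMatrix-accessors
#' @export
setGeneric("motifSource", function(x) standardGeneric("motifSource"))

#' @rdname MotifMatrix-accessors
#' @export
setMethod("motifID", "MotifMatrix", function(x) x@motifID)
#' @rdname MotifMatrix-accessors
#' @export
setMethod("tfNames", "MotifMatrix", function(x) x@tfNames)
#' @rdname MotifMatrix-accessors
#' @export
setMethod("motifProfile", "MotifMatrix", function(x) x@profile)
#' @rdname MotifMatrix-accessors
#' @export
setMethod("motifWidth", "MotifMatrix", function(x) ncol(x@profile))
#' @rdname MotifMatrix-accessors
#' @export
setMethod("motifSource", "MotifMatrix", function(x) x@source)

#' Reverse complement of a position weight matrix
#'
#' Reverses the column order and swaps A with T and C with G within each
#' column, giving the motif as read on the opposite strand. Applying it twice
#' returns the original motif.
#'
#' @param x a [MotifMatrix-class].
#' @return a [MotifMatrix-class] of the same width and id.
#' @examples
#' m <- MotifMatrix("m", matrix(c(1, 0, 0, 0), 4, 4), source = "known")
#' motifProfile(reverseComplement(m))["T", 4]  # the A column reappears as T
#' @export
setGeneric("reverseComplement", function(x) standardGeneric("reverseComplement"))

#' @rdname reverseComplement
#' @export
setMethod("reverseComplement", "MotifMatrix", function(x) {
  m <- x@profile[c("T", "G", "C", "A"), rev(seq_len(ncol(x@profile))), drop = FALSE]
  rownames(m) <- DNA_BASES
  new("MotifMatrix", motifID = x@motifID, tfNames = x@tfNames,
      profile = m, source = x@source)
})

#' @describeIn MotifMatrix-accessors show method
#' @param object a MotifMatrix
#' @export
setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix '%s' (%s), width %d%s\n",
              object@motifID, object@source, ncol(object@profile),
              if (length(object@tfNames))
                paste0(", TFs: ", paste(object@tfNames, collapse = ",")) else ""))
  print(round(object@profile, 3))
  invisible(object)
})

#' @export
#' @describeIn NullCalibration-class show method
#' @param object a NullCalibration
setMethod("show", "NullCalibration", function(object) {
  cat(sprintf(
    "NullCalibration: %d null scores (library size %d, seed %d)\n  score mean %.3f, sd %.3f; smallest empirical E = %.3g\n",
    object@nNull, object@librarySize, object@seed, object@mu, object@sigma,
    object@librarySize / (object@nNull + 1)))
  invisible(object)
})

#' @export
#' @describeIn PPINetwork-class show method
#' @param object a PPINetwork
setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("PPINetwork: %d proteins (%d TFs), %d edges\n",
              length(object@tfFlags), sum(object@tfFlags), nrow(object@edges)))
  invisible(object)
})

#' Accessors for PPINetwork
#' @param x a [PPINetwork-class].
#' @return \code{ppiEdges}: data.frame of unordered edges (columns a, b);
#'   \code{ppiTfFlags}: named logical vector of TF flags.
#' @export
ppiEdges <- function(x) x@edges

#' @rdname ppiEdges
#' @export
ppiTfFlags <- function(x) x@tfFlags

#' @export
#' @describeIn StudyBundle-class show method
#' @param object a StudyBundle
setMethod("show", "StudyBundle", function(object) {
  lines <- names(object@perLineMotifs)
  cat(sprintf(
    "StudyBundle: %d cell lines, %d known motifs, %d modules, %d peaks, %d genes\n",
    length(lines), length(object@knownLibrary), nrow(object@modules),
    length(object@peaks), nrow(object@annotation)))
  if (length(object@truth))
    cat(sprintf("  planted truth: anchor %s, %d cofactors, %d interacting pairs\n",
                object@truth$anchorTF, length(object@truth$cofactors),
                nrow(object@truth$interactingPairs %||% data.frame())))
  invisible(object)
})

#' Accessors for StudyBundle
#' @param x a [StudyBundle-class].
#' @name StudyBundle-accessors
#' @return the corresponding slot: known library (list of MotifMatrix),
#'   per-line motif lists, module table, anchor motif ids, peaks (GRanges),
#'   PPI network, gene annotation, gene-to-GO map, planted truth, cell-line
#'   names.
NULL

#' @rdname StudyBundle-accessors
#' @export
knownLibrary <- function(x) x@knownLibrary
#' @rdname StudyBundle-accessors
#' @export
perLineMotifs <- function(x) x@perLineMotifs
#' @rdname StudyBundle-accessors
#' @export
studyModules <- function(x) x@modules
#' @rdname StudyBundle-accessors
#' @export
anchorMotifIds <- function(x) x@anchorMotifIds
#' @rdname StudyBundle-accessors
#' @export
studyPeaks <- function(x) x@peaks
#' @rdname StudyBundle-accessors
#' @export
studyPpi <- function(x) x@ppi
#' @rdname StudyBundle-accessors
#' @export
geneAnnotation <- function(x) x@annotation
#' @rdname StudyBundle-accessors
#' @export
geneGoMap <- function(x) x@gene2go
#' @rdname StudyBundle-accessors
#' @export
studyTruth <- function(x) x@truth
#' @rdname StudyBundle-accessors
#' @export
cellLines <- function(x) names(x@perLineMotifs)
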