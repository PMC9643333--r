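#' Extend peaks to a minimum length
#'
#' Peaks shorter than \code{minLen} grow symmetrically about their midpoint
#' to exactly \code{minLen} (the extra base goes to the right when the
#' deficit is odd); longer peaks are unchanged. Extension is clamped to the
#' chromosome, preserving the target length by shifting inward when the
#' chromosome permits. The default of 800 bp is roughly the median length of
#' a cis-regulatory region.
#'
#' @param peaks a \code{GRanges}.
#' @param minLen minimum peak length in bp (default 800).
#' @param chromSizes named numeric vector of chromosome lengths; every peak
#'   chromosome must be present.
#' @return a \code{GRanges} of the same length and order, metadata preserved.
#' @export
extendPeaks <- function(peaks, minLen = 800L, chromSizes) {
  chr <- as.character(GenomicRanges::seqnames(peaks))
  miss <- setdiff(unique(chr), names(chromSizes))
  if (length(miss))
    stop("chromosome(s) absent from chromSizes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ## 0-based half-open arithmetic
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  len <- e0 - s0
  def <- pmax(0L, as.integer(minLen) - len)
  ns <- s0 - def %/% 2L
  ne <- e0 + (def + 1L) %/% 2L
  lim <- as.numeric(chromSizes[chr])
  shiftR <- pmax(0, -ns)
  ns <- ns + shiftR; ne <- ne + shiftR
  shiftL <- pmax(0, ne - lim)
  ns <- pmax(0, ns - shiftL); ne <- pmin(lim, ne)
  out <- peaks
  IRanges::ranges(out) <- IRanges::IRanges(start = as.integer(ns) + 1L,
                                           end = as.integer(ne))
  out
}

#' Fraction of peaks overlapping another peak set
#'
#' Percentage of peaks in \code{peaks} that overlap (by at least 1 bp) at
#' least one peak in \code{other}. Output does not depend on input order.
#'
#' @param peaks,other \code{GRanges} in the same coordinate system.
#' @return a percentage in [0, 100] (exact 100.0 for identical non-empty
#'   sets).
#' @export
overlapFraction <- function(peaks, other) {
  if (!length(peaks)) return(0)
  hits <- GenomicRanges::countOverlaps(peaks, other, ignore.strand = TRUE)
  100 * mean(hits > 0L)
}

#' Assign peaks to their nearest-TSS target gene
#'
#' Each peak is assigned to the gene whose TSS is nearest to the peak
#' midpoint (\code{floor((start + end)/2)} in 0-based coordinates), on the
#' same chromosome. Equidistant genes are resolved toward the
#' lexicographically smaller gene id, so the assignment is deterministic.
#' The signed distance is midpoint minus TSS, with the sign flipped for genes
#' on the minus strand, so negative always means upstream of the gene.
#'
#' @param peaks a \code{GRanges} (metadata column \code{peak_id} used if
#'   present).
#' @param annotation gene annotation data.frame ([readGeneAnnotation()]
#'   layout). Every peak chromosome must carry at least one gene.
#' @return data.frame with columns \code{peak_id}, \code{gene_id},
#'   \code{signed_distance}; one row per peak.
#' @export
nearestTss <- function(peaks, annotation) {
  if (!nrow(annotation)) stop("annotation is empty", call. = FALSE)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  miss <- setdiff(unique(chr), unique(annotation$chrom))
  if (length(miss))
    stop("no annotated gene on chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mid <- (GenomicRanges::start(peaks) - 1L + GenomicRanges::end(peaks)) %/% 2L
  ids <- if ("peak_id" %in% names(S4Vectors::mcols(peaks)))
    peaks$peak_id else sprintf("peak%d", seq_along(peaks))
  geneId <- character(length(peaks)); dist <- integer(length(peaks))
  for (cc in unique(chr)) {
    genes <- annotation[annotation$chrom == cc, , drop = FALSE]
    for (i in which(chr == cc)) {
      d <- abs(mid[i] - genes$tss)
      g <- order(d, genes$gene_id)[1L]
      geneId[i] <- genes$gene_id[g]
      raw <- mid[i] - genes$tss[g]
      dist[i] <- if (genes$strand[g] == "-") -raw else raw
    }
  }
  data.frame(peak_id = ids, gene_id = geneId, signed_distance = dist,
             stringsAsFactors = FALSE)
}
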