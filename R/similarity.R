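## Centered columns and per-column L2 norms; computed once per motif and
## reused across the many alignments of a library scan.
.colStats <- function(profile) {
  ctr <- sweep(profile, 2L, colMeans(profile))
  list(ctr = ctr, norm = sqrt(colSums(ctr^2)))
}

.pwmStats <- function(pwm) {
  p <- motifProfile(pwm)
  rc <- motifProfile(reverseComplement(pwm))
  list(fwd = .colStats(p), rev = .colStats(rc), w = ncol(p))
}

## Per-offset scores from one cross-correlation matrix: corMat[i, j] is the
## Pearson correlation of column i of a with column j of b; the score of
## offset o (start of b relative to a) is the sum of the diagonal band
## row - col == o, divided by denom.
.scoreOffsets <- function(sa, sb, wa, wb, minOv, denom) {
  corMat <- crossprod(sa$ctr, sb$ctr)
  den <- tcrossprod(sa$norm, sb$norm)
  pos <- den > 0
  corMat[pos] <- corMat[pos] / den[pos]
  corMat[!pos] <- 0  # uniform columns contribute 0
  band <- rowsum(as.vector(corMat),
                 rep(seq_len(wa), wb) - rep(seq_len(wb), each = wa))
  offsets <- as.integer(rownames(band))
  keep <- pmin(wa, wb + offsets) - pmax(0L, offsets) >= minOv
  list(offsets = offsets[keep], score = band[keep] / denom)
}

.alignStats <- function(sa, sb) {
  wa <- sa$w; wb <- sb$w
  minOv <- min(4L, wa, wb)
  denom <- max(wa, wb)
  fwd <- .scoreOffsets(sa$fwd, sb$fwd, wa, wb, minOv, denom)
  rev <- .scoreOffsets(sa$fwd, sb$rev, wa, wb, minOv, denom)
  score <- c(fwd$score, rev$score)
  offset <- c(fwd$offsets, rev$offsets)
  orient <- rep(c("+", "-"), c(length(fwd$offsets), length(rev$offsets)))
  best <- order(-score, abs(offset), orient != "+")[1L]
  list(score = score[best], offset = offset[best], orientation = orient[best])
}

#' Ungapped alignment score between two position weight matrices
#'
#' Slides motif \code{b} (both strands) along motif \code{a} over every
#' ungapped offset with overlap of at least \code{min(4, min(width))} columns.
#' For each offset the score is the sum over overlapping columns of the
#' per-column Pearson correlation of the two probability 4-vectors, divided by
#' \code{max(width(a), width(b))} -- so partial overlaps are penalised and a
#' perfect full-width match of informative columns scores 1. Uniform columns
#' (zero variance) contribute correlation 0. Ties are broken by smaller
#' absolute offset, then by the + orientation.
#'
#' @param a,b [MotifMatrix-class] objects, widths >= 4.
#' @return list with \code{score} (in [-1, 1]), \code{offset} (start of b
#'   relative to a, 0-based) and \code{orientation} ("+" or "-"; "-" means b
#'   was reverse-complemented).
#' @seealso [motifEvalue()], [matchKnown()]
#' @export
alignScore <- function(a, b) {
  .alignStats(.pwmStats(a), .pwmStats(b))
}

## Null motif: permute column order and shuffle entries within each column.
## Keeps the information-content profile of the library while destroying
## motif identity.
.nullMotif <- function(pwm) {
  p <- motifProfile(pwm)
  p <- p[, sample.int(ncol(p)), drop = FALSE]
  for (j in seq_len(ncol(p))) p[, j] <- p[sample.int(4L), j]
  rownames(p) <- DNA_BASES
  new("MotifMatrix", motifID = "null", tfNames = character(),
      profile = p, source = "predicted")
}

#' Calibrate an empirical null for motif-similarity E-values
#'
#' Draws \code{nNull} alignment scores between random pairs of
#' column-shuffled, within-column-resampled library motifs, producing the
#' null score distribution against which [motifEvalue()] converts alignment
#' scores into library-scale E-values. A Gaussian is also fitted to the null
#' scores to extrapolate tail probabilities beyond the empirical resolution.
#'
#' @param library list of [MotifMatrix-class] (>= 2 motifs).
#' @param nNull number of null scores (>= 1000; default 2000).
#' @param seed integer seed.
#' @return a [NullCalibration-class].
#' @export
calibrateNull <- function(library, nNull = 2000L, seed = 1L) {
  if (length(library) < 2L)
    stop("library must contain at least 2 motifs", call. = FALSE)
  nNull <- assertCount(nNull, "nNull", min = 1000L)
  seed <- assertCount(seed, "seed")
  set.seed(seed)
  scores <- numeric(nNull)
  n <- length(library)
  for (i in seq_len(nNull)) {
    pick <- sample.int(n, 2L)
    scores[i] <- .alignStats(.pwmStats(.nullMotif(library[[pick[1]]])),
                             .pwmStats(.nullMotif(library[[pick[2]]])))$score
  }
  scores <- sort(scores)
  new("NullCalibration", nullScores = scores, nNull = nNull,
      librarySize = length(library), seed = seed,
      mu = mean(scores), sigma = sd(scores))
}

#' Convert alignment scores to E-values
#'
#' The empirical E-value is
#' \deqn{E = L \times (\#\{null \ge score\} + 1) / (n_{null} + 1)}
#' with \code{L} the library size: the expected number of equally good matches
#' in a library scan under the null. It is monotone non-increasing in the
#' score and bounded below by \code{L / (n_null + 1)}.
#'
#' \code{method = "tail"} keeps the empirical value while null exceedances
#' exist, but when the score exceeds every null score it switches to
#' \code{L * min(1/(n_null+1), P(Z >= score))} with \code{Z} the Gaussian
#' fitted to the null -- allowing E-values far below the empirical floor
#' (needed for stringent thresholds such as 1e-5 or 1e-8) while preserving
#' monotonicity.
#'
#' @param score numeric vector of alignment scores.
#' @param calib a [NullCalibration-class].
#' @param method \code{"empirical"} (default) or \code{"tail"}.
#' @return numeric vector of positive E-values.
#' @export
motifEvalue <- function(score, calib, method = c("empirical", "tail")) {
  method <- match.arg(method)
  ns <- calib@nullScores
  n <- calib@nNull
  L <- as.numeric(calib@librarySize)
  countGE <- n - findInterval(score, ns, left.open = TRUE)
  e <- L * (countGE + 1) / (n + 1)
  if (method == "tail") {
    zero <- countGE == 0L
    if (any(zero)) {
      tail <- pnorm(score[zero], mean = calib@mu, sd = calib@sigma,
                    lower.tail = FALSE)
      e[zero] <- L * pmin(1 / (n + 1), pmax(tail, .Machine$double.xmin))
    }
  }
  e
}

#' Match a query motif against a known-motif library
#'
#' Aligns the query against every library motif, converts scores to E-values,
#' and returns the matches sorted by ascending E-value (ties by descending
#' score), truncated to the top \code{maxK} and, unless \code{filter =
#' FALSE}, restricted to matches with E-value strictly below \code{cutoff}.
#' The unfiltered mode mirrors allowing a motif-comparison tool to report
#' more top TFs than pass the similarity threshold (useful for paralog
#' diagnostics).
#'
#' @param query a [MotifMatrix-class].
#' @param library list of [MotifMatrix-class].
#' @param calib a [NullCalibration-class] for this library.
#' @param maxK maximum number of matches returned (default 5).
#' @param cutoff E-value threshold, exclusive (default 1e-5).
#' @param filter apply the cutoff (default TRUE).
#' @param method E-value method passed to [motifEvalue()]; default
#'   \code{"tail"} so stringent cutoffs are attainable.
#' @param libStats optional precomputed library column statistics from
#'   repeated scans (internal use; computed automatically when NULL).
#' @return data.frame with columns \code{query_id}, \code{target_id},
#'   \code{tf_names} (comma-joined), \code{offset}, \code{orientation},
#'   \code{score}, \code{evalue}; zero rows if nothing passes.
#' @export
matchKnown <- function(query, library, calib, maxK = 5L, cutoff = 1e-5,
                       filter = TRUE, method = "tail", libStats = NULL) {
  if (!length(library)) stop("empty motif library", call. = FALSE)
  if (is.null(libStats)) libStats <- lapply(library, .pwmStats)
  qs <- .pwmStats(query)
  res <- lapply(libStats, function(t) .alignStats(qs, t))
  score <- vapply(res, `[[`, 0, "score")
  ev <- motifEvalue(score, calib, method = method)
  out <- data.frame(
    query_id = motifID(query),
    target_id = vapply(library, motifID, ""),
    tf_names = vapply(library, function(t) paste(tfNames(t), collapse = ","), ""),
    offset = vapply(res, `[[`, 0L, "offset"),
    orientation = vapply(res, `[[`, "", "orientation"),
    score = score,
    evalue = ev,
    stringsAsFactors = FALSE)
  out <- out[order(out$evalue, -out$score, out$target_id), , drop = FALSE]
  out <- head(out, maxK)
  if (filter) out <- out[out$evalue < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
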