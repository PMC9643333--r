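#' Assign TF cofactors to predicted motifs
#'
#' Matches every predicted motif of every cell line against the known-motif
#' library and keeps, per motif, the TFs behind the passing matches: the
#' single best TF in \code{"top1"} mode, or up to the top five in
#' \code{"top5"} mode. TFs are deduplicated per motif keeping the best
#' (smallest) E-value. Motifs with no passing match are simply absent from
#' the result (not every predicted motif has a similar known motif).
#'
#' @param perLineMotifs named list (cell line -> list of
#'   [MotifMatrix-class]).
#' @param library known-motif library (list of MotifMatrix with TF names).
#' @param calib [NullCalibration-class] for the library.
#' @param mode \code{"top5"} (default) or \code{"top1"}.
#' @param cutoff E-value threshold, exclusive (default 1e-5).
#' @param method E-value method (default \code{"tail"}).
#' @return data.frame with columns \code{motif_id}, \code{cell_line},
#'   \code{tf_name}, \code{evalue}, sorted by ascending E-value within each
#'   motif.
#' @export
assignCofactors <- function(perLineMotifs, library, calib,
                            mode = c("top5", "top1"), cutoff = 1e-5,
                            method = "tail") {
  mode <- match.arg(mode)
  maxK <- if (mode == "top1") 1L else 5L
  libStats <- lapply(library, .pwmStats)
  rows <- list()
  for (line in names(perLineMotifs)) {
    for (m in perLineMotifs[[line]]) {
      hits <- matchKnown(m, library, calib, maxK = maxK, cutoff = cutoff,
                         filter = TRUE, method = method, libStats = libStats)
      if (!nrow(hits)) next
      tf <- strsplit(hits$tf_names, ",", fixed = TRUE)
      df <- data.frame(motif_id = motifID(m), cell_line = line,
                       tf_name = unlist(tf),
                       evalue = rep(hits$evalue, lengths(tf)),
                       stringsAsFactors = FALSE)
      df <- df[nzchar(df$tf_name), , drop = FALSE]
      df <- df[order(df$evalue), , drop = FALSE]
      df <- df[!duplicated(df$tf_name), , drop = FALSE]
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (!length(rows))
    return(data.frame(motif_id = character(), cell_line = character(),
                      tf_name = character(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cofactors whose motifs co-occur with the anchor motif
#'
#' Restricts assigned cofactors to TFs whose motifs share at least one motif
#' module with an anchor motif in at least one cell line -- the modules that
#' carry the anchor TF's own binding signal.
#'
#' @param modules module data.frame covering all cell lines.
#' @param assignments output of [assignCofactors()].
#' @param anchorIds named list (cell line -> character vector of anchor motif
#'   ids).
#' @return character vector of TF names (sorted). If no anchor motif is found
#'   in any line, an empty vector with a warning.
#' @export
anchorCofactors <- function(modules, assignments, anchorIds) {
  anchorIds <- anchorIds[vapply(anchorIds, length, 0L) > 0L]
  if (!length(anchorIds)) {
    warning("no anchor motif found in any cell line")
    return(character())
  }
  tfs <- character()
  for (line in names(anchorIds)) {
    mods <- modules[modules$cell_line == line, , drop = FALSE]
    inAnchor <- vapply(mods$motif_ids, function(ids)
      any(ids %in% anchorIds[[line]]), TRUE)
    partners <- setdiff(unique(unlist(mods$motif_ids[inAnchor])),
                        anchorIds[[line]])
    a <- assignments[assignments$cell_line == line &
                       assignments$motif_id %in% partners, , drop = FALSE]
    tfs <- c(tfs, a$tf_name)
  }
  sort(unique(tfs))
}

#' Predicted cofactor pairs from motif pairs
#'
#' Maps each motif pair to TF pairs under the chosen assignment: every
#' cross-product pair of the two motifs' assigned TFs is a predicted cofactor
#' pair (a motif may correspond to multiple TFs in top-5 mode). Same-TF
#' combinations are dropped; pairs are unordered and deduplicated.
#'
#' @param motifPairs pair data.frame from [modulePairs()] (one cell line).
#' @param assignments output of [assignCofactors()] restricted to (or
#'   covering) that cell line.
#' @return data.frame with character columns \code{a}, \code{b}
#'   (\code{a < b}).
#' @export
cofactorPairs <- function(motifPairs, assignments) {
  tfOf <- split(assignments$tf_name, assignments$motif_id)
  a <- character(); b <- character()
  for (i in seq_len(nrow(motifPairs))) {
    t1 <- tfOf[[motifPairs$a[i]]]; t2 <- tfOf[[motifPairs$b[i]]]
    if (is.null(t1) || is.null(t2)) next
    g <- expand.grid(x = t1, y = t2, stringsAsFactors = FALSE)
    g <- g[g$x != g$y, , drop = FALSE]
    a <- c(a, pmin(g$x, g$y)); b <- c(b, pmax(g$x, g$y))
  }
  keep <- !duplicated(pairKey(a, b))
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

#' Split a PPI network into direct and indirect TF pairs
#'
#' Direct pairs are edges whose two endpoints are both TFs (a physical
#' interaction). Indirect pairs are unordered TF pairs sharing at least one
#' common interactor (TF or not) -- a path of length two -- excluding pairs
#' that are already direct. The two classes are disjoint so they can be
#' tested separately.
#'
#' @param ppi a [PPINetwork-class].
#' @return list with data.frames \code{direct} and \code{indirect}, each with
#'   character columns \code{a}, \code{b} (\code{a < b}).
#' @export
splitDirectIndirect <- function(ppi) {
  e <- ppiEdges(ppi); flags <- ppiTfFlags(ppi)
  isTf <- flags[e$a] & flags[e$b]
  direct <- e[isTf, c("a", "b"), drop = FALSE]
  rownames(direct) <- NULL
  ## neighbours of every protein; TF pairs among each neighbourhood
  nb <- split(c(e$b, e$a), c(e$a, e$b))
  a <- character(); b <- character()
  for (p in names(nb)) {
    tfNb <- unique(nb[[p]])
    tfNb <- tfNb[flags[tfNb]]
    if (length(tfNb) < 2L) next
    cmb <- combn(sort(tfNb), 2L)
    a <- c(a, cmb[1L, ]); b <- c(b, cmb[2L, ])
  }
  if (length(a)) {
    keys <- pairKey(a, b)
    keep <- !duplicated(keys) & !(keys %in% pairKey(direct$a, direct$b))
    indirect <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  } else {
    indirect <- data.frame(a = character(), b = character(),
                           stringsAsFactors = FALSE)
  }
  list(direct = direct, indirect = indirect)
}

#' Hypergeometric upper tail
#'
#' The enrichment statistic
#' \deqn{phyper(x_1, y_1, x_2, y_2) = \sum_{k=x_1}^{\min(y_1, x_2)}
#'   \frac{\binom{y_1}{k} \binom{y_2-y_1}{x_2-k}}{\binom{y_2}{x_2}},}
#' the probability of drawing at least \eqn{x_1} marked items when drawing
#' \eqn{x_2} items without replacement from a population of \eqn{y_2} items
#' of which \eqn{y_1} are marked. Computed in log space via
#' \code{lchoose}, so large arguments are safe; infeasible summation terms
#' contribute 0, and \code{phyperTail(0, ...)} is 1.
#'
#' @param x1,y1,x2,y2 non-negative integers with \code{y1 <= y2} and
#'   \code{x2 <= y2}.
#' @return the tail probability in [0, 1].
#' @examples
#' phyperTail(1, 2, 2, 4)  # 5/6
#' @export
phyperTail <- function(x1, y1, x2, y2) {
  for (v in list(x1 = x1, y1 = y1, x2 = x2, y2 = y2))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("phyperTail arguments must be single non-negative integers",
           call. = FALSE)
  if (y1 > y2 || x2 > y2)
    stop("phyperTail requires y1 <= y2 and x2 <= y2", call. = FALSE)
  kmax <- min(y1, x2)
  kmin <- max(x1, 0, x2 - (y2 - y1))
  if (kmin > kmax) return(0)
  k <- seq.int(kmin, kmax)
  lt <- lchoose(y1, k) + lchoose(y2 - y1, x2 - k) - lchoose(y2, x2)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Enrichment of known interacting TF pairs among predicted cofactor pairs
#'
#' With \code{N} TFs in the interaction database and \code{M} known
#' interacting pairs, \code{n} distinct TFs among the predicted cofactor
#' pairs and \code{m} predicted pairs known to interact, the p-value is
#' \code{phyperTail(m, n(n-1)/2, M, N(N-1)/2)}.
#'
#' @param predictedPairs data.frame of unordered TF pairs (columns \code{a},
#'   \code{b}), e.g. from [cofactorPairs()].
#' @param knownPairs data.frame of known interacting TF pairs (one class from
#'   [splitDirectIndirect()]).
#' @param N number of TFs in the database universe.
#' @param interactionClass label recorded in the result
#'   (\code{"direct"}, \code{"indirect"} or \code{"either"}).
#' @return list with \code{n}, \code{m}, \code{N}, \code{M}, \code{pValue},
#'   \code{interactionClass}. When fewer than 2 distinct TFs are predicted,
#'   p = 1 with a warning.
#' @export
pairEnrichment <- function(predictedPairs, knownPairs, N,
                           interactionClass = c("direct", "indirect", "either")) {
  interactionClass <- match.arg(interactionClass)
  N <- assertCount(N, "N", 0L)
  n <- length(unique(c(predictedPairs$a, predictedPairs$b)))
  M <- nrow(knownPairs)
  if (n < 2L) {
    warning("fewer than 2 distinct predicted TFs; p = 1")
    return(list(n = n, m = 0L, N = N, M = M, pValue = 1,
                interactionClass = interactionClass))
  }
  m <- sum(pairKey(predictedPairs$a, predictedPairs$b) %in%
             pairKey(knownPairs$a, knownPairs$b))
  p <- phyperTail(m, n * (n - 1) / 2, M, N * (N - 1) / 2)
  list(n = n, m = m, N = N, M = M, pValue = p,
       interactionClass = interactionClass)
}

#' Rank predicted cofactors
#'
#' Per TF, let \code{L} be the number of cell lines with at least one motif
#' assigned to it and let the mean negative log E-value be the arithmetic
#' mean over those lines of \code{-log10} of the best (smallest) E-value of
#' the TF's motifs in the line (a geometric-mean E-value across lines). The
#' ranking score is their product \code{s = mean * L}; a TF passes the cutoff
#' when \code{s > tau} strictly -- at the default \code{tau = 15}, a TF with
#' average E-value exactly 1e-5 in exactly 3 lines scores 15 and does not
#' pass (a top cofactor must beat an average E-value of 1e-5 and occur in
#' more than three lines).
#'
#' @param assignments output of [assignCofactors()] across all lines.
#' @param tau score cutoff (default 15).
#' @param perLine alternative weighting: \code{"cell_lines"} (default, the
#'   number of distinct cell lines) or \code{"modules"} -- kept as a switch
#'   because study descriptions sometimes count motif modules instead; the
#'   cell-line count is what makes the default cutoff of 15 interpretable.
#' @param modules module data.frame, required for
#'   \code{perLine = "modules"}.
#' @return data.frame sorted by descending score with columns
#'   \code{tf_name}, \code{n_cell_lines}, \code{mean_neglog10_evalue},
#'   \code{score}, \code{passes_cutoff}.
#' @export
rankCofactors <- function(assignments, tau = 15,
                          perLine = c("cell_lines", "modules"),
                          modules = NULL) {
  perLine <- match.arg(perLine)
  if (!nrow(assignments))
    return(data.frame(tf_name = character(), n_cell_lines = integer(),
                      mean_neglog10_evalue = numeric(), score = numeric(),
                      passes_cutoff = logical(), stringsAsFactors = FALSE))
  best <- stats::aggregate(evalue ~ tf_name + cell_line, assignments, min)
  nl <- -log10(best$evalue)
  meanNl <- tapply(nl, best$tf_name, mean)
  cnt <- tapply(best$cell_line, best$tf_name, function(x) length(unique(x)))
  agg <- data.frame(tf_name = names(meanNl),
                    mean_neglog10_evalue = as.numeric(meanNl),
                    n_cell_lines = as.integer(cnt[names(meanNl)]),
                    stringsAsFactors = FALSE)
  weight <- if (perLine == "cell_lines") {
    agg$n_cell_lines
  } else {
    if (is.null(modules))
      stop("perLine = 'modules' requires the modules table", call. = FALSE)
    nMods <- vapply(agg$tf_name, function(tf) {
      ids <- assignments$motif_id[assignments$tf_name == tf]
      sum(vapply(modules$motif_ids, function(mm) any(mm %in% ids), TRUE))
    }, 0L)
    nMods
  }
  agg$score <- agg$mean_neglog10_evalue * weight
  agg$passes_cutoff <- agg$score > tau
  agg <- agg[order(-agg$score, agg$tf_name),
             c("tf_name", "n_cell_lines", "mean_neglog10_evalue", "score",
               "passes_cutoff")]
  rownames(agg) <- NULL
  agg
}

#' Recovery of curated cofactors
#'
#' How many curated cofactors appear among the predicted ones, as a count and
#' a percentage rounded to one decimal (half-up, as printed in study tables:
#' 21 of 29 gives 72.4).
#'
#' @param predicted character vector of predicted TF names.
#' @param curated non-empty character vector of curated cofactor names.
#' @return list with \code{hits}, \code{total}, \code{percent} and
#'   \code{missed} (curated cofactors not predicted, for paralog
#'   diagnostics).
#' @examples
#' recoveryStats(paste0("TF", 1:21), paste0("TF", 1:29))$percent  # 72.4
#' @export
recoveryStats <- function(predicted, curated) {
  curated <- unique(as.character(curated))
  if (!length(curated)) stop("curated cofactor list is empty", call. = FALSE)
  hits <- sum(curated %in% predicted)
  list(hits = hits, total = length(curated),
       percent = roundHalfUp(100 * hits / length(curated), 1L),
       missed = setdiff(curated, predicted))
}

#' Combine independent p-values with Fisher's method
#'
#' \code{-2 * sum(log(p))} is chi-squared with \code{2k} degrees of freedom
#' under the global null. Used to summarise the per-cell-line cofactor-pair
#' enrichment tests into one study-level p-value; for conservative
#' (super-uniform) component tests the combination stays conservative.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return a single p-value.
#' @export
fisherCombine <- function(p) {
  if (!length(p) || any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p must be p-values in (0, 1]", call. = FALSE)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
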