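#' GO term over-representation of a study gene set
#'
#' Hypergeometric over-representation of each GO term among the study genes
#' relative to a gene universe, using the same upper-tail statistic as the
#' cofactor-pair enrichment ([phyperTail()]): for a term annotating \code{K}
#' universe genes of which \code{k} are study genes,
#' \code{p = phyperTail(k, nStudy, K, nUniverse)}. Benjamini-Hochberg
#' q-values are computed across all tested terms (those with at least one
#' study hit); the "enriched set" is the terms with \code{q < alpha}.
#'
#' @param studyGenes character vector of study gene ids (must be a subset of
#'   the universe).
#' @param gene2go data.frame with columns \code{gene_id}, \code{term_id}.
#' @param universeGenes character vector of universe gene ids (non-empty).
#' @param alpha enrichment threshold on q (default 0.05).
#' @return data.frame sorted by p with columns \code{term_id}, \code{k},
#'   \code{n_study}, \code{K}, \code{n_universe}, \code{p}, \code{q},
#'   \code{enriched}.
#' @export
goEnrichment <- function(studyGenes, gene2go, universeGenes, alpha = 0.05) {
  universeGenes <- unique(as.character(universeGenes))
  if (!length(universeGenes)) stop("empty gene universe", call. = FALSE)
  studyGenes <- unique(as.character(studyGenes))
  if (!all(studyGenes %in% universeGenes))
    stop("study genes must be a subset of the universe", call. = FALSE)
  g2g <- gene2go[gene2go$gene_id %in% universeGenes, , drop = FALSE]
  g2g <- unique(g2g[c("gene_id", "term_id")])
  nU <- length(universeGenes); nS <- length(studyGenes)
  K <- table(g2g$term_id)
  kTab <- table(g2g$term_id[g2g$gene_id %in% studyGenes])
  terms <- names(kTab)   # tested terms: >= 1 study hit
  if (!length(terms))
    return(data.frame(term_id = character(), k = integer(), n_study = integer(),
                      K = integer(), n_universe = integer(), p = numeric(),
                      q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  k <- as.integer(kTab[terms])
  KK <- as.integer(K[terms])
  p <- vapply(seq_along(terms), function(i) phyperTail(k[i], nS, KK[i], nU), 0)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(term_id = terms, k = k, n_study = nS, K = KK,
                    n_universe = nU, p = p, q = q, enriched = q < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard distance between two sets
#'
#' \code{1 - |a intersect b| / |a union b|}; 0 for two empty sets by
#' convention. Used as the "difference" between two cell lines' cofactor or
#' GO-term sets: symmetric, bounded in [0, 1] and robust to set size.
#'
#' @param a,b character vectors (treated as sets).
#' @param method \code{"jaccard"} (default) or \code{"normdiff"}, the
#'   normalised symmetric difference \code{|a xor b| / (|a| + |b|)}.
#' @return a number in [0, 1].
#' @export
setDistance <- function(a, b, method = c("jaccard", "normdiff")) {
  method <- match.arg(method)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) && !length(b)) return(0)
  int <- length(intersect(a, b))
  if (method == "jaccard") 1 - int / length(union(a, b))
  else (length(a) + length(b) - 2 * int) / (length(a) + length(b))
}

#' Divergence regression: GO-term difference versus cofactor difference
#'
#' For every pair of cell lines, computes the difference (Jaccard distance by
#' default) between their cofactor sets and between their enriched GO-term
#' sets. For each cell line an ordinary least-squares regression of GO
#' difference on cofactor difference is fitted over that line's pairs with
#' every other line, giving a per-line R-squared; the summary statistic is
#' the arithmetic mean over lines. A strong positive relationship indicates
#' that cofactor divergence drives pathway divergence.
#'
#' @param perLineCofactors named list (cell line -> character vector of
#'   cofactor TF names).
#' @param perLineTerms named list (cell line -> character vector of enriched
#'   GO terms), same names.
#' @param method set-difference metric, see [setDistance()].
#' @return list with \code{points} (data.frame \code{line_a}, \code{line_b},
#'   \code{cofactor_diff}, \code{go_diff}), \code{perLineR2} (named numeric;
#'   NA where the regressor has zero variance, with a warning) and
#'   \code{meanR2} (mean over defined lines).
#' @export
divergenceRegression <- function(perLineCofactors, perLineTerms,
                                 method = "jaccard") {
  lines <- names(perLineCofactors)
  if (length(lines) < 3L)
    stop("divergence regression requires >= 3 cell lines", call. = FALSE)
  if (!identical(sort(lines), sort(names(perLineTerms))))
    stop("cofactor and term lists must cover the same cell lines", call. = FALSE)
  pairs <- combn(lines, 2L)
  cd <- vapply(seq_len(ncol(pairs)), function(i)
    setDistance(perLineCofactors[[pairs[1L, i]]],
                perLineCofactors[[pairs[2L, i]]], method), 0)
  gd <- vapply(seq_len(ncol(pairs)), function(i)
    setDistance(perLineTerms[[pairs[1L, i]]],
                perLineTerms[[pairs[2L, i]]], method), 0)
  points <- data.frame(line_a = pairs[1L, ], line_b = pairs[2L, ],
                       cofactor_diff = cd, go_diff = gd,
                       stringsAsFactors = FALSE)
  divergenceFit(points)
}

#' Per-line regression fits over divergence points
#'
#' The regression stage of [divergenceRegression()], exposed separately so
#' precomputed point sets can be fitted directly: per cell line, OLS of
#' \code{go_diff} on \code{cofactor_diff} over the pairs involving that line.
#'
#' @param points data.frame with columns \code{line_a}, \code{line_b},
#'   \code{cofactor_diff}, \code{go_diff} (symmetric in the pair).
#' @return list with \code{points}, \code{perLineR2}, \code{meanR2} as in
#'   [divergenceRegression()].
#' @export
divergenceFit <- function(points) {
  lines <- sort(unique(c(points$line_a, points$line_b)))
  perLineR2 <- setNames(rep(NA_real_, length(lines)), lines)
  for (line in lines) {
    sel <- points$line_a == line | points$line_b == line
    x <- points$cofactor_diff[sel]; y <- points$go_diff[sel]
    if (length(unique(x)) < 2L) {
      warning(sprintf("cell line %s: zero variance in cofactor difference; R2 undefined",
                      line))
      next
    }
    perLineR2[line] <- suppressWarnings(summary(lm(y ~ x))$r.squared)
  }
  list(points = points, perLineR2 = perLineR2,
       meanR2 = mean(perLineR2, na.rm = TRUE))
}
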