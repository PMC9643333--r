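#' All motif pairs occurring in a set of motif modules
#'
#' The union over modules of all unordered size-2 member subsets,
#' deduplicated. These are the "motif pairs of a cell line".
#'
#' @param modules module data.frame ([readMotifModules()] layout) or a list of
#'   character vectors of member motif ids; expected to come from one cell
#'   line.
#' @return data.frame with character columns \code{a}, \code{b}
#'   (\code{a < b}), one row per distinct pair.
#' @export
modulePairs <- function(modules) {
  members <- if (is.data.frame(modules)) modules$motif_ids else modules
  if (!length(members))
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  pairs <- lapply(members, function(ids) {
    ids <- unique(as.character(ids))
    if (length(ids) < 2L) return(NULL)
    combn(sort(ids), 2L)
  })
  m <- do.call(cbind, pairs)
  if (is.null(m))
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  keep <- !duplicated(pairKey(m[1L, ], m[2L, ]))
  data.frame(a = m[1L, keep], b = m[2L, keep], stringsAsFactors = FALSE)
}

#' Cross-cell-line motif similarity relation
#'
#' Computes, for every pair of predicted motifs from different cell lines,
#' whether their alignment E-value is below \code{thetaCross}, and returns the
#' resulting symmetric relation. Motif ids must be globally unique. Both
#' [motifConservation()] and [pairConservation()] consume the same relation,
#' so it is computed once and passed around.
#'
#' @param perLineMotifs named list (cell line -> list of
#'   [MotifMatrix-class]).
#' @param calib [NullCalibration-class] used for E-values.
#' @param thetaCross E-value threshold for cross-line similarity (default
#'   1e-8).
#' @param method E-value method (default \code{"tail"}; see [motifEvalue()]).
#' @return object of class \code{"motifSimilarity"}: list with
#'   \code{similar} (named list: motif id -> character vector of similar
#'   motif ids in other lines), \code{motifLine} (named character: id ->
#'   line) and \code{theta}.
#' @export
crossLineSimilarity <- function(perLineMotifs, calib, thetaCross = 1e-8,
                                method = "tail") {
  allMotifs <- unlist(perLineMotifs, recursive = FALSE, use.names = FALSE)
  ids <- vapply(allMotifs, motifID, "")
  if (anyDuplicated(ids))
    stop("motif ids must be globally unique across cell lines", call. = FALSE)
  lineOf <- setNames(rep(names(perLineMotifs), lengths(perLineMotifs)), ids)
  n <- length(allMotifs)
  similar <- setNames(vector("list", n), ids)
  for (x in ids) similar[[x]] <- character()
  if (n >= 2L) {
    stats <- lapply(allMotifs, .pwmStats)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (lineOf[ids[i]] == lineOf[ids[j]]) next
        s <- .alignStats(stats[[i]], stats[[j]])$score
        if (motifEvalue(s, calib, method = method) < thetaCross) {
          similar[[ids[i]]] <- c(similar[[ids[i]]], ids[j])
          similar[[ids[j]]] <- c(similar[[ids[j]]], ids[i])
        }
      }
    }
  }
  structure(list(similar = similar, motifLine = lineOf, theta = thetaCross),
            class = "motifSimilarity")
}

#' Cross-cell-line motif conservation
#'
#' For each cell line, the fraction of its predicted motifs that have at
#' least one similar motif (E-value below \code{thetaCross}) in at least one
#' other cell line.
#'
#' @inheritParams crossLineSimilarity
#' @param simRel optional precomputed [crossLineSimilarity()] relation; when
#'   supplied, \code{calib}/\code{thetaCross}/\code{method} are ignored.
#' @return named numeric vector of fractions in [0, 1], one per cell line.
#' @export
motifConservation <- function(perLineMotifs, calib = NULL, thetaCross = 1e-8,
                              method = "tail", simRel = NULL) {
  if (length(perLineMotifs) < 2L)
    stop("motif conservation requires >= 2 cell lines", call. = FALSE)
  if (is.null(simRel))
    simRel <- crossLineSimilarity(perLineMotifs, calib, thetaCross, method)
  vapply(names(perLineMotifs), function(line) {
    ids <- vapply(perLineMotifs[[line]], motifID, "")
    mean(vapply(ids, function(id) length(simRel$similar[[id]]) > 0L, TRUE))
  }, 0)
}

.linePairSets <- function(perLinePairs) {
  lapply(perLinePairs, function(p) pairKey(p$a, p$b))
}

.pairConserved <- function(a, b, line, simRel, pairSets) {
  simA <- simRel$similar[[a]]; simB <- simRel$similar[[b]]
  if (!length(simA) || !length(simB)) return(FALSE)
  for (other in names(pairSets)) {
    if (other == line) next
    ca <- simA[simRel$motifLine[simA] == other]
    cb <- simB[simRel$motifLine[simB] == other]
    if (!length(ca) || !length(cb)) next
    keys <- pairKey(rep(ca, each = length(cb)), rep(cb, length(ca)))
    if (any(keys %in% pairSets[[other]])) return(TRUE)
  }
  FALSE
}

#' Cross-cell-line conservation of motif pairs
#'
#' A motif pair (a, b) of one cell line is conserved if some other cell line
#' contains a pair (c, d) with a similar to c and b similar to d, or a
#' similar to d and b similar to c (unordered matching), similarity meaning
#' an alignment E-value below the relation's threshold.
#'
#' @param perLinePairs named list (cell line -> pair data.frame from
#'   [modulePairs()]).
#' @param simRel a [crossLineSimilarity()] relation over the same motifs.
#' @return list with \code{perLine} (named fractions), \code{overall}
#'   (pooled fraction over all lines' pairs) and \code{theta}. With a single
#'   cell line all fractions are 0 and a warning is raised.
#' @export
pairConservation <- function(perLinePairs, simRel) {
  if (length(perLinePairs) < 2L)
    warning("pair conservation over a single cell line is 0 by definition")
  pairSets <- .linePairSets(perLinePairs)
  conserved <- 0L; total <- 0L
  perLine <- setNames(numeric(length(perLinePairs)), names(perLinePairs))
  for (line in names(perLinePairs)) {
    p <- perLinePairs[[line]]
    if (!nrow(p)) { perLine[line] <- 0; next }
    hit <- vapply(seq_len(nrow(p)), function(i)
      .pairConserved(p$a[i], p$b[i], line, simRel, pairSets), TRUE)
    perLine[line] <- mean(hit)
    conserved <- conserved + sum(hit); total <- total + nrow(p)
  }
  list(perLine = perLine,
       overall = if (total > 0L) conserved / total else 0,
       theta = simRel$theta)
}

#' Random-motif-module resampling null for pair conservation
#'
#' Assesses whether the observed cross-line conservation of motif pairs
#' exceeds what random motif modules would produce. Per replicate, every
#' module in every cell line is rebuilt by sampling (without replacement,
#' uniformly from that line's predicted motifs) a random member set of the
#' same size, and the overall pair-conservation fraction is recomputed. The
#' motif similarity relation is unchanged by the resampling, so it is
#' computed once and reused.
#'
#' @param modules module data.frame covering all cell lines.
#' @param perLineMotifs named list (cell line -> list of MotifMatrix).
#' @param calib [NullCalibration-class] (ignored when \code{simRel} given).
#' @param R number of replicates (>= 99).
#' @param thetaCross similarity threshold (default 1e-8).
#' @param seed integer seed.
#' @param method E-value method (default \code{"tail"}).
#' @param simRel optional precomputed [crossLineSimilarity()].
#' @return list with \code{observed} (the real overall fraction, identical to
#'   [pairConservation()]'s), \code{nullFractions} (length R),
#'   \code{pEmpirical} = (1 + #\{null >= observed\}) / (R + 1),
#'   \code{pNormal} (upper tail of a Gaussian fitted to the null fractions)
#'   and \code{seed}.
#' @export
randomPairNull <- function(modules, perLineMotifs, calib = NULL, R = 199L,
                           thetaCross = 1e-8, seed = 1L, method = "tail",
                           simRel = NULL) {
  R <- assertCount(R, "R", min = 99L)
  seed <- assertCount(seed, "seed")
  lines <- names(perLineMotifs)
  if (is.null(simRel))
    simRel <- crossLineSimilarity(perLineMotifs, calib, thetaCross, method)
  lineIds <- lapply(perLineMotifs, function(ms) vapply(ms, motifID, ""))
  sizesByLine <- lapply(lines, function(line)
    lengths(modules$motif_ids[modules$cell_line == line]))
  names(sizesByLine) <- lines
  for (line in lines)
    if (length(sizesByLine[[line]]) &&
        max(sizesByLine[[line]]) > length(lineIds[[line]]))
      stop(sprintf("cell line %s: a module is larger than its motif list", line),
           call. = FALSE)
  realPairs <- lapply(lines, function(line)
    modulePairs(modules$motif_ids[modules$cell_line == line]))
  names(realPairs) <- lines
  observed <- pairConservation(realPairs, simRel)$overall
  set.seed(seed)
  nullFractions <- vapply(seq_len(R), function(r) {
    rndPairs <- lapply(lines, function(line) {
      memb <- lapply(sizesByLine[[line]], function(k)
        sample(lineIds[[line]], k))
      modulePairs(memb)
    })
    names(rndPairs) <- lines
    pairConservation(rndPairs, simRel)$overall
  }, 0)
  mu <- mean(nullFractions); sg <- sd(nullFractions)
  pNormal <- if (is.na(sg) || sg == 0)
    as.numeric(observed <= mu) else
    pnorm(observed, mean = mu, sd = sg, lower.tail = FALSE)
  list(observed = observed, nullFractions = nullFractions,
       pEmpirical = (1 + sum(nullFractions >= observed)) / (R + 1),
       pNormal = pNormal, seed = seed)
}

#' Co-occurrence significance of a motif set
#'
#' One-sided binomial tail for the number of sequences containing every
#' member of the set, under the independence null: with \code{n} sequences,
#' \code{x} sequences containing all members and \code{p0} the product of the
#' per-motif marginal frequencies, returns \code{P(X >= x)} for
#' \code{X ~ Binomial(n, p0)}. This is the significance notion behind calling
#' a motif set a module.
#'
#' @param occurrence logical matrix, sequences x motifs, with motif ids as
#'   column names.
#' @param motifSet character vector (>= 2) of member motif ids.
#' @return p-value in (0, 1]. Any zero marginal yields p = 1 with a warning.
#' @export
cooccurrencePvalue <- function(occurrence, motifSet) {
  motifSet <- unique(as.character(motifSet))
  if (length(motifSet) < 2L)
    stop("motifSet must contain >= 2 motifs", call. = FALSE)
  if (!all(motifSet %in% colnames(occurrence)))
    stop("all motifs in motifSet must be columns of the occurrence matrix",
         call. = FALSE)
  sub <- occurrence[, motifSet, drop = FALSE]
  marg <- colMeans(sub)
  if (any(marg == 0)) {
    warning("zero marginal frequency for motif(s): ",
            paste(motifSet[marg == 0], collapse = ", "), "; p = 1")
    return(1)
  }
  n <- nrow(sub)
  x <- sum(rowSums(sub) == length(motifSet))
  p0 <- prod(marg)
  if (x == 0L) return(1)
  pbinom(x - 1L, size = n, prob = p0, lower.tail = FALSE)
}
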