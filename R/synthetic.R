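.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

.columnIC <- function(p) {
  nz <- p > 0
  2 + sum(p[nz] * log2(p[nz]))
}

#' Configuration for a synthetic cofactor study
#'
#' Collects every knob of the synthetic-study generator. The defaults emulate
#' an eight-cell-line anchor-TF ChIP-seq study: each line carries ~25
#' predicted motifs of which 70\% derive from a shared conserved core, motif
#' modules of size 2-5 that contain the anchor motif with probability 0.8, a
#' PPI network whose TF-TF edges concentrate on the planted cofactors, and a
#' toy two-chromosome genome whose peak-target genes carry GO terms tied to
#' the planted cofactors (so that cell lines sharing more cofactors share
#' more target-gene GO terms).
#'
#' @param nCellLines number of cell lines (default 8).
#' @param librarySize number of known TF motifs in the library (default 60).
#' @param motifsPerLine predicted motifs per cell line, anchor included
#'   (default 25; must be <= librarySize).
#' @param conservationRate fraction of a line's non-anchor motifs drawn from
#'   the shared conserved core pool (default 0.7).
#' @param nModulesPerLine motif modules per cell line (default 30).
#' @param moduleSizeRange integer interval of module sizes (default c(2, 5)).
#' @param pAnchor probability a module contains the anchor motif (default 0.8).
#' @param pwmNoise Dirichlet concentration multiplier used to perturb planted
#'   motifs into "predicted" ones (default 50; larger = less noise).
#' @param nTrueCofactors number of planted cofactor TFs (default 15).
#' @param ppiBackgroundDensity probability of a background PPI edge between
#'   any two proteins (default 0.02).
#' @param nGenes annotated genes on the toy genome (default 500).
#' @param nGoTerms GO terms (default 40).
#' @param seed integer seed; a counter-based fan-out derives independent
#'   per-component seeds from it.
#' @param widthRange motif width interval (default c(6, 12)).
#' @param corePoolSize size of the conserved core pool the per-line cores are
#'   drawn from; must hold all true cofactors (default 28).
#' @param cofactorEdgeRate fraction of co-occurring cofactor-cofactor pairs
#'   planted as PPI edges (default 0.6).
#' @param nBackgroundProteins non-TF proteins in the PPI network (default 60).
#' @param genesPerCofactor program genes per core-pool TF (default 12):
#'   every conserved-core TF drives a small target-gene program.
#' @param termsPerCofactor GO terms per core-pool TF program (default 1).
#' @param backgroundPeaksPerLine background peaks per cell line (default 50).
#' @param peakLenRange peak length interval in bp (default c(200, 600)).
#' @param lineSimilarityBandwidth bandwidth of the circular similarity
#'   gradient weighting each line's core-pool draw (default 0.18). Cell lines
#'   and pool TFs sit on a circle; a line samples pool TFs with Gaussian
#'   preference for nearby ones, so related lines share more of the conserved
#'   core and pairwise cofactor overlap varies across line pairs, as it does
#'   across real cell-line panels. Large values approach uniform draws.
#' @param sharedModuleRate fraction of a line's modules instantiating a
#'   shared cross-line module template rather than a line-random motif set
#'   (default 0.7): TF complexes recur across cell lines, which is what the
#'   conservation analysis measures.
#' @param nModuleTemplates number of global module templates (default 40).
#' @return a list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nCellLines = 8L, librarySize = 60L,
                            motifsPerLine = 25L, conservationRate = 0.7,
                            nModulesPerLine = 30L, moduleSizeRange = c(2L, 5L),
                            pAnchor = 0.8, pwmNoise = 50,
                            nTrueCofactors = 15L, ppiBackgroundDensity = 0.02,
                            nGenes = 500L, nGoTerms = 40L, seed = 1L,
                            widthRange = c(6L, 12L), corePoolSize = 28L,
                            cofactorEdgeRate = 0.6, nBackgroundProteins = 60L,
                            genesPerCofactor = 12L, termsPerCofactor = 1L,
                            backgroundPeaksPerLine = 50L,
                            peakLenRange = c(200L, 600L),
                            lineSimilarityBandwidth = 0.18,
                            sharedModuleRate = 0.7, nModuleTemplates = 40L) {
  cfg <- list(nCellLines = assertCount(nCellLines, "nCellLines", 2L),
              librarySize = assertCount(librarySize, "librarySize", 2L),
              motifsPerLine = assertCount(motifsPerLine, "motifsPerLine", 2L),
              conservationRate = conservationRate,
              nModulesPerLine = assertCount(nModulesPerLine, "nModulesPerLine", 1L),
              moduleSizeRange = as.integer(moduleSizeRange),
              pAnchor = pAnchor, pwmNoise = pwmNoise,
              nTrueCofactors = assertCount(nTrueCofactors, "nTrueCofactors", 1L),
              ppiBackgroundDensity = ppiBackgroundDensity,
              nGenes = assertCount(nGenes, "nGenes", 10L),
              nGoTerms = assertCount(nGoTerms, "nGoTerms", 2L),
              seed = assertCount(seed, "seed"),
              widthRange = as.integer(widthRange),
              corePoolSize = assertCount(corePoolSize, "corePoolSize", 2L),
              cofactorEdgeRate = cofactorEdgeRate,
              nBackgroundProteins = assertCount(nBackgroundProteins,
                                                "nBackgroundProteins", 0L),
              genesPerCofactor = assertCount(genesPerCofactor, "genesPerCofactor", 1L),
              termsPerCofactor = assertCount(termsPerCofactor, "termsPerCofactor", 1L),
              backgroundPeaksPerLine = assertCount(backgroundPeaksPerLine,
                                                   "backgroundPeaksPerLine", 0L),
              peakLenRange = as.integer(peakLenRange),
              lineSimilarityBandwidth = lineSimilarityBandwidth,
              sharedModuleRate = sharedModuleRate,
              nModuleTemplates = assertCount(nModuleTemplates,
                                             "nModuleTemplates", 1L))
  probs <- c(conservationRate = cfg$conservationRate, pAnchor = cfg$pAnchor,
             ppiBackgroundDensity = cfg$ppiBackgroundDensity,
             cofactorEdgeRate = cfg$cofactorEdgeRate,
             sharedModuleRate = cfg$sharedModuleRate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "), call. = FALSE)
  if (cfg$pwmNoise <= 0) stop("pwmNoise must be > 0", call. = FALSE)
  if (cfg$lineSimilarityBandwidth <= 0)
    stop("lineSimilarityBandwidth must be > 0", call. = FALSE)
  if (cfg$motifsPerLine > cfg$librarySize)
    stop("infeasible config: motifsPerLine > librarySize", call. = FALSE)
  if (cfg$moduleSizeRange[1] < 2L || cfg$moduleSizeRange[2] < cfg$moduleSizeRange[1])
    stop("module sizes must be >= 2 with a valid range", call. = FALSE)
  if (cfg$moduleSizeRange[2] > cfg$motifsPerLine)
    stop("infeasible config: module size exceeds motifsPerLine", call. = FALSE)
  if (cfg$widthRange[1] < 4L)
    stop("motif widths must be >= 4", call. = FALSE)
  if (cfg$corePoolSize < cfg$nTrueCofactors)
    stop("corePoolSize must be >= nTrueCofactors", call. = FALSE)
  if (cfg$corePoolSize > cfg$librarySize - 1L)
    stop("corePoolSize must leave room for the anchor TF", call. = FALSE)
  if (cfg$nTrueCofactors > cfg$librarySize - 1L)
    stop("infeasible config: more cofactors than non-anchor TFs", call. = FALSE)
  if (cfg$termsPerCofactor * cfg$corePoolSize > cfg$nGoTerms)
    stop("infeasible config: not enough GO terms for the core-pool TF programs",
         call. = FALSE)
  if (cfg$genesPerCofactor * cfg$corePoolSize > cfg$nGenes)
    stop("infeasible config: not enough genes for the core-pool TF programs",
         call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a library of informative position weight matrices
#'
#' Columns are drawn from a sparse Dirichlet (concentration 0.2 per base) so
#' that motifs are informative; any motif whose mean per-column information
#' content falls below 0.5 bits is redrawn. Ids (\code{KN...}) and TF names
#' (\code{TF...}) are assigned deterministically from the seed.
#'
#' @param n number of motifs (>= 1).
#' @param widthRange integer interval of motif widths (lower bound >= 4).
#' @param seed integer seed.
#' @param source provenance tag (default \code{"known"}).
#' @return list of \code{n} [MotifMatrix-class] objects.
#' @export
generatePwmLibrary <- function(n, widthRange = c(6L, 12L), seed = 1L,
                               source = "known") {
  assertCount(n, "n", 1L)
  if (widthRange[1] < 4L)
    stop("motif widths must be >= 4", call. = FALSE)
  set.seed(assertCount(seed, "seed"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- sample(seq.int(widthRange[1], widthRange[2]), 1L)
    repeat {
      m <- vapply(seq_len(w), function(j) .rdirichlet1(rep(0.2, 4L)), numeric(4))
      rownames(m) <- DNA_BASES
      if (mean(apply(m, 2L, .columnIC)) >= 0.5) break
    }
    out[[i]] <- new("MotifMatrix", motifID = sprintf("KN%03d", i),
                    tfNames = sprintf("TF%03d", i), profile = m, source = source)
  }
  out
}

#' Perturb a position weight matrix
#'
#' Resamples each column from \code{Dirichlet(kappa * column + 0.01)},
#' preserving the width. Large \code{kappa} means small drift (at
#' \code{kappa = 1e4} the maximum per-entry drift is below 0.05 with high
#' probability); the generator uses this to derive "predicted" motifs from
#' planted known ones.
#'
#' @param pwm a [MotifMatrix-class].
#' @param kappa concentration multiplier (> 0).
#' @param seed optional integer seed for reproducibility.
#' @param motifID id for the perturbed copy (default: same as source).
#' @return a [MotifMatrix-class] tagged \code{source = "predicted"}.
#' @export
perturbPwm <- function(pwm, kappa = 50, seed = NULL, motifID = NULL) {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(assertCount(seed, "seed"))
  p <- motifProfile(pwm)
  q <- vapply(seq_len(ncol(p)), function(j) .rdirichlet1(kappa * p[, j] + 0.01),
              numeric(4))
  rownames(q) <- DNA_BASES
  new("MotifMatrix", motifID = motifID %||% motifID(pwm), tfNames = character(),
      profile = q, source = "predicted")
}

#' Simulate a complete cofactor study with planted ground truth
#'
#' Generates one synthetic study under a [syntheticConfig()]:
#' \itemize{
#'   \item a known-motif library with TF names; the first TF is the anchor;
#'   \item planted cofactor TFs and a conserved core pool containing them;
#'   \item per cell line, predicted motifs = perturbed copies of the anchor,
#'     of a core-pool draw (fraction \code{conservationRate}) and of
#'     line-private TFs;
#'   \item motif modules sampling members from the line's motifs, containing
#'     the anchor motif with probability \code{pAnchor};
#'   \item a PPI network with every cofactor-anchor edge, a
#'     \code{cofactorEdgeRate} fraction of co-occurring cofactor-cofactor
#'     edges, and uniform background edges;
#'   \item non-overlapping peaks on a toy two-chromosome genome placed near
#'     the TSSs of each cofactor's "program genes", plus background peaks;
#'   \item gene GO annotations tying each cofactor's program genes to its own
#'     GO terms, so lines sharing more cofactors share more target-gene GO
#'     terms (a planted positive divergence trend).
#' }
#' The \code{truth} slot records every plant: anchor TF, cofactors, per-line
#' motif-to-TF sources, interacting cofactor pairs, per-line cofactor sets,
#' per-line planted conserved fractions, program genes and cofactor GO terms.
#'
#' @param config a [syntheticConfig()].
#' @return a [StudyBundle-class].
#' @examples
#' cfg <- syntheticConfig(nCellLines = 3, librarySize = 20, motifsPerLine = 8,
#'                        nTrueCofactors = 4, corePoolSize = 7, nGenes = 60,
#'                        nModulesPerLine = 6, nGoTerms = 12,
#'                        genesPerCofactor = 5, seed = 11)
#' bundle <- simulateStudy(cfg)
#' cellLines(bundle)
#' @export
simulateStudy <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must come from syntheticConfig()", call. = FALSE)
  cfg <- config
  lines <- sprintf("CL%02d", seq_len(cfg$nCellLines))

  library <- generatePwmLibrary(cfg$librarySize, cfg$widthRange,
                                seed = fanSeed(cfg$seed, 1L))
  tfs <- vapply(library, function(m) tfNames(m)[1], "")
  names(library) <- tfs
  anchorTF <- tfs[1]

  ## planted cofactors and the conserved core pool
  set.seed(fanSeed(cfg$seed, 2L))
  cofactors <- sort(sample(tfs[-1], cfg$nTrueCofactors))
  poolExtra <- sample(setdiff(tfs[-1], cofactors),
                      cfg$corePoolSize - cfg$nTrueCofactors)
  corePool <- c(cofactors, poolExtra)
  coreDraw <- round(cfg$conservationRate * (cfg$motifsPerLine - 1L))
  if (coreDraw > cfg$corePoolSize) coreDraw <- cfg$corePoolSize
  nPriv <- cfg$motifsPerLine - 1L - coreDraw
  ## private TFs come from a global shuffled queue, so they are disjoint
  ## across lines whenever the library is large enough
  privPool <- setdiff(tfs[-1], corePool)
  privQueue <- sample(privPool)
  ## circular similarity gradient: pool TFs at shuffled positions, each line
  ## prefers pool TFs near its own position
  poolPos <- setNames((sample(length(corePool)) - 1) / length(corePool),
                      corePool)
  lineCtr <- setNames((seq_along(lines) - 1) / length(lines), lines)

  ## per-line motif sources: the anchor, a gradient-weighted core-pool draw
  ## and line-private TFs
  set.seed(fanSeed(cfg$seed, 3L))
  sourcesByLine <- list()
  for (line in lines) {
    d <- abs(poolPos - lineCtr[line])
    d <- pmin(d, 1 - d)
    core <- sample(corePool, coreDraw,
                   prob = exp(-0.5 * (d / cfg$lineSimilarityBandwidth)^2) + 1e-9)
    priv <- character()
    if (nPriv > 0L) {
      if (length(privQueue) < nPriv)
        privQueue <- c(privQueue, sample(setdiff(privPool, privQueue)))
      if (length(privQueue) < nPriv)  # library too small for full privacy
        privQueue <- c(privQueue, sample(setdiff(tfs[-1], c(core, privQueue))))
      priv <- privQueue[seq_len(nPriv)]
      privQueue <- privQueue[-seq_len(nPriv)]
    }
    sourcesByLine[[line]] <- c(anchorTF, core, priv)
  }
  ## repair pass: every planted cofactor must carry a motif in >= 1 line
  absent <- setdiff(cofactors, unique(unlist(sourcesByLine)))
  li <- 0L
  for (cf in absent) {
    li <- li %% length(lines) + 1L
    src <- sourcesByLine[[lines[li]]]
    repl <- rev(which(!(src %in% c(anchorTF, cofactors))))[1]
    if (is.na(repl)) next
    sourcesByLine[[lines[li]]][repl] <- cf
  }

  perLineMotifs <- list(); anchorIds <- list(); motifSource <- list()
  for (line in lines) {
    sources <- sourcesByLine[[line]]
    ids <- sprintf("%s_m%02d", line, seq_along(sources))
    perLineMotifs[[line]] <- mapply(function(tf, id)
      perturbPwm(library[[tf]], kappa = cfg$pwmNoise, motifID = id),
      sources, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    names(perLineMotifs[[line]]) <- ids
    anchorIds[[line]] <- ids[1]
    motifSource[[line]] <- setNames(sources, ids)
  }

  ## motif modules: most instantiate a shared cross-line template (TF
  ## composition over the core pool), the rest are line-random sets
  set.seed(fanSeed(cfg$seed, 4L))
  tplSizes <- sample(seq.int(cfg$moduleSizeRange[1], cfg$moduleSizeRange[2]),
                     cfg$nModuleTemplates, replace = TRUE)
  tplAnchor <- runif(cfg$nModuleTemplates) < cfg$pAnchor
  templates <- lapply(seq_len(cfg$nModuleTemplates), function(j) {
    k <- tplSizes[j] - as.integer(tplAnchor[j])
    sample(corePool, min(k, length(corePool)))
  })
  modList <- list()
  for (line in lines) {
    ids <- names(perLineMotifs[[line]])
    others <- setdiff(ids, anchorIds[[line]])
    motifOfTF <- setNames(names(motifSource[[line]]),
                          unname(motifSource[[line]]))
    sizes <- sample(seq.int(cfg$moduleSizeRange[1], cfg$moduleSizeRange[2]),
                    cfg$nModulesPerLine, replace = TRUE)
    withAnchor <- runif(cfg$nModulesPerLine) < cfg$pAnchor
    fromTpl <- runif(cfg$nModulesPerLine) < cfg$sharedModuleRate
    tplPick <- sample.int(cfg$nModuleTemplates, cfg$nModulesPerLine,
                          replace = TRUE)
    members <- lapply(seq_len(cfg$nModulesPerLine), function(j) {
      if (fromTpl[j]) {
        tpl <- templates[[tplPick[j]]]
        core <- unname(motifOfTF[tpl[tpl %in% names(motifOfTF)]])
        size <- tplSizes[tplPick[j]]
        anchored <- tplAnchor[tplPick[j]]
        want <- size - as.integer(anchored)
        if (length(core) > want) core <- core[seq_len(want)]
        fill <- setdiff(others, core)
        if (length(core) < want)
          core <- c(core, sample(fill, want - length(core)))
        out <- if (anchored) c(anchorIds[[line]], core) else core
        if (length(out) < 2L)
          out <- c(out, sample(setdiff(others, out), 2L - length(out)))
        out
      } else if (withAnchor[j]) {
        c(anchorIds[[line]], sample(others, sizes[j] - 1L))
      } else {
        sample(others, sizes[j])
      }
    })
    modList[[line]] <- data.frame(
      module_id = sprintf("%s_mod%02d", line, seq_len(cfg$nModulesPerLine)),
      cell_line = line,
      support = stats::rpois(cfg$nModulesPerLine, 15) + 1L,
      motif_ids = I(members), stringsAsFactors = FALSE)
  }
  modules <- do.call(rbind, modList)
  rownames(modules) <- NULL

  ## TFs whose motifs actually appear in each line's modules, and TF pairs
  ## co-occurring within a module in at least one line
  tfsInModules <- lapply(lines, function(line) {
    ids <- unique(unlist(modules$motif_ids[modules$cell_line == line]))
    unique(unname(motifSource[[line]][ids]))
  })
  names(tfsInModules) <- lines
  coocKeys <- unique(unlist(lapply(seq_len(nrow(modules)), function(i) {
    tfsIn <- unique(unname(
      motifSource[[modules$cell_line[i]]][modules$motif_ids[[i]]]))
    if (length(tfsIn) < 2L) return(character())
    cmb <- combn(sort(tfsIn), 2L)
    pairKey(cmb[1L, ], cmb[2L, ])
  })))

  ## PPI network
  set.seed(fanSeed(cfg$seed, 5L))
  bg <- if (cfg$nBackgroundProteins > 0L)
    sprintf("P%03d", seq_len(cfg$nBackgroundProteins)) else character()
  proteins <- c(tfs, bg)
  flags <- setNames(c(rep(TRUE, length(tfs)), rep(FALSE, length(bg))), proteins)
  edgeA <- rep(anchorTF, length(cofactors)); edgeB <- cofactors
  cofPairs <- if (length(cofactors) >= 2L) combn(cofactors, 2L) else
    matrix(character(), 2L, 0L)
  eligible <- if (ncol(cofPairs))
    pairKey(cofPairs[1L, ], cofPairs[2L, ]) %in% coocKeys else logical()
  kept <- which(eligible & runif(ncol(cofPairs)) < cfg$cofactorEdgeRate)
  edgeA <- c(edgeA, cofPairs[1L, kept]); edgeB <- c(edgeB, cofPairs[2L, kept])
  allPairs <- combn(proteins, 2L)
  bgKeep <- runif(ncol(allPairs)) < cfg$ppiBackgroundDensity
  edgeA <- c(edgeA, allPairs[1L, bgKeep]); edgeB <- c(edgeB, allPairs[2L, bgKeep])
  ppi <- suppressWarnings(PPINetwork(edgeA, edgeB, flags))
  interacting <- data.frame(a = pmin(c(rep(anchorTF, length(cofactors)),
                                       cofPairs[1L, kept]),
                                     c(cofactors, cofPairs[2L, kept])),
                            b = pmax(c(rep(anchorTF, length(cofactors)),
                                       cofPairs[1L, kept]),
                                     c(cofactors, cofPairs[2L, kept])),
                            stringsAsFactors = FALSE)

  ## toy genome, genes, GO terms
  set.seed(fanSeed(cfg$seed, 6L))
  windowSize <- 8000L
  perChrom <- ceiling(cfg$nGenes / 2)
  chromSizes <- c(chr1 = perChrom * windowSize, chr2 = perChrom * windowSize)
  geneIds <- sprintf("G%03d", seq_len(cfg$nGenes))
  chrom <- ifelse(seq_len(cfg$nGenes) <= perChrom, "chr1", "chr2")
  winStart <- (ifelse(chrom == "chr1", seq_len(cfg$nGenes) - 1L,
                      seq_len(cfg$nGenes) - perChrom - 1L)) * windowSize
  tss <- winStart + 3000L + sample.int(2000L, cfg$nGenes, replace = TRUE) - 1L
  annotation <- data.frame(gene_id = geneIds, chrom = chrom, tss = as.integer(tss),
                           strand = sample(c("+", "-"), cfg$nGenes, TRUE),
                           stringsAsFactors = FALSE)
  terms <- sprintf("GO%03d", seq_len(cfg$nGoTerms))
  ## every core-pool TF drives a program: disjoint GO terms and target genes
  nProg <- cfg$corePoolSize
  cofTermIdx <- matrix(sample(cfg$nGoTerms, cfg$termsPerCofactor * nProg),
                       nrow = cfg$termsPerCofactor)
  cofactorTerms <- lapply(seq_len(nProg), function(i) terms[cofTermIdx[, i]])
  names(cofactorTerms) <- corePool
  progIdx <- matrix(sample(cfg$nGenes, cfg$genesPerCofactor * nProg),
                    nrow = cfg$genesPerCofactor)
  programGenes <- lapply(seq_len(nProg), function(i) geneIds[progIdx[, i]])
  names(programGenes) <- corePool
  g2gGene <- character(); g2gTerm <- character()
  for (cf in corePool) {
    g2gGene <- c(g2gGene, rep(programGenes[[cf]],
                              each = length(cofactorTerms[[cf]])))
    g2gTerm <- c(g2gTerm, rep(cofactorTerms[[cf]], length(programGenes[[cf]])))
  }
  ## annotation noise goes to the background (non-program) terms, so the
  ## planted program annotations stay intact
  noisePool <- setdiff(terms, terms[as.vector(cofTermIdx)])
  if (!length(noisePool)) noisePool <- terms
  nNoise <- stats::rpois(cfg$nGenes, 0.4)
  nNoise <- pmin(nNoise, length(noisePool))
  g2gGene <- c(g2gGene, rep(geneIds, nNoise))
  g2gTerm <- c(g2gTerm, unlist(lapply(nNoise, function(k)
    if (k > 0) sample(noisePool, k) else character())))
  gene2go <- unique(data.frame(gene_id = g2gGene, term_id = g2gTerm,
                               stringsAsFactors = FALSE))
  rownames(gene2go) <- NULL

  ## peaks: program peaks near cofactor program-gene TSSs + background peaks,
  ## one peak per gene window per line, so peaks never overlap within a line
  set.seed(fanSeed(cfg$seed, 7L))
  geneWin <- setNames(winStart, geneIds)
  geneChrom <- setNames(chrom, geneIds)
  geneTss <- setNames(as.integer(tss), geneIds)
  perLineCofactors <- lapply(lines, function(line)
    intersect(unname(motifSource[[line]]), cofactors))
  names(perLineCofactors) <- lines
  perLinePool <- lapply(lines, function(line)
    intersect(unname(motifSource[[line]]), corePool))
  names(perLinePool) <- lines
  pk <- list()
  for (line in lines) {
    target <- unlist(programGenes[perLinePool[[line]]], use.names = FALSE)
    free <- setdiff(geneIds, target)
    bgGenes <- sample(free, min(cfg$backgroundPeaksPerLine, length(free)))
    genes <- c(target, bgGenes)
    lens <- sample(seq.int(cfg$peakLenRange[1], cfg$peakLenRange[2]),
                   length(genes), replace = TRUE)
    isTarget <- c(rep(TRUE, length(target)), rep(FALSE, length(bgGenes)))
    ctr <- ifelse(isTarget,
                  geneTss[genes] + sample(-200:200, length(genes), TRUE),
                  geneWin[genes] + sample.int(windowSize - 700L, length(genes),
                                              replace = TRUE) + 350L)
    s0 <- pmax(geneWin[genes], ctr - lens %/% 2L)
    e0 <- pmin(geneWin[genes] + windowSize, s0 + lens)
    pk[[line]] <- GenomicRanges::GRanges(
      seqnames = geneChrom[genes],
      ranges = IRanges::IRanges(start = as.integer(s0) + 1L,
                                end = as.integer(e0)),
      cell_line = line,
      peak_id = sprintf("%s_p%03d", line, seq_along(genes)))
  }
  peaks <- suppressWarnings(do.call(c, unname(pk)))
  GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
  if (GenomeInfoDb_ok)
    GenomeInfoDb::seqlengths(peaks) <- chromSizes[GenomeInfoDb::seqlevels(peaks)]

  ## planted conserved fraction per line: motifs whose source TF recurs in
  ## at least one other line (the anchor always does)
  conservedFraction <- vapply(lines, function(line) {
    src <- motifSource[[line]]
    othersTFs <- unique(unlist(motifSource[setdiff(lines, line)]))
    mean(unname(src) %in% othersTFs)
  }, 0)

  truth <- list(anchorTF = anchorTF, cofactors = cofactors,
                corePool = corePool, motifSource = motifSource,
                interactingPairs = interacting,
                perLineCofactors = perLineCofactors,
                perLinePool = perLinePool,
                tfsInModules = tfsInModules,
                conservedFraction = conservedFraction,
                programGenes = programGenes, cofactorTerms = cofactorTerms,
                chromSizes = chromSizes)

  new("StudyBundle", knownLibrary = library, perLineMotifs = perLineMotifs,
      modules = modules, anchorMotifIds = anchorIds, peaks = peaks, ppi = ppi,
      annotation = annotation, gene2go = gene2go, truth = truth,
      config = unclass(cfg))
}

#' Simulate a sequence-by-motif occurrence matrix
#'
#' Independent Bernoulli occurrences per motif, with an optional planted
#' co-occurring set: a fraction \code{coOccur$rate} of sequences gets every
#' member of \code{coOccur$members} set to TRUE. Used to exercise
#' [cooccurrencePvalue()].
#'
#' @param nSeq number of sequences (rows).
#' @param marginals named numeric vector of per-motif occurrence
#'   probabilities (columns).
#' @param coOccur optional list(members = character ids, rate = probability).
#' @param seed optional integer seed.
#' @return logical matrix, \code{nSeq} x \code{length(marginals)}.
#' @export
simulateOccurrence <- function(nSeq, marginals, coOccur = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(assertCount(seed, "seed"))
  stopifnot(!is.null(names(marginals)), all(marginals >= 0 & marginals <= 1))
  occ <- matrix(runif(nSeq * length(marginals)) < rep(marginals, each = nSeq),
                nrow = nSeq, dimnames = list(NULL, names(marginals)))
  if (!is.null(coOccur)) {
    hit <- runif(nSeq) < coOccur$rate
    occ[hit, coOccur$members] <- TRUE
  }
  occ
}
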