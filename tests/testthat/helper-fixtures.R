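# shared fixtures, built once per test run

# a deterministic PWM from a consensus string, optionally softened
consensusPwm <- function(id, consensus, soft = 0, source = "known",
                         tfNames = character()) {
  base <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(soft / 3, 4L, length(base))
  m[cbind(base, seq_along(base))] <- 1 - soft
  rownames(m) <- c("A", "C", "G", "T")
  MotifMatrix(id, m, tfNames = tfNames, source = source, normalize = FALSE)
}

uniformPwm <- function(id, width) {
  MotifMatrix(id, matrix(0.25, 4L, width), source = "known", normalize = FALSE)
}

# small library + calibration reused across similarity/cofactor tests
smallLib <- generatePwmLibrary(20L, widthRange = c(6L, 10L), seed = 101L)
names(smallLib) <- vapply(smallLib, function(m) tfNames(m)[1], "")
smallCal <- calibrateNull(smallLib, nNull = 1000L, seed = 102L)

# a small synthetic study for structural tests (fast to simulate)
tinyConfig <- function(seed = 301L, ...) {
  args <- list(nCellLines = 4L, librarySize = 30L, motifsPerLine = 10L,
               nTrueCofactors = 5L, corePoolSize = 10L, nModulesPerLine = 8L,
               moduleSizeRange = c(2L, 4L), nGenes = 120L, nGoTerms = 20L,
               genesPerCofactor = 6L, nBackgroundProteins = 20L,
               backgroundPeaksPerLine = 20L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticConfig, args)
}
tinyBundle <- simulateStudy(tinyConfig())
tinyCal <- calibrateNull(knownLibrary(tinyBundle), nNull = 1000L, seed = 302L)

# brute-force PWM alignment scorer, independent of the package's band-sum
# implementation: explicit double loop over offsets/orientations using cor()
naiveAlignScore <- function(a, b) {
  pa <- motifProfile(a)
  best <- -Inf
  for (orient in c("+", "-")) {
    pb <- if (orient == "+") motifProfile(b)
      else motifProfile(reverseComplement(b))
    wa <- ncol(pa); wb <- ncol(pb)
    minOv <- min(4, wa, wb)
    for (o in -(wb - minOv):(wa - minOv)) {
      ia <- (max(0, o) + 1):min(wa, wb + o)
      tot <- 0
      for (i in ia) {
        x <- pa[, i]; y <- pb[, i - o]
        tot <- tot + if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
      }
      best <- max(best, tot / max(wa, wb))
    }
  }
  best
}

# enumeration oracle for the hypergeometric upper tail: all C(y2, x2) draws
# of x2 items from y2, counting draws with >= x1 items among the y1 marked
enumPhyperTail <- function(x1, y1, x2, y2) {
  if (x2 == 0L) return(as.numeric(x1 <= 0L))
  draws <- utils::combn(y2, x2)
  mean(colSums(draws <= y1) >= x1)
}
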