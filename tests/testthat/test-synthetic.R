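test_that("PWM library generation is seeded and well-formed", {
  l1 <- generatePwmLibrary(10L, c(6L, 12L), seed = 5L)
  l2 <- generatePwmLibrary(10L, c(6L, 12L), seed = 5L)
  expect_identical(lapply(l1, motifProfile), lapply(l2, motifProfile))
  one <- generatePwmLibrary(1L, c(6L, 8L), seed = 6L)
  expect_length(one, 1L)
  expect_equal(colSums(motifProfile(one[[1]])), rep(1, motifWidth(one[[1]])))
  expect_error(generatePwmLibrary(5L, c(3L, 8L), 1L), ">= 4")
})

test_that("library motifs are more similar to themselves than to each other", {
  lib <- generatePwmLibrary(12L, seed = 1L)
  selfScores <- vapply(lib, function(m) alignScore(m, m)$score, 0)
  pairScores <- c()
  for (i in 1:11) for (j in (i + 1):12)
    pairScores <- c(pairScores, alignScore(lib[[i]], lib[[j]])$score)
  expect_lt(mean(pairScores), mean(selfScores))
})

test_that("PWM perturbation concentrates around the source at high kappa", {
  src <- smallLib[[2]]
  p1 <- perturbPwm(src, kappa = 50, seed = 31L)
  p2 <- perturbPwm(src, kappa = 50, seed = 31L)
  expect_identical(motifProfile(p1), motifProfile(p2))
  expect_equal(motifWidth(p1), motifWidth(src))
  hi <- perturbPwm(src, kappa = 1e4, seed = 32L)
  expect_lt(max(abs(motifProfile(hi) - motifProfile(src))), 0.05)
  expect_error(perturbPwm(src, kappa = 0), "kappa")
})

test_that("infeasible synthetic configurations are rejected", {
  expect_error(tinyConfig(motifsPerLine = 40L), "librarySize")
  expect_error(tinyConfig(moduleSizeRange = c(1L, 3L)), "module sizes")
  expect_error(tinyConfig(conservationRate = 1.4), "probabilities")
  expect_error(tinyConfig(corePoolSize = 3L), "corePoolSize")
  expect_error(tinyConfig(widthRange = c(3L, 8L)), ">= 4")
  expect_error(tinyConfig(pwmNoise = -1), "pwmNoise")
})

test_that("study simulation is deterministic in the seed", {
  b1 <- simulateStudy(tinyConfig(seed = 77L))
  b2 <- simulateStudy(tinyConfig(seed = 77L))
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudyBundle(b1, d1); writeStudyBundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("full conservation rate plants every core motif in all lines", {
  cfg <- tinyConfig(conservationRate = 1, corePoolSize = 9L, seed = 9L)
  b <- simulateStudy(cfg)
  tr <- studyTruth(b)
  expect_true(all(unlist(tr$conservedFraction) == 1))
  cal <- calibrateNull(knownLibrary(b), 1000L, seed = 91L)
  cons <- motifConservation(perLineMotifs(b), cal, thetaCross = 1e-8)
  expect_true(all(cons == 1))
})

test_that("disjoint cores leave no planted cross-line correspondence", {
  # two lines, no conserved core: privates come from a global queue, so the
  # two lines' motif sources are disjoint apart from the anchor
  cfg <- tinyConfig(nCellLines = 2L, conservationRate = 0, seed = 13L,
                    librarySize = 30L, motifsPerLine = 10L)
  b <- simulateStudy(cfg)
  src <- studyTruth(b)$motifSource
  shared <- intersect(unname(src[[1]][-1]), unname(src[[2]][-1]))
  expect_length(shared, 0L)
  fr <- unlist(studyTruth(b)$conservedFraction)
  expect_equal(unname(fr), rep(1 / 10, 2))  # only the anchor recurs
})

test_that("planted truth is internally consistent", {
  tr <- studyTruth(tinyBundle)
  # every planted interacting pair has both TFs in a common line's modules
  for (i in seq_len(nrow(tr$interactingPairs))) {
    a <- tr$interactingPairs$a[i]; b <- tr$interactingPairs$b[i]
    common <- any(vapply(tr$tfsInModules, function(s) all(c(a, b) %in% s), TRUE))
    expect_true(common, info = paste(a, b))
  }
  # every planted cofactor carries a motif somewhere
  carried <- unique(unlist(lapply(tr$motifSource, unname)))
  expect_true(all(tr$cofactors %in% carried))
  # anchor-cofactor edges are all in the PPI
  keys <- paste(ppiEdges(studyPpi(tinyBundle))$a,
                ppiEdges(studyPpi(tinyBundle))$b)
  for (cf in tr$cofactors) {
    e <- sort(c(tr$anchorTF, cf))
    expect_true(paste(e[1], e[2]) %in% keys, info = cf)
  }
})

test_that("bundles round-trip through the on-disk formats", {
  d <- withr::local_tempdir()
  writeStudyBundle(tinyBundle, d)
  back <- readStudyBundle(d)
  expect_identical(cellLines(back), cellLines(tinyBundle))
  expect_identical(studyModules(back)$module_id,
                   studyModules(tinyBundle)$module_id)
  expect_identical(studyModules(back)$motif_ids,
                   studyModules(tinyBundle)$motif_ids)
  expect_identical(ppiEdges(studyPpi(back)), ppiEdges(studyPpi(tinyBundle)))
  expect_identical(geneAnnotation(back), geneAnnotation(tinyBundle))
  expect_identical(geneGoMap(back), geneGoMap(tinyBundle))
  expect_equal(GenomicRanges::start(studyPeaks(back)),
               GenomicRanges::start(studyPeaks(tinyBundle)))
  for (line in cellLines(tinyBundle)) {
    m1 <- perLineMotifs(tinyBundle)[[line]]
    m2 <- perLineMotifs(back)[[line]]
    expect_identical(vapply(m2, motifID, ""), vapply(m1, motifID, ""))
    expect_lt(max(abs(motifProfile(m2[[1]]) - motifProfile(m1[[1]]))), 1e-9)
  }
  expect_identical(sort(studyTruth(back)$cofactors),
                   sort(studyTruth(tinyBundle)$cofactors))
})

test_that("occurrence matrices honour marginals and planted co-occurrence", {
  occ <- simulateOccurrence(5000L, c(m1 = 0.3, m2 = 0.6), seed = 41L)
  expect_equal(dim(occ), c(5000L, 2L))
  expect_lt(abs(mean(occ[, "m1"]) - 0.3), 0.03)
  occ2 <- simulateOccurrence(5000L, c(m1 = 0.1, m2 = 0.1),
                             coOccur = list(members = c("m1", "m2"),
                                            rate = 0.2),
                             seed = 42L)
  both <- mean(occ2[, 1] & occ2[, 2])
  expect_gt(both, 0.15)  # far above the 0.01 independence rate
  expect_identical(occ, simulateOccurrence(5000L, c(m1 = 0.3, m2 = 0.6),
                                           seed = 41L))
})
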