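test_that("module pairs are all size-2 subsets, deduplicated", {
  p <- modulePairs(list(c("a", "b", "c")))
  expect_equal(nrow(p), 3L)
  expect_setequal(paste(p$a, p$b), c("a b", "a c", "b c"))
  expect_equal(nrow(modulePairs(list(c("a", "b"), c("b", "a")))), 1L)
  expect_equal(nrow(modulePairs(list())), 0L)
})

# two toy lines: L1 has exact copies of L2's motifs -> full conservation;
# L3 has unrelated motifs -> zero conservation
.twoLineMotifs <- function() {
  base <- smallLib[1:4]
  l1 <- lapply(seq_along(base), function(i)
    MotifMatrix(paste0("L1_m", i), motifProfile(base[[i]]),
                source = "predicted", normalize = FALSE))
  l2 <- lapply(seq_along(base), function(i)
    MotifMatrix(paste0("L2_m", i), motifProfile(base[[i]]),
                source = "predicted", normalize = FALSE))
  other <- smallLib[11:14]
  l3 <- lapply(seq_along(other), function(i)
    MotifMatrix(paste0("L3_m", i), motifProfile(other[[i]]),
                source = "predicted", normalize = FALSE))
  list(L1 = l1, L2 = l2, L3 = l3)
}

test_that("motif conservation finds identical motifs and misses unrelated ones", {
  motifs <- .twoLineMotifs()
  cons <- motifConservation(motifs[c("L1", "L2")], smallCal, thetaCross = 1e-8)
  expect_equal(unname(cons), c(1, 1))
  cons3 <- motifConservation(motifs, smallCal, thetaCross = 1e-8)
  expect_equal(unname(cons3["L3"]), 0)
  expect_error(motifConservation(motifs["L1"], smallCal), ">= 2")
})

test_that("pair conservation matches pairs in either orientation", {
  motifs <- .twoLineMotifs()[c("L1", "L2")]
  simRel <- crossLineSimilarity(motifs, smallCal, thetaCross = 1e-8)
  # identical module sets -> full conservation
  pairs <- list(L1 = modulePairs(list(c("L1_m1", "L1_m2"), c("L1_m3", "L1_m4"))),
                L2 = modulePairs(list(c("L2_m1", "L2_m2"), c("L2_m3", "L2_m4"))))
  pc <- pairConservation(pairs, simRel)
  expect_equal(pc$overall, 1)
  expect_equal(unname(pc$perLine), c(1, 1))
  # cross-orientation: (m1, m2) in L1 vs (m2, m1) in L2 is the same pair
  pairs2 <- list(L1 = data.frame(a = "L1_m1", b = "L1_m2"),
                 L2 = data.frame(a = "L2_m1", b = "L2_m2"))
  expect_equal(pairConservation(pairs2, simRel)$overall, 1)
  # unmatched pair
  pairs3 <- list(L1 = data.frame(a = "L1_m1", b = "L1_m2"),
                 L2 = data.frame(a = "L2_m3", b = "L2_m4"))
  expect_equal(pairConservation(pairs3, simRel)$overall, 0)
  # single line: zero with a warning
  expect_warning(pc1 <- pairConservation(pairs["L1"], simRel), "single")
  expect_equal(pc1$overall, 0)
})

test_that("conservation is invariant to motif relabeling and line order", {
  motifs <- perLineMotifs(tinyBundle)
  simRel <- crossLineSimilarity(motifs, tinyCal, thetaCross = 1e-8)
  cons <- motifConservation(motifs, simRel = simRel)
  # permute line order
  perm <- rev(names(motifs))
  simRelP <- crossLineSimilarity(motifs[perm], tinyCal, thetaCross = 1e-8)
  consP <- motifConservation(motifs[perm], simRel = simRelP)
  expect_equal(consP[names(cons)], cons)
  # relabel motif ids
  relab <- lapply(motifs, function(ms) lapply(ms, function(m)
    MotifMatrix(paste0("X", motifID(m)), motifProfile(m),
                source = "predicted", normalize = FALSE)))
  simRelR <- crossLineSimilarity(relab, tinyCal, thetaCross = 1e-8)
  expect_equal(unname(motifConservation(relab, simRel = simRelR)),
               unname(cons))
})

test_that("loosening the similarity threshold never lowers conservation", {
  motifs <- perLineMotifs(tinyBundle)
  consTight <- motifConservation(motifs, tinyCal, thetaCross = 1e-8)
  consLoose <- motifConservation(motifs, tinyCal, thetaCross = 1e-4)
  expect_true(all(consLoose >= consTight))
})

test_that("the random-module null is reproducible and anchored to the observed", {
  motifs <- perLineMotifs(tinyBundle)
  simRel <- crossLineSimilarity(motifs, tinyCal, thetaCross = 1e-8)
  mods <- studyModules(tinyBundle)
  n1 <- randomPairNull(mods, motifs, R = 99L, seed = 51L, simRel = simRel)
  n2 <- randomPairNull(mods, motifs, R = 99L, seed = 51L, simRel = simRel)
  expect_identical(n1$nullFractions, n2$nullFractions)
  expect_length(n1$nullFractions, 99L)
  # the observed statistic equals pairConservation's overall fraction
  perLinePairs <- lapply(cellLines(tinyBundle), function(line)
    modulePairs(mods$motif_ids[mods$cell_line == line]))
  names(perLinePairs) <- cellLines(tinyBundle)
  expect_equal(n1$observed, pairConservation(perLinePairs, simRel)$overall)
  expect_true(n1$pEmpirical > 0 && n1$pEmpirical <= 1)
  # module larger than the motif list is rejected
  badMods <- mods[1, ]
  badMods$motif_ids <- I(list(sprintf("zz%d", 1:50)))
  badMods$cell_line <- cellLines(tinyBundle)[1]
  expect_error(randomPairNull(badMods, motifs, R = 99L, seed = 1L,
                              simRel = simRel), "larger")
})

test_that("co-occurrence p-values equal the exact binomial tail", {
  # 10 of 100 sequences carry both motifs, marginals 0.1 each
  occ <- matrix(FALSE, 100L, 2L, dimnames = list(NULL, c("m1", "m2")))
  occ[1:10, ] <- TRUE
  p <- cooccurrencePvalue(occ, c("m1", "m2"))
  # independent oracle: direct summation of the binomial upper tail
  p0 <- 0.1 * 0.1
  direct <- sum(vapply(10:100, function(k)
    choose(100, k) * p0^k * (1 - p0)^(100 - k), 0))
  expect_equal(p, direct, tolerance = 1e-12)
  # no sequence with all members: the tail from zero is certain
  occ0 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2L, 2L,
                 dimnames = list(NULL, c("m1", "m2")))
  expect_equal(cooccurrencePvalue(occ0, c("m1", "m2")), 1)
  # zero marginal
  occz <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2L, 2L,
                 dimnames = list(NULL, c("m1", "m2")))
  expect_warning(pz <- cooccurrencePvalue(occz, c("m1", "m2")), "zero marginal")
  expect_equal(pz, 1)
  expect_error(cooccurrencePvalue(occ, "m1"), ">= 2")
  expect_error(cooccurrencePvalue(occ, c("m1", "nope")), "columns")
})

test_that("co-occurrence p-values are near-uniform under independence", {
  set.seed(61)
  ps <- vapply(1:500, function(i) {
    occ <- simulateOccurrence(60L, c(a = 0.4, b = 0.5, c = 0.45))
    cooccurrencePvalue(occ, c("a", "b", "c"))
  }, 0)
  # discrete statistic: check super-uniformity plus non-degeneracy rather
  # than exact uniformity
  expect_gt(suppressWarnings(
    stats::ks.test(ps, "punif", alternative = "greater")$p.value), 0.01)
  expect_gt(mean(ps < 0.5), 0.2)
})
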