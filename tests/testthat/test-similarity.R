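test_that("reverse complement swaps bases and mirrors positions", {
  # A at position 1 of width 3+1 reappears as T at the last position
  m <- consensusPwm("m", "ACGG")
  rc <- reverseComplement(m)
  expect_equal(unname(motifProfile(rc)["T", 4]), 1)
  expect_equal(unname(motifProfile(rc)["C", 1]), 1)  # G complement
  # involution
  expect_equal(motifProfile(reverseComplement(rc)), motifProfile(m))
  # palindromic uniform matrix is fixed
  u <- uniformPwm("u", 6)
  expect_equal(motifProfile(reverseComplement(u)), motifProfile(u))
})

test_that("alignment score is 1 for self-matches and RC matches", {
  m <- smallLib[[3]]
  s <- alignScore(m, m)
  expect_equal(s$score, 1.0)
  expect_equal(s$offset, 0L)
  expect_identical(s$orientation, "+")
  s2 <- alignScore(m, reverseComplement(m))
  expect_equal(s2$score, 1.0)
  expect_identical(s2$orientation, "-")
})

test_that("a motif embedded in uniform padding scores overlap/width", {
  core <- consensusPwm("core", "ACGTAC", soft = 0.06)
  padded <- motifProfile(uniformPwm("p", 12))
  padded[, 3:8] <- motifProfile(core)
  emb <- MotifMatrix("emb", padded, source = "known", normalize = FALSE)
  s <- alignScore(emb, core)
  expect_equal(s$score, 6 / 12, tolerance = 1e-12)
  expect_equal(s$offset, 2L)  # core sits at columns 3-8 (0-based start 2)
})

test_that("alignment agrees with a brute-force scorer and is symmetric", {
  set.seed(42)
  for (i in 1:12) {
    a <- smallLib[[sample(length(smallLib), 1)]]
    b <- smallLib[[sample(length(smallLib), 1)]]
    fast <- alignScore(a, b)$score
    expect_equal(fast, naiveAlignScore(a, b), tolerance = 1e-12)
    expect_equal(fast, alignScore(b, a)$score, tolerance = 1e-12)
  }
})

test_that("null calibration is deterministic with informative-library scores", {
  c1 <- calibrateNull(smallLib, nNull = 1000L, seed = 7L)
  c2 <- calibrateNull(smallLib, nNull = 1000L, seed = 7L)
  expect_identical(c1@nullScores, c2@nullScores)
  expect_length(c1@nullScores, 1000L)
  expect_lt(mean(c1@nullScores), 0.5)
  expect_error(calibrateNull(smallLib[1], 1000L, 1L), "at least 2")
  expect_error(calibrateNull(smallLib, 500L, 1L), "nNull")
})

test_that("E-values follow the empirical formula at the extremes", {
  calib <- smallCal
  L <- calib@librarySize
  n <- calib@nNull
  # above every null score
  expect_equal(motifEvalue(max(calib@nullScores) + 0.1, calib),
               L * 1 / (n + 1))
  # below every null score
  expect_equal(motifEvalue(min(calib@nullScores) - 0.1, calib), L)
  # monotone non-increasing in score, both methods
  grid <- seq(-1, 1.2, length.out = 241)
  for (meth in c("empirical", "tail")) {
    ev <- motifEvalue(grid, calib, method = meth)
    expect_true(all(diff(ev) <= 1e-12))
    expect_true(all(ev > 0))
  }
  # the tail method only drops below the empirical floor past all null scores
  ev <- motifEvalue(grid, calib, method = "tail")
  expect_true(all(ev[grid < max(calib@nullScores)] >=
                    L / (n + 1) - 1e-12))
})

test_that("E-value tails are calibrated for null queries", {
  # queries generated under the calibration null itself: the fraction with
  # E < t * librarySize must match t within 3 binomial SDs
  set.seed(11)
  nulls <- calibrateNull(smallLib, nNull = 1000L, seed = 12L)
  scores <- calibrateNull(smallLib, nNull = 1000L, seed = 13L)@nullScores
  ev <- motifEvalue(scores, nulls)
  L <- nulls@librarySize
  for (t in c(0.01, 0.05)) {
    frac <- mean(ev < t * L)
    expect_lt(abs(frac - t), 3 * sqrt(t * (1 - t) / length(scores)) + 1e-3)
  }
})

test_that("library matching returns the source motif first", {
  q <- smallLib[[9]]
  hits <- matchKnown(q, smallLib, smallCal, maxK = 5L, cutoff = Inf,
                     filter = FALSE)
  expect_identical(hits$target_id[1], motifID(smallLib[[9]]))
  expect_equal(nrow(hits), 5L)
  expect_true(!is.unsorted(hits$evalue))

  # perturbed copies still find their source in the top five
  set.seed(21)
  top5 <- vapply(seq_along(smallLib), function(i) {
    p <- perturbPwm(smallLib[[i]], kappa = 50, motifID = "q")
    h <- matchKnown(p, smallLib, smallCal, maxK = 5L, cutoff = Inf,
                    filter = FALSE)
    motifID(smallLib[[i]]) %in% h$target_id
  }, TRUE)
  expect_gte(mean(top5), 0.95)
  expect_error(matchKnown(q, list(), smallCal), "empty")
})
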