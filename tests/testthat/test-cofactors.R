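test_that("hypergeometric tail matches enumeration and stats::phyper", {
  # worked example: 3 equally likely positions for the second marked item
  expect_equal(phyperTail(1, 2, 2, 4), 5 / 6, tolerance = 1e-12)
  expect_equal(phyperTail(1, 2, 2, 4), enumPhyperTail(1, 2, 2, 4),
               tolerance = 1e-12)
  # tail from zero is the total mass
  expect_equal(phyperTail(0, 3, 2, 6), 1)
  expect_equal(phyperTail(0, 0, 0, 0), 1)
  # monotone non-increasing in x1
  vals <- vapply(0:4, function(x1) phyperTail(x1, 4, 4, 10), 0)
  expect_true(all(diff(vals) <= 0))
  # random instances against the standard upper tail
  set.seed(71)
  for (i in 1:200) {
    y2 <- sample(0:80, 1); y1 <- sample(0:y2, 1); x2 <- sample(0:y2, 1)
    x1 <- sample(0:(min(y1, x2) + 1), 1)
    expect_equal(phyperTail(x1, y1, x2, y2),
                 stats::phyper(x1 - 1, y1, y2 - y1, x2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(phyperTail(1, 5, 2, 4), "y1 <= y2")
  expect_error(phyperTail(-1, 2, 2, 4), "non-negative")
})

test_that("direct and indirect TF pairs are split disjointly", {
  # single TF-TF edge
  s <- splitDirectIndirect(PPINetwork("A", "B", c(A = TRUE, B = TRUE)))
  expect_equal(nrow(s$direct), 1L)
  expect_equal(nrow(s$indirect), 0L)
  # two TFs through a non-TF bridge
  s2 <- splitDirectIndirect(PPINetwork(c("A", "B"), c("C", "C"),
                                       c(A = TRUE, B = TRUE, C = FALSE)))
  expect_equal(nrow(s2$direct), 0L)
  expect_equal(paste(s2$indirect$a, s2$indirect$b), "A B")
  # triangle of TFs: every pair is direct, none indirect (exclusion rule)
  s3 <- splitDirectIndirect(PPINetwork(c("A", "A", "B"), c("B", "C", "C"),
                                       c(A = TRUE, B = TRUE, C = TRUE)))
  expect_equal(nrow(s3$direct), 3L)
  expect_equal(nrow(s3$indirect), 0L)
  # brute force over all length-2 paths on a random graph
  set.seed(72)
  prot <- paste0("P", 1:12)
  flags <- setNames(runif(12) < 0.5, prot)
  pairs <- t(utils::combn(prot, 2))
  keep <- runif(nrow(pairs)) < 0.3
  net <- PPINetwork(pairs[keep, 1], pairs[keep, 2], flags)
  s4 <- splitDirectIndirect(net)
  e <- ppiEdges(net)
  adj <- lapply(setNames(prot, prot), function(p)
    c(e$b[e$a == p], e$a[e$b == p]))
  expected <- character()
  for (p in prot) {
    tf <- intersect(adj[[p]], prot[flags])
    if (length(tf) >= 2) {
      cmb <- utils::combn(sort(tf), 2)
      expected <- c(expected, paste(cmb[1, ], cmb[2, ]))
    }
  }
  directKeys <- paste(s4$direct$a, s4$direct$b)
  expected <- setdiff(unique(expected), directKeys)
  expect_setequal(paste(s4$indirect$a, s4$indirect$b), expected)
})

test_that("pair enrichment follows the m/n/M/N hypergeometric", {
  pred <- data.frame(a = "A", b = "B")
  known <- data.frame(a = "A", b = "B")
  r <- pairEnrichment(pred, known, N = 3)
  expect_equal(r$n, 2L); expect_equal(r$m, 1L)
  expect_equal(r$pValue, 1 / 3, tolerance = 1e-12)
  # nothing known among predictions: certain event
  r0 <- pairEnrichment(pred, data.frame(a = "C", b = "D"), N = 5)
  expect_equal(r0$m, 0L)
  expect_equal(r0$pValue, 1)
  expect_warning(r1 <- pairEnrichment(data.frame(a = character(),
                                                 b = character()),
                                      known, N = 4), "fewer than 2")
  expect_equal(r1$pValue, 1)
})

test_that("cofactor assignment maps motifs to their source TFs", {
  motifs <- list(LX = list(
    MotifMatrix("LX_m1", motifProfile(smallLib[[4]]), source = "predicted",
                normalize = FALSE),
    MotifMatrix("LX_m2", motifProfile(smallLib[[8]]), source = "predicted",
                normalize = FALSE)))
  top1 <- assignCofactors(motifs, smallLib, smallCal, mode = "top1")
  expect_equal(nrow(top1), 2L)
  expect_setequal(top1$tf_name, c(tfNames(smallLib[[4]]), tfNames(smallLib[[8]])))
  top5 <- assignCofactors(motifs, smallLib, smallCal, mode = "top5")
  # top-5 assignments are a superset of top-1 per motif
  for (id in top1$motif_id)
    expect_true(all(top1$tf_name[top1$motif_id == id] %in%
                      top5$tf_name[top5$motif_id == id]))
})

test_that("anchor cofactors require co-occurrence with the anchor motif", {
  mods <- data.frame(module_id = c("M1", "M2"), cell_line = "LX",
                     support = c(3L, 3L), stringsAsFactors = FALSE)
  mods$motif_ids <- I(list(c("anc", "m1"), c("m2", "m3")))
  asg <- data.frame(motif_id = c("m1", "m2", "m3"), cell_line = "LX",
                    tf_name = c("TF_X", "TF_Y", "TF_Z"), evalue = 1e-8,
                    stringsAsFactors = FALSE)
  got <- anchorCofactors(mods, asg, list(LX = "anc"))
  expect_identical(got, "TF_X")  # TF_Y/TF_Z only in anchor-free modules
  expect_warning(none <- anchorCofactors(mods, asg, list(LX = character())),
                 "no anchor")
  expect_identical(none, character())
})

test_that("motif pairs expand to cross-product TF pairs", {
  mp <- data.frame(a = "m1", b = "m2")
  asg <- data.frame(motif_id = c("m1", "m1", "m2"), cell_line = "LX",
                    tf_name = c("T1", "T2", "T1"), evalue = 1e-8,
                    stringsAsFactors = FALSE)
  cp <- cofactorPairs(mp, asg)
  # (T1,T1) dropped as a self-pair; (T2,T1) kept once
  expect_equal(paste(cp$a, cp$b), "T1 T2")
})

test_that("cofactor ranking scores mean -log10 E-value times line count", {
  mk <- function(tf, lines, ev) data.frame(
    motif_id = paste0(lines, "_m"), cell_line = lines, tf_name = tf,
    evalue = ev, stringsAsFactors = FALSE)
  asg <- rbind(mk("T_cut", c("c1", "c2", "c3"), 1e-5),
               mk("T_one", "c1", 1e-8),
               mk("T_two", c("c1", "c2"), c(1e-4, 1e-6)))
  r <- rankCofactors(asg, tau = 15)
  row <- function(tf) r[r$tf_name == tf, ]
  # mean E-value 1e-5 in 3 lines scores exactly the cutoff and does not pass
  expect_equal(row("T_cut")$score, 15)
  expect_false(row("T_cut")$passes_cutoff)
  expect_equal(row("T_one")$score, 8)
  expect_equal(row("T_two")$score, 10)  # mean(4, 6) * 2
  # invariance to cell-line order
  r2 <- rankCofactors(asg[rev(seq_len(nrow(asg))), ], tau = 15)
  expect_equal(r2, r)
  # within a line, the best (smallest) E-value of a TF wins
  asg3 <- rbind(mk("T_dup", "c1", 1e-2), mk("T_dup", "c1", 1e-6))
  expect_equal(rankCofactors(asg3)$score, 6)
})

test_that("recovery percentages are printed-table arithmetic", {
  expect_equal(recoveryStats(paste0("x", 1:21), paste0("x", 1:29))$percent, 72.4)
  expect_equal(recoveryStats(paste0("x", 1:15), paste0("x", 1:20))$percent, 75.0)
  r <- recoveryStats(character(), c("a", "b"))
  expect_equal(r$percent, 0)
  expect_setequal(r$missed, c("a", "b"))
  expect_error(recoveryStats("a", character()), "empty")
})
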