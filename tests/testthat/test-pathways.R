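test_that("GO enrichment reproduces exact hypergeometric tails", {
  universe <- sprintf("g%03d", 1:100)
  g2g <- data.frame(gene_id = universe[1:5], term_id = "T_hit",
                    stringsAsFactors = FALSE)
  # study = exactly the term's genes: minimal attainable tail
  enr <- goEnrichment(universe[1:5], g2g, universe)
  expect_equal(enr$p, 1 / choose(100, 5), tolerance = 1e-12)
  expect_lt(enr$p, 1e-3)
  expect_true(enr$enriched)
  # one hit out of ten studied when ten annotated: about the expectation
  g2g2 <- data.frame(gene_id = universe[1:10], term_id = "T_bg",
                     stringsAsFactors = FALSE)
  enr2 <- goEnrichment(universe[10:19], g2g2, universe)  # k = 1
  expect_gt(enr2$p, 0.05)
  expect_equal(enr2$p, phyperTail(1, 10, 10, 100), tolerance = 1e-12)
  expect_error(goEnrichment("g001", g2g, character()), "empty")
  expect_error(goEnrichment("nope", g2g, universe), "subset")
})

test_that("BH adjustment scales the smallest p by the number of tested terms", {
  universe <- sprintf("g%03d", 1:60)
  g2g <- rbind(
    data.frame(gene_id = universe[1:4], term_id = "T1"),
    data.frame(gene_id = universe[5:20], term_id = "T2"),
    data.frame(gene_id = universe[c(1, 21:30)], term_id = "T3"))
  enr <- goEnrichment(universe[1:6], g2g, universe)
  Ttested <- nrow(enr)
  expect_equal(enr$q[1], min(enr$p[1] * Ttested / 1, 1))
  expect_true(all(enr$q >= enr$p))
})

test_that("GO enrichment p-values are uniform under random study draws", {
  set.seed(81)
  universe <- sprintf("g%03d", 1:80)
  g2g <- data.frame(gene_id = sample(universe, 30), term_id = "T1",
                    stringsAsFactors = FALSE)
  ps <- replicate(500, {
    enr <- goEnrichment(sample(universe, 20), g2g, universe)
    if (nrow(enr)) enr$p[1] else 1
  })
  expect_gt(suppressWarnings(
    stats::ks.test(ps, "punif", alternative = "greater")$p.value), 0.01)
})

test_that("set distances follow the Jaccard definition", {
  expect_equal(setDistance(c("a", "b"), c("a", "b")), 0)
  expect_equal(setDistance(c("a", "b"), c("c", "d")), 1)
  expect_equal(setDistance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(setDistance(character(), character()), 0)
  expect_equal(setDistance(character(), "a"), 1)
  expect_equal(setDistance(c("a", "b", "c"), c("b", "c", "d"),
                           method = "normdiff"), 2 / 6)
})

test_that("divergence regression recovers exact linear relations", {
  lines <- paste0("L", 1:4)
  pairs <- t(utils::combn(lines, 2))
  pts <- data.frame(line_a = pairs[, 1], line_b = pairs[, 2],
                    cofactor_diff = seq(0.2, 0.9, length.out = nrow(pairs)),
                    stringsAsFactors = FALSE)
  pts$go_diff <- 0.5 * pts$cofactor_diff
  fit <- divergenceFit(pts)
  expect_equal(unname(fit$perLineR2), rep(1, 4), tolerance = 1e-9)
  expect_equal(fit$meanR2, 1, tolerance = 1e-9)
  # zero-variance regressor is excluded with a warning
  pts0 <- pts
  pts0$cofactor_diff[pairs[, 1] == "L1" | pairs[, 2] == "L1"] <- 0.4
  expect_warning(fit0 <- divergenceFit(pts0), "zero variance")
  expect_true(is.na(fit0$perLineR2["L1"]))
})

test_that("permuted responses give small R2 on average", {
  set.seed(82)
  lines <- paste0("L", 1:8)
  pairs <- t(utils::combn(lines, 2))
  x <- runif(nrow(pairs), 0.2, 0.9)
  meanR2 <- replicate(100, {
    pts <- data.frame(line_a = pairs[, 1], line_b = pairs[, 2],
                      cofactor_diff = x, go_diff = sample(x))
    suppressWarnings(divergenceFit(pts)$meanR2)
  })
  # for 7 points per line, E[R2] under independence is 1/6
  expect_lt(mean(meanR2), 0.3)
})

test_that("divergence regression validates its inputs", {
  cofs <- list(L1 = "a", L2 = "b")
  terms <- list(L1 = "t", L2 = "u")
  expect_error(divergenceRegression(cofs, terms), ">= 3")
  cofs3 <- list(L1 = c("a", "b"), L2 = c("b", "c"), L3 = c("a", "c"))
  terms3 <- list(L1 = "t", L2 = "u", L9 = "v")
  expect_error(divergenceRegression(cofs3, terms3), "same cell lines")
  # symmetric in the pair members
  terms3b <- list(L1 = c("t", "u"), L2 = c("u", "v"), L3 = c("t", "v"))
  fit <- suppressWarnings(divergenceRegression(cofs3, terms3b))
  expect_true(all(fit$points$cofactor_diff >= 0 &
                    fit$points$cofactor_diff <= 1))
  expect_equal(nrow(fit$points), 3L)
})
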