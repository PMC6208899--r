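test_that("logit normalization maps columns onto the stated logit scale", {
  m <- makeExprMatrix(cbind(c(1, 2, 3)))
  n <- logitNormalize(m)
  l <- log(0.025 / 0.975)
  expect_equal(unname(n[, 1]), c(l, 0, -l), tolerance = 1e-6)
  expect_equal(round(n[1, 1], 4), -3.6636)

  # midpoint of the column range -> 0; monotone map
  m2 <- makeExprMatrix(cbind(c(0, 5, 10, 7)))
  n2 <- logitNormalize(m2)
  expect_equal(unname(n2[2, 1]), 0)
  expect_identical(order(n2[, 1]), order(m2[, 1]))

  # constant column -> all zero
  mc <- makeExprMatrix(cbind(c(2, 2, 2)))
  expect_true(all(logitNormalize(mc) == 0))

  expect_error(logitNormalize(makeExprMatrix(cbind(c(1, NA, 3)))),
               "non-finite")
  expect_error(logitNormalize(m, epsilon = 0.7), "epsilon")
})

test_that("per-sample affine transformations do not change the signature", {
  p <- simulateCellLinePanel(300, 30, nPlantedUp = 40, nPlantedDown = 40,
                             effectSize = 1, seed = 61)
  comp <- simulateClinicalCompendium(50, rownames(p$expr), 0, seed = 62)
  sig1 <- buildSignature(p$expr, p$sensitivity, comp$expr)

  scaled <- sweep(p$expr, 2, runif(ncol(p$expr), 0.5, 3), `*`)
  scaled <- sweep(scaled, 2, rnorm(ncol(p$expr), 0, 10), `+`)
  sig2 <- buildSignature(scaled, p$sensitivity, comp$expr)
  expect_identical(upGenes(sig1), upGenes(sig2))
  expect_identical(downGenes(sig1), downGenes(sig2))
})

test_that("gene correlations hit exact endpoints and validate alignment", {
  s <- c(a = -1.2, b = 0.3, c = 0.8, d = 2.1, e = -0.5)
  m <- makeExprMatrix(rbind(s, -s, c(1, 1, 1, 1, 1)),
                      genes = c("gPos", "gNeg", "gFlat"),
                      samples = names(s))
  co <- geneCorrelations(m, s)
  expect_equal(co$r[co$gene_id == "gPos"], 1)
  expect_equal(co$r[co$gene_id == "gNeg"], -1)
  expect_equal(co$r[co$gene_id == "gFlat"], 0)
  expect_true(co$degenerate[co$gene_id == "gFlat"])

  expect_error(geneCorrelations(m[, 1:3], s[1:3]), "at least 4")
  expect_error(geneCorrelations(m, setNames(s, LETTERS[1:5])),
               "do not match")
})

test_that("candidate selection applies the strict threshold rule", {
  corr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     r = c(0.30, 0.25, -0.40, 0.00),
                     degenerate = FALSE)
  cand <- selectCandidates(corr, 0.25, strict = TRUE)
  expect_identical(cand$up, "g1")
  expect_identical(cand$down, "g3")
  # non-strict picks up the boundary gene
  expect_setequal(selectCandidates(corr, 0.25, strict = FALSE)$up,
                  c("g1", "g2"))
  # all sub-threshold -> both empty
  weak <- data.frame(gene_id = c("a", "b"), r = c(0.1, -0.2),
                     degenerate = FALSE)
  expect_length(selectCandidates(weak)$up, 0L)
  expect_length(selectCandidates(weak)$down, 0L)
  # threshold 0: every non-degenerate gene assigned by sign
  all0 <- selectCandidates(corr, 0)
  expect_setequal(c(all0$up, all0$down), c("g1", "g2", "g3"))
})

test_that("raising the correlation threshold never adds genes", {
  p <- simulateCellLinePanel(500, 60, nPlantedUp = 50, nPlantedDown = 50,
                             effectSize = 0.5, seed = 71)
  co <- geneCorrelations(logitNormalize(p$expr), p$sensitivity)
  prev <- selectCandidates(co, 0.1)
  for (thr in c(0.2, 0.3, 0.4)) {
    cur <- selectCandidates(co, thr)
    expect_true(all(cur$up %in% prev$up))
    expect_true(all(cur$down %in% prev$down))
    prev <- cur
  }
})

test_that("the presence filter removes exactly the silent candidates", {
  genes <- sprintf("g%04d", 1:800)
  comp <- simulateClinicalCompendium(60, genes, silentFraction = 0.25,
                                     seed = 81)
  up <- genes[1:100]; down <- genes[101:200]
  sig <- presenceFilter(up, down, comp$expr)
  expect_setequal(setdiff(up, upGenes(sig)),
                  intersect(comp$truth$silent, up))
  expect_setequal(setdiff(down, downGenes(sig)),
                  intersect(comp$truth$silent, down))

  # gene absent from the compendium rows is removed
  sig2 <- presenceFilter(c(up, "ghost"), down, comp$expr)
  expect_false("ghost" %in% upGenes(sig2))

  # minFraction = 0 keeps every gene present in the compendium
  sig3 <- presenceFilter(up, down, comp$expr, presenceMinFraction = 0)
  expect_setequal(upGenes(sig3), up)

  # empty filtered set -> explicit invalid-signature error
  expect_error(
    presenceFilter(intersect(comp$truth$silent, genes)[1:5], down,
                   comp$expr),
    "invalid signature")
})

test_that("signature build recovers planted genes and is deterministic", {
  p <- simulateCellLinePanel(600, 60, nPlantedUp = 150, nPlantedDown = 140,
                             effectSize = 0.75, seed = 91)
  comp <- simulateClinicalCompendium(80, rownames(p$expr), 0, seed = 92)
  sig <- buildSignature(p$expr, p$sensitivity, comp$expr)

  recall <- function(found, truth) length(intersect(found, truth)) /
    length(truth)
  precision <- function(found, truth) length(intersect(found, truth)) /
    length(found)
  expect_gte(recall(upGenes(sig), p$truth$up), 0.90)
  expect_gte(recall(downGenes(sig), p$truth$down), 0.90)
  expect_gte(precision(upGenes(sig), p$truth$up), 0.90)
  expect_gte(precision(downGenes(sig), p$truth$down), 0.90)
  expect_length(intersect(upGenes(sig), downGenes(sig)), 0L)

  md <- signatureMetadata(sig)
  expect_equal(md$nUp, length(upGenes(sig)))
  expect_gte(md$nUpCandidates, md$nUp)

  sigAgain <- buildSignature(p$expr, p$sensitivity, comp$expr)
  expect_identical(upGenes(sig), upGenes(sigAgain))
  expect_identical(downGenes(sig), downGenes(sigAgain))
})

test_that("GI50-scale input is converted so sensitivity genes correlate up", {
  p <- simulateCellLinePanel(400, 60, nPlantedUp = 40, nPlantedDown = 40,
                             effectSize = 1, seed = 95)
  comp <- simulateClinicalCompendium(50, rownames(p$expr), 0, seed = 96)
  # express the same sensitivity as raw GI50: sensitivity = -log10(GI50)
  gi50 <- 10^(-p$sensitivity)
  sigA <- buildSignature(p$expr, p$sensitivity, comp$expr)
  sigB <- buildSignature(p$expr, setNames(gi50, names(p$sensitivity)),
                         comp$expr, sensitivityScale = "gi50")
  expect_identical(upGenes(sigA), upGenes(sigB))
  expect_identical(downGenes(sigA), downGenes(sigB))
})
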