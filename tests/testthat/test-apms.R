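test_that("fold change applies unconditional background smoothing", {
  expect_equal(foldChange(c(5, 5), rep(0, 161)), 50, tolerance = 1e-15)
  expect_equal(foldChange(c(4, 6), c(1, 1, 1)), 5 / 1.1, tolerance = 1e-15)
  expect_identical(foldChange(c(0, 0), c(3, 1)), 0)
  # scale-free in run count: duplicating every control leaves it unchanged
  ctrl <- c(0, 1, 0, 2, 0)
  expect_identical(foldChange(c(7, 9), ctrl), foldChange(c(7, 9), rep(ctrl, 2)))
  expect_error(foldChange(numeric(), c(1)), "non-empty")
  expect_error(foldChange(c(-1), c(1)), "non-negative")
})

test_that("the Poisson-mixture posterior behaves as specified", {
  # no evidence: count 0 cannot exceed the prior
  expect_lte(scoreReplicate(0, rep(0, 161)), 0.1)
  expect_lte(scoreReplicate(0, rpois(20, 2)), 0.1)
  # prey never seen in 161 controls, 20 bait spectra: near-certain
  expect_gt(scoreReplicate(20, rep(0, 161)), 0.99)
  # direct evaluation of the stated posterior formula
  ctrl <- c(rep(0, 150), rep(1, 11))
  lam0 <- max(mean(ctrl), 0.1)
  lam1 <- max(6, 2 * lam0)
  p_manual <- dpois(6, lam1) * 0.1 /
    (dpois(6, lam1) * 0.1 + dpois(6, lam0) * 0.9)
  expect_equal(scoreReplicate(6, ctrl), p_manual, tolerance = 1e-12)
  # monotone in the bait count
  ps <- vapply(0:25, scoreReplicate, numeric(1), controlCounts = ctrl)
  expect_true(all(diff(ps) >= -1e-12))
  expect_error(scoreReplicate(3, c(0, 0)), "at least 5 control")
  expect_error(scoreReplicate(2.5, rep(0, 10)), "integer")
})

test_that("counts drawn from the background itself score low on average", {
  set.seed(31)
  ctrl <- rpois(161, 0.5)
  draws <- rpois(1000, 0.5)
  ps <- vapply(draws, scoreReplicate, numeric(1), controlCounts = ctrl)
  expect_lt(mean(ps), 0.5)
})

test_that("AvgP is the exact replicate mean and the pass gate is inclusive", {
  sim <- simulateApms(apmsSimConfig(n_preys = 60, n_controls = 30, seed = 3))
  sc <- scoreInteractions(sim$counts, condition = "mock")
  expect_equal(sc$avgp, (sc$p_rep1 + sc$p_rep2) / 2, tolerance = 0)
  # threshold set exactly at an observed AvgP: that prey still passes
  mid <- sc$avgp[sc$avgp > 0 & sc$avgp < 1][1]
  sc2 <- scoreInteractions(sim$counts,
                           scoringConfig(avgp_threshold = mid),
                           condition = "mock")
  expect_true(sc2$passes[sc2$avgp == mid][1])
  expect_true(all(sc2$passes == (sc2$avgp >= mid)))
  # a prey absent from all bait runs scores minimally and never passes
  k <- SummarizedExperiment::assay(sim$counts, "counts")
  k["PREY0001", runInfo(sim$counts)$kind == "bait"] <- 0L
  sc3 <- scoreInteractions(SpectralCountMatrix(k, runInfo(sim$counts)),
                           condition = "mock")
  expect_false(sc3$passes[sc3$prey == "PREY0001"])
  # with zero bait evidence the posterior cannot exceed the prior
  expect_lte(sc3$avgp[sc3$prey == "PREY0001"], 0.1)
})

test_that("interaction ranking is total, deterministic and input-order free", {
  sim <- simulateApms(apmsSimConfig(n_preys = 80, n_controls = 20, seed = 5))
  sc <- scoreInteractions(sim$counts, condition = "mock")
  expect_true(all(diff(sc$avgp) <= 0))
  perm <- sample(nrow(sim$counts))
  k <- SummarizedExperiment::assay(sim$counts, "counts")[perm, ]
  sc_perm <- scoreInteractions(SpectralCountMatrix(k, runInfo(sim$counts)),
                               condition = "mock")
  expect_identical(sc$prey, sc_perm$prey)
  expect_equal(sc$avgp, sc_perm$avgp, tolerance = 0)
})

test_that("scoring recovers simulated interactors with low FDR", {
  sim <- simulateApms(apmsSimConfig(seed = 1))
  sc <- scoreInteractions(sim$counts, condition = "mock")
  called <- sc$prey[sc$passes]
  truth <- trueInteractors(sim$truth)
  sens <- mean(truth %in% called)
  fdr <- if (length(called)) mean(!(called %in% truth)) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.05)
})

test_that("enhancement classification follows fold-ratio and pass-only rules", {
  # prey A: 10 -> 40 spectra (ratio 4): enhanced
  # prey B: symmetric counts: unchanged; prey C: 40 -> 10: reduced
  # prey D: passes only in stimulated: enhanced regardless of ratio
  bait_mock <- cbind(c(10, 20, 40, 0), c(10, 20, 40, 1))
  bait_stim <- cbind(c(40, 20, 10, 15), c(40, 20, 10, 15))
  controls <- matrix(0L, 4, 20)
  rownames(bait_mock) <- rownames(bait_stim) <- rownames(controls) <-
    c("A", "B", "C", "D")
  scm <- make_manual_scm(bait_mock, bait_stim, controls)
  mock <- scoreInteractions(scm, condition = "mock")
  stim <- scoreInteractions(scm, condition = "stimulated")
  enh <- classifyEnhancement(mock, stim)
  cls <- setNames(enh$enhancement, enh$prey)
  expect_identical(unname(cls[c("A", "B", "C", "D")]),
                   c("enhanced", "unchanged", "reduced", "enhanced"))
  expect_false(enh$passes_mock[enh$prey == "D"])
  # prey universes must match
  expect_error(classifyEnhancement(mock[-1, ], stim), "universes")
})
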