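test_that("normalization computes N, log2N and the viability gate", {
  mult <- matrix(1, 12, 1)
  ps <- make_manual_plateset(mult, baseline_lucia = 1000, ctg = 500)
  nw <- normalizePlates(ps)
  ex <- nw[nw$role == "experimental", ]
  expect_identical(unique(ex$N), 2)        # 1000 / 500 exactly
  expect_identical(unique(ex$log2N), 1)
  # ctg equal to the negative-control mean: viability ratio 1, viable
  expect_identical(unique(ex$viability_ratio), 1)
  expect_true(all(ex$viable))

  # toxic gene at depth 0.5 in a noise-free screen fails the 30% gate
  cfg <- screenSimConfig(n_genes = 320, cv_noise = 0, toxic_fraction = 0.05,
                         seed = 2)
  sim <- simulateScreen(cfg)
  nw2 <- normalizePlates(sim$plates)
  ex2 <- nw2[nw2$role == "experimental", ]
  tox <- ex2$gene %in% toxicGenes(sim$truth)
  expect_true(all(!ex2$viable[tox]))
  expect_true(all(ex2$viable[!tox]))
})

test_that("per-plate z-scores match an independent two-pass computation", {
  set.seed(4)
  mult <- matrix(2^rnorm(16, 0, 0.4), 16, 1)
  ps <- make_manual_plateset(mult)
  z <- plateZScores(normalizePlates(ps))
  ze <- z[z$role == "experimental", ]
  # brute-force oracle: two-pass mean / sample-SD standardization
  x <- log2(1000 * mult[, 1] / 2000)
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(ze$z, (x - m) / s, tolerance = 1e-12)
  # a well sitting at the plate mean scores zero
  mult2 <- matrix(2^c(-1, 1, -2, 2, -0.5, 0.5, -1.5, 1.5, 3, -3, 0.25,
                      -0.25, 0), 13, 1)
  z2 <- plateZScores(normalizePlates(make_manual_plateset(mult2)))
  expect_equal(z2$z[z2$role == "experimental"][13], 0, tolerance = 1e-12)
  # controls receive no z
  expect_true(all(is.na(z$z[z$role != "experimental"])))
})

test_that("z-scoring standardizes each plate to mean 0 / SD 1", {
  sim <- simulateScreen(screenSimConfig(n_genes = 640, seed = 6))
  z <- plateZScores(normalizePlates(sim$plates))
  grp <- paste(z$replicate, z$plate_id)
  for (g in unique(grp)) {
    zi <- z$z[grp == g & !is.na(z$z)]
    expect_equal(mean(zi), 0, tolerance = 1e-9)
    expect_equal(sd(zi), 1, tolerance = 1e-9)
  }
  # degenerate plate: all wells identical
  flat <- make_manual_plateset(matrix(1, 12, 1))
  expect_error(plateZScores(normalizePlates(flat)), "zero spread")
  # robust variant agrees with median/MAD
  zr <- plateZScores(normalizePlates(sim$plates), robust = TRUE)
  ex <- zr[zr$role == "experimental" & zr$replicate == 1 &
             zr$plate_id == "P01" & !is.na(zr$z), ]
  x <- ex$log2N
  expect_equal(ex$z, (x - median(x)) / mad(x), tolerance = 1e-12)
})

test_that("primary calls follow the two-of-three rule with discordance veto", {
  # 30 tightly spread null genes plus three crafted genes:
  #   DOWNHIT: strong reporter loss in replicates 1-2 only
  #   DISCORD: strong loss in rep 1, strong gain in rep 2
  #   UPHIT:   strong gain in replicates 1-2 only
  nulls <- matrix(2^(rep(c(-0.5, 0.5), 15)), 30, 3)
  crafted <- rbind(DOWNHIT = 2^c(-3, -3, 0),
                   DISCORD = 2^c(-3, 4, 0),
                   UPHIT = 2^c(4, 4, 0))
  mult <- rbind(nulls, crafted)
  rownames(mult) <- c(sprintf("NULL%02d", 1:30), rownames(crafted))
  ps <- make_manual_plateset(mult)
  z <- plateZScores(normalizePlates(ps))
  ze <- z[z$role == "experimental", ]
  zmat <- matrix(ze$z, ncol = 3)
  rownames(zmat) <- rownames(mult)
  # crafted z patterns really cross the thresholds they are meant to
  expect_true(sum(zmat["DOWNHIT", ] <= -2) >= 2)
  expect_true(any(zmat["DISCORD", ] <= -2) && any(zmat["DISCORD", ] >= 3))
  expect_true(sum(zmat["UPHIT", ] >= 3) >= 2)

  hits <- callPrimary(ps)
  expect_identical(hits$primary_call[hits$gene == "DOWNHIT"], "down")
  expect_identical(hits$n_supporting[hits$gene == "DOWNHIT"], 2L)
  expect_identical(hits$primary_call[hits$gene == "UPHIT"], "up")
  expect_identical(hits$primary_call[hits$gene == "DISCORD"], "none")
  expect_true(hits$discordant[hits$gene == "DISCORD"])
  expect_true(all(hits$primary_call[grepl("NULL", hits$gene)] == "none"))
})

test_that("primary calling equals a brute-force scan of the z matrix", {
  sim <- simulateScreen(screenSimConfig(n_genes = 960, seed = 8))
  hits <- callPrimary(sim$plates)
  zmat <- as.matrix(hits[, c("z_1", "z_2", "z_3")])
  rownames(zmat) <- hits$gene
  expect_identical(unname(oracle_primary_call(zmat)),
                   ifelse(hits$callable, hits$primary_call, "none"))
  # monotonicity: a more extreme down threshold never adds down hits
  strict <- callPrimary(sim$plates, zLow = -3)
  expect_true(all(strict$gene[strict$primary_call == "down"] %in%
                    hits$gene[hits$primary_call == "down"]))
})

test_that("primary calls are invariant under common channel rescaling", {
  sim <- simulateScreen(screenSimConfig(n_genes = 320, seed = 10))
  lay <- plateLayout(sim$plates)[, c("plate_id", "row", "column", "role",
                                     "gene", "sirna_id")]
  lu <- SummarizedExperiment::assay(sim$plates, "lucia")
  ct <- SummarizedExperiment::assay(sim$plates, "ctg")
  scaled <- PlateSet(lu * 7.3, ct * 0.6, lay, "smartpool")
  h0 <- callPrimary(sim$plates)
  h1 <- callPrimary(scaled)
  expect_identical(h0$primary_call, h1$primary_call)
  expect_equal(h0$z_1, h1$z_1, tolerance = 1e-9)
})

test_that("genes without enough QC-passing replicates are uncallable", {
  mult <- matrix(2^rep(c(-0.5, 0.5), 6), 12, 3)
  mult[1, ] <- 2^c(-4, -4, -4)  # would be a clear hit
  # controls overlap in replicates 2 and 3 -> negative Z' there
  neg <- cbind(c(900, 950, 1050, 1100), c(990, 1000, 1010, 1020),
               c(990, 1000, 1010, 1020))
  pos <- cbind(c(180, 190, 210, 220), c(970, 980, 1000, 1010),
               c(970, 980, 1000, 1010))
  ps <- make_manual_plateset(mult, neg_lucia = neg, pos_lucia = pos)
  qc <- qcPlates(ps)
  expect_identical(qc$pass, c(TRUE, FALSE, FALSE))
  hits <- callPrimary(ps)
  expect_true(all(!hits$callable))
  expect_true(all(hits$primary_call == "none"))
})

test_that("secondary confirmation needs two duplexes in one direction", {
  genes <- c("GA", "GB")
  # GA: two strong-down duplexes -> confirmed down
  # GB: one down + one up duplex -> directions disagree, not confirmed
  dm <- rbind(c(0.30, 0.30, 0.30), c(0.35, 0.35, 0.35),
              c(0.90, 0.90, 0.90), c(1.00, 1.00, 1.00),
              c(0.30, 0.30, 0.30), c(1.80, 1.80, 1.80),
              c(1.00, 1.00, 1.00), c(1.00, 1.00, 1.00))
  ps <- make_manual_deconv(genes, dm)
  sec <- callSecondary(ps)
  a <- sec[sec$gene == "GA", ]
  expect_true(a$confirmed)
  expect_identical(a$direction, "down")
  expect_identical(a$n_pass_down, 2L)
  b <- sec[sec$gene == "GB", ]
  expect_false(b$confirmed)
  expect_true(b$discordant)

  # a toxic duplex is vetoed even with a strong activity ratio
  dm2 <- rbind(c(0.15), c(0.3), c(1), c(1))
  cm2 <- rbind(c(0.5), c(1), c(1), c(1))  # duplex 1 loses 50% viability
  ps2 <- make_manual_deconv("GC", dm2, ctg_mult = cm2)
  sec2 <- callSecondary(ps2)
  expect_false(sec2$confirmed)  # only duplex 2 passes
  expect_identical(sec2$n_pass_down, 1L)
})

test_that("deconvolution of two active duplexes confirms, one does not", {
  cfg <- screenSimConfig(effect_size_down = 0.3, cv_noise = 0, seed = 5)
  genes <- sprintf("G%04d", 1:8)
  two <- simulateDeconvolution(cfg, genes, 2)
  sec2 <- callSecondary(two$plates)
  expect_true(all(sec2$confirmed))
  one <- simulateDeconvolution(cfg, genes, 1)
  sec1 <- callSecondary(one$plates)
  expect_true(all(!sec1$confirmed))
})
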