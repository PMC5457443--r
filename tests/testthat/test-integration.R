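test_that("hit-list overlap is an exact, normalized set intersection", {
  ov <- hitOverlap(c("NXF1", "WDR77", "GPS1"), c("NXF1", "GPS1", "MYD88"))
  expect_identical(ov$overlap, c("GPS1", "NXF1"))
  expect_identical(ov$n_overlap, 2L)
  # commutative and idempotent
  ov2 <- hitOverlap(c("NXF1", "GPS1", "MYD88"), c("NXF1", "WDR77", "GPS1"))
  expect_identical(ov$overlap, ov2$overlap)
  expect_identical(hitOverlap(ov$overlap, ov$overlap)$overlap, ov$overlap)
  # disjoint and case-normalized inputs
  expect_identical(hitOverlap(c("A", "B"), c("C"))$n_overlap, 0L)
  expect_identical(hitOverlap(c("nxf1"), c("NXF1"))$n_overlap, 1L)
  # alias mapping unifies synonymous symbols
  expect_identical(hitOverlap(c("COPS1"), c("GPS1"),
                              aliasMap = c(COPS1 = "GPS1"))$n_overlap, 1L)
  expect_warning(hitOverlap(character(), c("A")), "empty")
})

test_that("supplementary filter re-application counts survivors by hand", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(prey = paste0("P", 1:5),
                       AvgP = c(0.95, 0.89, 0.50, 0.88, 1.0)),
            p, row.names = FALSE)
  rep <- reproduceSupplementary(p, list(id = "prey", avgp = "AvgP"), "apms")
  expect_identical(rep$n_survivors, 3L)  # inclusive >= 0.89
  expect_identical(rep$survivors, c("P1", "P2", "P5"))

  write.csv(data.frame(prey = character(), AvgP = numeric()), p,
            row.names = FALSE)
  expect_identical(
    reproduceSupplementary(p, list(avgp = "AvgP"), "apms")$n_survivors, 0L)
  expect_error(reproduceSupplementary(p, list(avgp = "missing"), "apms"),
               "AvgP column")
})

test_that("re-filtering the package's own hit table is a fixed point", {
  sim <- simulateScreen(screenSimConfig(n_genes = 640, seed = 21))
  hits <- callPrimary(sim$plates)
  p <- tempfile(fileext = ".csv")
  writeHitTable(hits, p)
  rep <- reproduceSupplementary(
    p, list(id = "gene", z = c("z_1", "z_2", "z_3"),
            viability = c("viable_1", "viable_2", "viable_3")), "primary")
  expect_identical(sort(rep$survivors),
                   sort(hits$gene[hits$primary_call != "none"]))
  expect_match(paste(rep$filters_applied, collapse = "; "), "viability")
  # unmapped viability columns degrade gracefully and are reported
  rep2 <- reproduceSupplementary(
    p, list(id = "gene", z = c("z_1", "z_2", "z_3"),
            viability = c("nope_1")), "primary")
  expect_identical(rep2$missing_columns, "nope_1")
})

test_that("network export writes consistent node and edge sets", {
  scores <- data.frame(prey = sprintf("INT%02d", 1:19),
                       fold_change = 19:1, avgp = seq(1, 0.9, length = 19),
                       passes = TRUE,
                       enhancement = c(rep("enhanced", 3),
                                       rep("unchanged", 16)))
  hits <- data.frame(gene = c("INT01", "REG1"), confirmed = TRUE)
  p <- tempfile(fileext = ".csv")
  net <- exportNetwork(scores, hits, p, "edge_csv")
  expect_identical(nrow(net$nodes), 21L)  # bait + 19 interactors + REG1
  expect_identical(nrow(net$edges), 20L)
  expect_identical(net$nodes$category[net$nodes$id == "INT01"], "both")
  expect_identical(sum(net$edges$condition_enhanced), 3L)
  # edge CSV round trip reproduces the edge set
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_identical(back$target, net$edges$target)
  expect_identical(back$evidence, net$edges$evidence)
  nodes_back <- read.csv(sub("\\.csv$", "_nodes.csv", p))
  expect_identical(nrow(nodes_back), 21L)
  # bait-only graph from empty inputs
  empty <- exportNetwork(scores[0, ], hits[0, ], p, "edge_csv")
  expect_identical(empty$nodes$id, "IRF5")
  expect_identical(nrow(empty$edges), 0L)
  # graphml export loads in igraph
  g <- tempfile(fileext = ".graphml")
  exportNetwork(scores, hits, g, "graphml")
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gr), 21)
  expect_equal(igraph::ecount(gr), 20)
})

test_that("the pipeline runs end to end, deterministically, stage-gated", {
  cfgfile <- tempfile(fileext = ".yaml")
  out1 <- file.path(tempdir(), "run1"); out2 <- file.path(tempdir(), "run2")
  base_cfg <- list(
    screen = list(simulate = list(n_genes = 320, seed = 11)),
    deconvolution = list(simulate = list(seed = 12,
                                         active_duplexes_per_gene = 4)),
    apms = list(simulate = list(n_preys = 120, n_controls = 25, seed = 13)))
  yaml::write_yaml(c(base_cfg, list(outdir = out1)), cfgfile)
  res <- runPipeline(cfgfile)
  produced <- c("plate_qc.csv", "replicate_concordance.csv",
                "primary_hits.csv", "secondary_hits.csv", "apms_mock.csv",
                "apms_stimulated.csv", "apms_enhancement.csv",
                "overlap.csv", "network_edges.csv", "manifest.json")
  expect_true(all(file.exists(file.path(out1, produced))))
  # manifest records every effective threshold
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$stages$primary$zLow, -2)
  expect_equal(man$stages$apms_scoring$avgp_threshold, 0.89)
  expect_equal(man$stages$secondary$changeFraction, 0.6)
  expect_equal(man$stages$qc$threshold, 0.2)

  yaml::write_yaml(c(base_cfg, list(outdir = out2)), cfgfile)
  runPipeline(cfgfile)
  for (f in setdiff(produced, "manifest.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)

  # apms-only config runs only the AP-MS stages
  out3 <- file.path(tempdir(), "run3")
  yaml::write_yaml(list(outdir = out3,
                        apms = list(simulate = list(n_preys = 60,
                                                    n_controls = 20,
                                                    seed = 2))), cfgfile)
  runPipeline(cfgfile)
  expect_true(file.exists(file.path(out3, "apms_mock.csv")))
  expect_false(file.exists(file.path(out3, "primary_hits.csv")))
})
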