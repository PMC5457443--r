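#' Run the full discovery pipeline from a YAML config
#'
#' Orchestrates the stages in dependency order — simulate (or read)
#' plates, plate QC, replicate concordance, normalization + primary hit
#' calling, deconvolution confirmation, AP-MS scoring under both
#' conditions with enhancement classification, hit-list overlap and
#' network export — writing every result as CSV into `outdir` plus a
#' machine-readable `manifest.json` listing inputs, every effective
#' threshold and all seeds. Stages whose config section is absent are
#' skipped; any stage failure aborts with a stage-labelled error while
#' partial outputs are kept. Identical config and seeds produce
#' byte-identical result files.
#'
#' The YAML layout (all thresholds optional, shown with defaults):
#' ```yaml
#' outdir: results
#' screen:
#'   simulate: {n_genes: 960, seed: 1}          # or readout:/layout: paths
#'   qc: {metric: normalized_N, threshold: 0.2}
#'   primary: {z_low: -2, z_high: 3, min_replicates: 2}
#' deconvolution:
#'   simulate: {active_duplexes_per_gene: 4, seed: 2}  # genes default to
#'                                                     # primary hits
#'   secondary: {change_fraction: 0.6, sd_mult: 2, min_duplexes: 2}
#' apms:
#'   simulate: {n_preys: 500, seed: 3}          # or counts:/runs: paths
#'   scoring: {avgp_threshold: 0.89, background_factor: 0.1,
#'             enhancement_ratio: 2}
#' network: {bait: IRF5}
#' ```
#'
#' @param configPath path to the YAML configuration.
#' @return invisibly, a named list of the stage results (and `manifest`).
#' @export
runPipeline <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(package_version = as.character(packageVersion("screenomics")),
                   config = basename(configPath),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  primary_hits <- NULL
  if (!is.null(cfg$screen)) {
    ps <- stage("screen-input", {
      if (!is.null(cfg$screen$simulate)) {
        sc <- do.call(screenSimConfig, cfg$screen$simulate)
        manifest$stages$screen_simulate <- unclass(sc)
        sim <- simulateScreen(sc)
        results$screen_truth <- sim$truth
        sim$plates
      } else {
        readPlateSet(cfg$screen$readout, cfg$screen$layout)
      }
    })
    qc_args <- cfg$screen$qc %||% list()
    qc <- stage("qc", do.call(qcPlates, c(list(ps),
      list(metric = qc_args$metric %||% "normalized_N",
           threshold = qc_args$threshold %||% 0.2))))
    manifest$stages$qc <- list(metric = qc_args$metric %||% "normalized_N",
                               threshold = qc_args$threshold %||% 0.2)
    writeHitTable(qc, file.path(outdir, "plate_qc.csv"))
    conc <- stage("concordance", replicateR2(ps))
    writeHitTable(conc, file.path(outdir, "replicate_concordance.csv"))
    pr <- cfg$screen$primary %||% list()
    primary_args <- list(zLow = pr$z_low %||% -2, zHigh = pr$z_high %||% 3,
                         minReplicates = pr$min_replicates %||% 2,
                         qcMetric = qc_args$metric %||% "normalized_N",
                         qcThreshold = qc_args$threshold %||% 0.2)
    primary_hits <- stage("primary",
                          do.call(callPrimary, c(list(ps), primary_args)))
    manifest$stages$primary <- primary_args
    writeHitTable(primary_hits, file.path(outdir, "primary_hits.csv"))
    results$qc <- qc; results$concordance <- conc
    results$primary <- primary_hits
  }

  secondary_hits <- NULL
  if (!is.null(cfg$deconvolution)) {
    dps <- stage("deconvolution-input", {
      if (!is.null(cfg$deconvolution$simulate)) {
        dsim <- cfg$deconvolution$simulate
        genes <- dsim$genes %||%
          primary_hits$gene[primary_hits$primary_call != "none"]
        if (!length(genes)) stop("no genes to deconvolve")
        direction <- dsim$direction %||%
          (if (is.null(dsim$genes) && !is.null(primary_hits))
            primary_hits$primary_call[match(genes, primary_hits$gene)]
           else "down")
        sc_args <- dsim[setdiff(names(dsim),
                                c("genes", "direction",
                                  "active_duplexes_per_gene"))]
        sc <- do.call(screenSimConfig, sc_args)
        manifest$stages$deconvolution_simulate <-
          c(unclass(sc), list(active_duplexes_per_gene =
                                dsim$active_duplexes_per_gene %||% 4))
        simulateDeconvolution(sc, genes,
                              dsim$active_duplexes_per_gene %||% 4,
                              direction = direction)$plates
      } else {
        readPlateSet(cfg$deconvolution$readout, cfg$deconvolution$layout,
                     screenMode = "deconvolution")
      }
    })
    se <- cfg$deconvolution$secondary %||% list()
    sec_args <- list(changeFraction = se$change_fraction %||% 0.6,
                     sdMult = se$sd_mult %||% 2,
                     minDuplexes = se$min_duplexes %||% 2,
                     maxViabilityLoss = se$max_viability_loss %||% 0.3)
    secondary_hits <- stage("secondary",
                            do.call(callSecondary, c(list(dps), sec_args)))
    manifest$stages$secondary <- sec_args
    writeHitTable(secondary_hits, file.path(outdir, "secondary_hits.csv"))
    results$secondary <- secondary_hits
  }

  apms_enh <- NULL
  if (!is.null(cfg$apms)) {
    scm <- stage("apms-input", {
      if (!is.null(cfg$apms$simulate)) {
        ac <- do.call(apmsSimConfig, cfg$apms$simulate)
        manifest$stages$apms_simulate <- unclass(ac)
        sim <- simulateApms(ac)
        results$apms_truth <- sim$truth
        sim$counts
      } else {
        counts <- as.matrix(read.csv(cfg$apms$counts, row.names = 1))
        SpectralCountMatrix(counts, read.csv(cfg$apms$runs))
      }
    })
    sc_cfg <- do.call(scoringConfig, cfg$apms$scoring %||% list())
    manifest$stages$apms_scoring <- unclass(sc_cfg)
    mock <- stage("apms-score",
                  scoreInteractions(scm, sc_cfg, condition = "mock"))
    stim <- stage("apms-score",
                  scoreInteractions(scm, sc_cfg, condition = "stimulated"))
    writeHitTable(mock, file.path(outdir, "apms_mock.csv"))
    writeHitTable(stim, file.path(outdir, "apms_stimulated.csv"))
    apms_enh <- stage("apms-enhancement",
                      classifyEnhancement(mock, stim,
                                          sc_cfg$enhancement_ratio))
    writeHitTable(apms_enh, file.path(outdir, "apms_enhancement.csv"))
    results$apms <- apms_enh
  }

  if (!is.null(apms_enh) &&
      (!is.null(secondary_hits) || !is.null(primary_hits))) {
    hits <- secondary_hits %||% primary_hits
    called <- if ("confirmed" %in% colnames(hits))
      hits$gene[hits$confirmed] else hits$gene[hits$primary_call != "none"]
    ov <- stage("overlap", hitOverlap(
      apms_enh$prey[apms_enh$passes_mock | apms_enh$passes_stim], called))
    writeHitTable(data.frame(gene = ov$overlap),
                  file.path(outdir, "overlap.csv"))
    results$overlap <- ov
    net_cfg <- cfg$network %||% list()
    stage("network", exportNetwork(apms_enh, hits,
                                   file.path(outdir, "network_edges.csv"),
                                   bait = net_cfg$bait %||% "IRF5"))
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
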