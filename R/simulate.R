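# Default control placement on a 384-well plate, mirroring common edge
# layouts: columns 1 and 23 non-targeting negatives, column 2 the
# pathway-specific positive control (siTLR7-like), column 24 cytotoxic
# transfection controls (siKIF11/siPLK1-like). Columns 3-22 are the 320
# experimental wells, filled row-major.
.plateTemplate <- function(plate_id) {
  grid <- expand.grid(column = PLATE_COLS, row = PLATE_ROWS,
                      stringsAsFactors = FALSE)[, c("row", "column")]
  role <- rep("experimental", nrow(grid))
  role[grid$column %in% c(1L, 23L)] <- "negative_control"
  role[grid$column == 2L] <- "positive_control"
  role[grid$column == 24L] <- "toxicity_control"
  data.frame(plate_id = plate_id, row = grid$row, column = grid$column,
             role = role, gene = NA_character_, sirna_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Configuration for the reporter-screen simulator
#'
#' Bundles and validates the parameters of [simulateScreen()] /
#' [simulateDeconvolution()]. Defaults describe a paper-like triplicate
#' SMARTpool campaign: 2.5% spiked regulators split evenly between
#' activators of the reporter (knockdown raises signal 4-fold, i.e. the
#' gene is a repressor of the pathway) and repressors of the reporter
#' (signal down to 0.25x), 2% cytotoxic genes losing half their
#' viability, 10% multiplicative log-normal well noise on each channel,
#' and a positive control that knocks reporter activity down 5-fold
#' (the assay's siTLR7 control reduces activity more than 3-fold).
#'
#' @param n_genes genes screened, one SMARTpool well per gene per plate.
#' @param hit_fraction_up,hit_fraction_down fractions of genes spiked with
#'   the up/down reporter effect.
#' @param effect_size_up,effect_size_down multiplicative factors on the
#'   reporter signal for spiked genes (`down < 1 < up`).
#' @param toxic_fraction,toxicity_depth fraction of cytotoxic genes and the
#'   proportion of viability they lose.
#' @param cv_noise coefficient of variation of the log-normal well noise
#'   (sdlog of the noise term); independent between the Lucia and CTG
#'   channels, which are coupled only through the shared viability factor.
#' @param n_replicates replicate plate sets sharing one layout.
#' @param baseline_lucia,baseline_ctg expected raw luminescence of an
#'   unperturbed well (relative light units).
#' @param pos_control_effect multiplicative reporter effect of the positive
#'   control wells (< 1).
#' @param seed integer seed; a fixed seed makes the generator bit
#'   reproducible.
#' @return a validated list of class `ScreenSimConfig`.
#' @export
screenSimConfig <- function(n_genes = 960,
                            hit_fraction_up = 0.0125,
                            hit_fraction_down = 0.0125,
                            effect_size_up = 4,
                            effect_size_down = 0.25,
                            toxic_fraction = 0.02,
                            toxicity_depth = 0.5,
                            cv_noise = 0.1,
                            n_replicates = 3,
                            baseline_lucia = 1000,
                            baseline_ctg = 2000,
                            pos_control_effect = 0.2,
                            seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              hit_fraction_up = hit_fraction_up,
              hit_fraction_down = hit_fraction_down,
              effect_size_up = effect_size_up,
              effect_size_down = effect_size_down,
              toxic_fraction = toxic_fraction,
              toxicity_depth = toxicity_depth,
              cv_noise = cv_noise,
              n_replicates = as.integer(n_replicates),
              baseline_lucia = baseline_lucia,
              baseline_ctg = baseline_ctg,
              pos_control_effect = pos_control_effect,
              seed = as.integer(seed))
  fr <- c(cfg$hit_fraction_up, cfg$hit_fraction_down, cfg$toxic_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("hit/toxic fractions must lie in [0,1] and sum to at most 1")
  if (!(cfg$effect_size_down < 1 && cfg$effect_size_up > 1))
    stop("effect sizes must satisfy effect_size_down < 1 < effect_size_up")
  if (cfg$cv_noise < 0) stop("cv_noise must be >= 0")
  if (cfg$toxicity_depth < 0 || cfg$toxicity_depth >= 1)
    stop("toxicity_depth must lie in [0,1)")
  if (cfg$pos_control_effect >= 1 || cfg$pos_control_effect <= 0)
    stop("pos_control_effect must lie in (0,1)")
  if (cfg$baseline_lucia <= 0 || cfg$baseline_ctg <= 0)
    stop("baselines must be positive")
  if (cfg$n_genes < 1 || cfg$n_replicates < 1)
    stop("n_genes and n_replicates must be positive")
  class(cfg) <- "ScreenSimConfig"
  cfg
}

# Shared noise/assembly step. `effect` and `viab` are per-well vectors
# aligned with `layout`. One random stream per generator call, consumed
# replicate by replicate: lucia noise over wells in layout order, then ctg
# noise over wells in layout order.
.assemblePlates <- function(layout, effect, viab, cfg, screenMode) {
  n <- nrow(layout)
  nonempty <- layout$role != "empty"
  lucia <- matrix(NA_real_, n, cfg$n_replicates)
  ctg <- matrix(NA_real_, n, cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    noise_l <- rlnorm(n, meanlog = 0, sdlog = cfg$cv_noise)
    noise_c <- rlnorm(n, meanlog = 0, sdlog = cfg$cv_noise)
    lucia[, r] <- cfg$baseline_lucia * effect * viab * noise_l
    ctg[, r] <- cfg$baseline_ctg * viab * noise_c
  }
  lucia[!nonempty, ] <- NA_real_
  ctg[!nonempty, ] <- NA_real_
  PlateSet(lucia, ctg, layout, screenMode)
}

#' Simulate a SMARTpool reporter screen with known ground truth
#'
#' Generates replicate 384-well plates following the assay's generative
#' model: `lucia = baseline_lucia * gene_effect * control_effect *
#' viability * LogNormal(0, cv_noise)` and `ctg = baseline_ctg * viability
#' * LogNormal(0, cv_noise)`. Spiked genes multiply the reporter by
#' `effect_size_up`/`effect_size_down`; toxic genes (and toxicity-control
#' wells) get `viability = 1 - toxicity_depth`, which depresses both
#' channels; positive-control wells multiply the reporter by
#' `pos_control_effect`. Genes are assigned row-major to the experimental
#' wells of as many plates as needed; spare wells are `empty`.
#'
#' @param config a [screenSimConfig()].
#' @return `list(plates = PlateSet, truth = GroundTruth)`.
#' @examples
#' sim <- simulateScreen(screenSimConfig(n_genes = 320, seed = 7))
#' sim$truth
#' @export
simulateScreen <- function(config) {
  stopifnot(inherits(config, "ScreenSimConfig"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_up <- round(config$hit_fraction_up * config$n_genes)
  n_down <- round(config$hit_fraction_down * config$n_genes)
  n_tox <- round(config$toxic_fraction * config$n_genes)
  pick <- sample(genes, n_up + n_down + n_tox)
  up <- pick[seq_len(n_up)]
  down <- pick[n_up + seq_len(n_down)]
  toxic <- pick[n_up + n_down + seq_len(n_tox)]

  n_plates <- ceiling(config$n_genes / 320)
  layout <- do.call(rbind, lapply(seq_len(n_plates), function(p)
    .plateTemplate(sprintf("P%02d", p))))
  exp_idx <- which(layout$role == "experimental")
  layout$gene[exp_idx[seq_along(genes)]] <- genes
  layout$role[exp_idx[-seq_along(genes)]] <- "empty"

  effect <- rep(1, nrow(layout))
  effect[layout$gene %in% up] <- config$effect_size_up
  effect[layout$gene %in% down] <- config$effect_size_down
  effect[layout$role == "positive_control"] <- config$pos_control_effect
  viab <- rep(1, nrow(layout))
  viab[layout$gene %in% toxic] <- 1 - config$toxicity_depth
  viab[layout$role == "toxicity_control"] <- 1 - config$toxicity_depth

  plates <- .assemblePlates(layout, effect, viab, config, "smartpool")
  list(plates = plates,
       truth = GroundTruth(trueUp = up, trueDown = down, toxic = toxic))
}

#' Simulate a duplex-deconvolution (secondary) screen
#'
#' Each gene is screened as 4 individual siRNA duplex wells; exactly
#' `activeDuplexesPerGene` of them (the first ones, deterministically)
#' carry the gene's reporter effect, the rest behave as nulls. This
#' emulates on-target confirmation: a pool whose phenotype is driven by
#' at least two active duplexes should be confirmed downstream, a
#' single-duplex (off-target-like) pool should not.
#'
#' @param config a [screenSimConfig()]; `effect_size_down` /
#'   `effect_size_up` give the active-duplex effect.
#' @param genes character vector of genes to deconvolve.
#' @param activeDuplexesPerGene integer 0-4.
#' @param direction `"down"` or `"up"` per gene (recycled).
#' @return `list(plates = PlateSet, truth = GroundTruth)`; the truth
#'   records genes with at least one active duplex under their direction.
#' @export
simulateDeconvolution <- function(config, genes, activeDuplexesPerGene,
                                  direction = "down") {
  stopifnot(inherits(config, "ScreenSimConfig"))
  if (length(genes) < 1) stop("genes must be non-empty")
  if (activeDuplexesPerGene < 0 || activeDuplexesPerGene > 4)
    stop("activeDuplexesPerGene must lie in 0-4")
  direction <- rep_len(direction, length(genes))
  if (!all(direction %in% c("down", "up")))
    stop("direction must be 'down' or 'up'")
  set.seed(config$seed)

  per_gene <- 4L
  n_wells_needed <- length(genes) * per_gene
  n_plates <- ceiling(n_wells_needed / 320)
  layout <- do.call(rbind, lapply(seq_len(n_plates), function(p)
    .plateTemplate(sprintf("D%02d", p))))
  exp_idx <- which(layout$role == "experimental")
  gene_vec <- rep(genes, each = per_gene)
  duplex <- sprintf("%s_d%d", gene_vec, rep(1:4, length(genes)))
  layout$gene[exp_idx[seq_along(gene_vec)]] <- gene_vec
  layout$sirna_id[exp_idx[seq_along(gene_vec)]] <- duplex
  layout$role[exp_idx[-seq_along(gene_vec)]] <- "empty"

  active <- rep(rep(1:4, length(genes)) <= activeDuplexesPerGene,
                length.out = length(gene_vec))
  eff_gene <- ifelse(direction == "down", config$effect_size_down,
                     config$effect_size_up)
  effect <- rep(1, nrow(layout))
  effect[exp_idx[seq_along(gene_vec)]] <-
    ifelse(active, rep(eff_gene, each = per_gene), 1)
  effect[layout$role == "positive_control"] <- config$pos_control_effect
  viab <- rep(1, nrow(layout))
  viab[layout$role == "toxicity_control"] <- 1 - config$toxicity_depth

  plates <- .assemblePlates(layout, effect, viab, config, "deconvolution")
  carried <- activeDuplexesPerGene > 0
  list(plates = plates,
       truth = GroundTruth(
         trueUp = if (carried) genes[direction == "up"] else character(),
         trueDown = if (carried) genes[direction == "down"] else character()))
}

#' Configuration for the AP-MS spectral-count simulator
#'
#' Defaults emulate the bait purification design scored downstream: 2
#' biological replicates per condition (mock and stimulated), a panel of
#' 161 negative-control purifications, Poisson spectral counts with a
#' true-interaction rate well separated from the background rate, and a
#' small stimulation-enhanced subset whose bait-run rate is multiplied
#' under stimulation.
#'
#' @param n_preys number of candidate prey proteins.
#' @param n_true_interactors genuine interactors among them.
#' @param n_enhanced subset of true interactors enhanced by stimulation.
#' @param lambda_true,lambda_bg Poisson means of true-interaction and
#'   background counts (`lambda_true > lambda_bg >= 0`).
#' @param enhancement_factor multiplier (>= 2) on `lambda_true` in
#'   stimulated bait runs of enhanced preys.
#' @param n_bait_reps bait replicates per condition.
#' @param n_controls negative-control purifications.
#' @param seed integer seed.
#' @return a validated list of class `ApmsSimConfig`.
#' @export
apmsSimConfig <- function(n_preys = 500, n_true_interactors = 50,
                          n_enhanced = 3, lambda_true = 10, lambda_bg = 0.2,
                          enhancement_factor = 4, n_bait_reps = 2,
                          n_controls = 161, seed = 1) {
  cfg <- list(n_preys = as.integer(n_preys),
              n_true_interactors = as.integer(n_true_interactors),
              n_enhanced = as.integer(n_enhanced),
              lambda_true = lambda_true, lambda_bg = lambda_bg,
              enhancement_factor = enhancement_factor,
              n_bait_reps = as.integer(n_bait_reps),
              n_controls = as.integer(n_controls),
              seed = as.integer(seed))
  if (!(cfg$n_enhanced <= cfg$n_true_interactors &&
        cfg$n_true_interactors <= cfg$n_preys))
    stop("need n_enhanced <= n_true_interactors <= n_preys")
  if (!(cfg$lambda_true > cfg$lambda_bg && cfg$lambda_bg >= 0))
    stop("need lambda_true > lambda_bg >= 0")
  if (cfg$enhancement_factor < 2)
    stop("enhancement_factor must be >= 2")
  if (cfg$n_bait_reps < 1 || cfg$n_controls < 1)
    stop("need at least one bait replicate and one control run")
  class(cfg) <- "ApmsSimConfig"
  cfg
}

#' Simulate an AP-MS spectral-count matrix with known interactors
#'
#' Counts are independent Poisson draws: true interactors at
#' `lambda_true` in bait runs (times `enhancement_factor` in stimulated
#' runs for the enhanced subset), everything else — including all preys
#' in every control run — at `lambda_bg`. The random stream is consumed
#' run by run in column order after the truth sets are drawn.
#'
#' @param config an [apmsSimConfig()].
#' @return `list(counts = SpectralCountMatrix, truth = GroundTruth)`.
#' @examples
#' sim <- simulateApms(apmsSimConfig(n_preys = 100, n_controls = 20, seed = 2))
#' sim$counts
#' @export
simulateApms <- function(config) {
  stopifnot(inherits(config, "ApmsSimConfig"))
  set.seed(config$seed)
  preys <- sprintf("PREY%04d", seq_len(config$n_preys))
  truth_preys <- sample(preys, config$n_true_interactors)
  enhanced <- truth_preys[seq_len(config$n_enhanced)]

  runs <- rbind(
    data.frame(run_id = sprintf("bait_mock_r%d", seq_len(config$n_bait_reps)),
               kind = "bait", condition = "mock",
               replicate = seq_len(config$n_bait_reps)),
    data.frame(run_id = sprintf("bait_stim_r%d", seq_len(config$n_bait_reps)),
               kind = "bait", condition = "stimulated",
               replicate = seq_len(config$n_bait_reps)),
    data.frame(run_id = sprintf("ctrl_%03d", seq_len(config$n_controls)),
               kind = "control", condition = "na",
               replicate = seq_len(config$n_controls)))

  is_true <- preys %in% truth_preys
  is_enh <- preys %in% enhanced
  counts <- matrix(0L, config$n_preys, nrow(runs),
                   dimnames = list(preys, runs$run_id))
  for (j in seq_len(nrow(runs))) {
    lam <- rep(config$lambda_bg, config$n_preys)
    if (runs$kind[j] == "bait") {
      lam[is_true] <- config$lambda_true
      if (runs$condition[j] == "stimulated")
        lam[is_enh] <- config$lambda_true * config$enhancement_factor
    }
    counts[, j] <- rpois(config$n_preys, lam)
  }
  list(counts = SpectralCountMatrix(counts, runs),
       truth = GroundTruth(interactors = truth_preys, enhanced = enhanced))
}
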