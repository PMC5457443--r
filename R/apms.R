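#' Smoothed spectral-count fold change
#'
#' Ratio of the mean spectral count across replicate bait purifications
#' to the mean count across all negative-control purifications, with a
#' small background factor (default 0.1) added unconditionally to the
#' control mean. The addition prevents division by zero for preys never
#' seen in any control and keeps the statistic continuous in the data.
#'
#' @param baitCounts,controlCounts non-negative integer spectral counts.
#' @param backgroundFactor smoothing constant added to the control mean.
#' @return the (positive) fold change.
#' @examples
#' foldChange(c(5, 5), rep(0, 161))  # 50
#' foldChange(c(4, 6), c(1, 1, 1))   # 5 / 1.1
#' @export
foldChange <- function(baitCounts, controlCounts, backgroundFactor = 0.1) {
  if (!length(baitCounts) || !length(controlCounts))
    stop("baitCounts and controlCounts must be non-empty")
  if (any(baitCounts < 0) || any(controlCounts < 0))
    stop("spectral counts must be non-negative")
  if (backgroundFactor <= 0) stop("backgroundFactor must be positive")
  mean(baitCounts) / (mean(controlCounts) + backgroundFactor)
}

#' Per-replicate interaction probability
#'
#' Posterior probability that one bait run's spectral count for a prey
#' arises from a true-interaction Poisson component rather than the
#' background component estimated from the negative-control panel.
#'
#' The default `poisson_mixture` scorer is a deliberately simple
#' two-component model: background rate `lambda0 = max(mean(controls),
#' backgroundFactor)`; true-interaction rate `lambda1 = max(baitCount,
#' lambda0 * foldFloor)` (the observed count as the rate estimate,
#' floored at `foldFloor` times background so low counts cannot shrink
#' the alternative below the null); and
#' `p = dpois(k, lambda1) * prior / (dpois(k, lambda1) * prior +
#' dpois(k, lambda0) * (1 - prior))`. It is a documented stand-in
#' exposing the same interface as heavier interactome scorers, so an
#' external backend can be slotted in; it makes no claim of replicating
#' any particular one. The `fold_only` scorer maps the smoothed fold
#' change through `fc / (1 + fc)` as a crude monotone score.
#'
#' @param baitCount spectral count of the prey in one bait run.
#' @param controlCounts counts of the prey across the control panel (the
#'   mixture scorer requires at least 5 control runs).
#' @param scorer `"poisson_mixture"` or `"fold_only"`.
#' @param prior prior probability of a true interaction (default 0.1).
#' @param foldFloor floor on `lambda1 / lambda0` (default 2).
#' @param backgroundFactor floor on the background rate / smoothing for
#'   `fold_only`.
#' @return a probability in \[0, 1\].
#' @examples
#' scoreReplicate(20, rep(0, 161))   # ~1: never seen in controls
#' scoreReplicate(0, rep(0, 161))    # below the prior: no evidence
#' @export
scoreReplicate <- function(baitCount, controlCounts,
                           scorer = c("poisson_mixture", "fold_only"),
                           prior = 0.1, foldFloor = 2,
                           backgroundFactor = 0.1) {
  scorer <- match.arg(scorer)
  if (baitCount < 0 || baitCount != round(baitCount))
    stop("baitCount must be a non-negative integer")
  if (scorer == "fold_only") {
    fc <- foldChange(baitCount, controlCounts, backgroundFactor)
    return(fc / (1 + fc))
  }
  if (length(controlCounts) < 5)
    stop("poisson_mixture requires at least 5 control runs")
  lam0 <- max(mean(controlCounts), backgroundFactor)
  lam1 <- max(baitCount, lam0 * foldFloor)
  # log-space for numerical safety at large counts
  l1 <- dpois(baitCount, lam1, log = TRUE) + log(prior)
  l0 <- dpois(baitCount, lam0, log = TRUE) + log(1 - prior)
  m <- max(l1, l0)
  exp(l1 - m) / (exp(l1 - m) + exp(l0 - m))
}

#' Scoring configuration for AP-MS interaction calling
#'
#' @param background_factor smoothing constant for [foldChange()] and
#'   the background-rate floor (default 0.1).
#' @param avgp_threshold inclusive AvgP pass threshold (default 0.89,
#'   the stringent cutoff used for the final interactome list).
#' @param enhancement_ratio fold-change ratio declaring an interaction
#'   condition-enhanced (default 2).
#' @param scorer per-replicate scorer, see [scoreReplicate()].
#' @param prior,fold_floor mixture-scorer parameters.
#' @return a validated list of class `ScoringConfig`.
#' @export
scoringConfig <- function(background_factor = 0.1, avgp_threshold = 0.89,
                          enhancement_ratio = 2,
                          scorer = c("poisson_mixture", "fold_only"),
                          prior = 0.1, fold_floor = 2) {
  scorer <- match.arg(scorer)
  if (background_factor <= 0) stop("background_factor must be positive")
  if (avgp_threshold <= 0 || avgp_threshold >= 1)
    stop("avgp_threshold must lie in (0,1)")
  if (enhancement_ratio <= 1) stop("enhancement_ratio must exceed 1")
  structure(list(background_factor = background_factor,
                 avgp_threshold = avgp_threshold,
                 enhancement_ratio = enhancement_ratio,
                 scorer = scorer, prior = prior, fold_floor = fold_floor),
            class = "ScoringConfig")
}

#' Score all bait-prey interactions for one condition
#'
#' For every prey: per-bait-replicate probabilities
#' ([scoreReplicate()]), their arithmetic mean AvgP (the final score),
#' the smoothed fold change over that condition's bait runs, and the
#' pass flag `avgp >= avgp_threshold` (inclusive). Rows are sorted by
#' AvgP descending, ties broken by fold change descending, then by prey
#' identifier, so the ordering is total and deterministic.
#'
#' @param scm a [SpectralCountMatrix].
#' @param config a [scoringConfig()].
#' @param condition bait condition to score (`"mock"`, `"stimulated"` or
#'   `"na"`).
#' @return data.frame with `prey`, `fold_change`, `p_rep1..k`, `avgp`,
#'   `passes`, `enhancement` (`"na"` until [classifyEnhancement()]).
#' @examples
#' sim <- simulateApms(apmsSimConfig(n_preys = 100, n_controls = 20, seed = 1))
#' head(scoreInteractions(sim$counts, condition = "mock"))
#' @export
scoreInteractions <- function(scm, config = scoringConfig(),
                              condition = c("mock", "stimulated", "na")) {
  condition <- match.arg(condition)
  stopifnot(is(scm, "SpectralCountMatrix"),
            inherits(config, "ScoringConfig"))
  ri <- runInfo(scm)
  bait_j <- which(ri$kind == "bait" & ri$condition == condition)
  ctrl_j <- which(ri$kind == "control")
  if (!length(bait_j))
    stop("no bait runs for condition '", condition, "'")
  k <- assay(scm, "counts")
  preys <- rownames(k)
  if (is.null(preys)) preys <- sprintf("prey%04d", seq_len(nrow(k)))

  pmat <- vapply(bait_j, function(j)
    vapply(seq_len(nrow(k)), function(i)
      scoreReplicate(k[i, j], k[i, ctrl_j], scorer = config$scorer,
                     prior = config$prior, foldFloor = config$fold_floor,
                     backgroundFactor = config$background_factor),
      numeric(1)),
    numeric(nrow(k)))
  pmat <- matrix(pmat, nrow = nrow(k))
  avgp <- rowMeans(pmat)
  fc <- vapply(seq_len(nrow(k)), function(i)
    foldChange(k[i, bait_j], k[i, ctrl_j], config$background_factor),
    numeric(1))

  out <- data.frame(prey = preys, fold_change = fc,
                    stringsAsFactors = FALSE)
  for (r in seq_along(bait_j)) out[[paste0("p_rep", r)]] <- pmat[, r]
  out$avgp <- avgp
  out$passes <- avgp >= config$avgp_threshold
  out$enhancement <- "na"
  out <- out[order(-out$avgp, -out$fold_change, out$prey), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "condition") <- condition
  attr(out, "config") <- unclass(config)
  out
}

#' Classify condition enhancement of scored interactions
#'
#' Compares one prey universe scored under two conditions. For preys
#' passing the AvgP gate in either condition: an interaction passing
#' only under stimulation is `enhanced` and one passing only in mock is
#' `reduced` (presence/absence dominates); otherwise the fold-change
#' ratio decides: `enhanced` if `fc_stim / fc_mock >= ratio`, `reduced`
#' if `<= 1/ratio`, else `unchanged`. Preys passing in neither condition
#' keep `"na"`.
#'
#' @param scoresMock,scoresStim outputs of [scoreInteractions()] over
#'   the same preys.
#' @param ratio enhancement ratio (default 2; the cutoff is an explicit
#'   package convention, recorded in the output attributes).
#' @return merged data.frame with `_mock`/`_stim` columns and
#'   `enhancement` in `c("enhanced", "unchanged", "reduced", "na")`.
#' @export
classifyEnhancement <- function(scoresMock, scoresStim, ratio = 2) {
  if (!setequal(scoresMock$prey, scoresStim$prey))
    stop("prey universes differ between the two conditions")
  m <- scoresMock[order(scoresMock$prey),
                  c("prey", "fold_change", "avgp", "passes")]
  s <- scoresStim[order(scoresStim$prey),
                  c("prey", "fold_change", "avgp", "passes")]
  out <- data.frame(prey = m$prey,
                    fold_change_mock = m$fold_change,
                    fold_change_stim = s$fold_change,
                    avgp_mock = m$avgp, avgp_stim = s$avgp,
                    passes_mock = m$passes, passes_stim = s$passes,
                    stringsAsFactors = FALSE)
  fc_ratio <- out$fold_change_stim / out$fold_change_mock
  enh <- rep("na", nrow(out))
  any_pass <- out$passes_mock | out$passes_stim
  only_stim <- out$passes_stim & !out$passes_mock
  only_mock <- out$passes_mock & !out$passes_stim
  enh[any_pass] <- "unchanged"
  enh[any_pass & fc_ratio >= ratio] <- "enhanced"
  enh[any_pass & fc_ratio <= 1 / ratio] <- "reduced"
  enh[only_stim] <- "enhanced"
  enh[only_mock] <- "reduced"
  out$enhancement <- enh
  attr(out, "enhancement_ratio") <- ratio
  out
}
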