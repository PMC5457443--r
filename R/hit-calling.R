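# Viability gate: wells keeping at least 70% of the negative-control CTG
# signal are considered viable; pools losing more than 30% viability are
# excluded from hit statistics.
VIABILITY_THRESHOLD <- 0.7

#' Viability-normalized well table
#'
#' Computes, for every non-empty well of every replicate, the normalized
#' reporter value `N = lucia / ctg`, its log2, and the viability ratio
#' `ctg / mean(ctg of the plate's negative-control wells)`. A well is
#' `viable` when its viability ratio is at least 0.7 (i.e. it lost no
#' more than 30% viability relative to the non-targeting controls, the
#' natural baseline). Wells with non-positive or missing CTG are flagged
#' `valid = FALSE`, excluded downstream, and reported via a warning.
#'
#' @param ps a [PlateSet].
#' @return a long data.frame with one row per non-empty well per
#'   replicate: layout columns plus `lucia`, `ctg`, `N`, `log2N`,
#'   `viability_ratio`, `viable`, `valid`.
#' @examples
#' sim <- simulateScreen(screenSimConfig(n_genes = 320, seed = 1))
#' head(normalizePlates(sim$plates))
#' @export
normalizePlates <- function(ps) {
  lay <- plateLayout(ps)
  lu <- assay(ps, "lucia")
  ct <- assay(ps, "ctg")
  nonempty <- lay$role != "empty"
  out <- do.call(rbind, lapply(seq_len(ncol(ps)), function(r) {
    df <- cbind(replicate = r, lay[nonempty, , drop = FALSE])
    df$lucia <- lu[nonempty, r]
    df$ctg <- ct[nonempty, r]
    df
  }))
  out$valid <- is.finite(out$ctg) & out$ctg > 0 & is.finite(out$lucia)
  if (any(!out$valid))
    warning(sum(!out$valid), " well(s) with non-positive or missing CTG ",
            "excluded, e.g. ", out$plate_id[!out$valid][1L], ":",
            out$well[!out$valid][1L])
  out$N <- ifelse(out$valid, out$lucia / out$ctg, NA_real_)
  out$log2N <- log2(out$N)
  grp <- paste(out$replicate, out$plate_id)
  neg <- out$role == "negative_control" & out$valid
  neg_mean <- tapply(out$ctg[neg], grp[neg], mean)
  if (any(!unique(grp) %in% names(neg_mean)))
    stop("plate without usable negative-control wells")
  out$viability_ratio <- out$ctg / as.numeric(neg_mean[grp])
  out$viable <- out$valid & out$viability_ratio >= VIABILITY_THRESHOLD
  rownames(out) <- NULL
  out
}

#' Per-plate z-scores of log2 N
#'
#' Standardizes `log2N` on a per-plate, per-replicate basis:
#' `z = (log2N - center) / scale`, where center and scale are the mean
#' and sample SD (or median and 1.4826 * MAD when `robust = TRUE`) of
#' that plate's *viable experimental* wells. Control wells and wells
#' failing the viability gate receive no z-score: controls would bias the
#' plate center, and pools that kill cells contribute no evidence. The
#' log base is immaterial to z-values (standardization is affine
#' invariant).
#'
#' @param normWells output of [normalizePlates()].
#' @param robust use median/MAD instead of mean/SD.
#' @return `normWells` with a `z` column (NA outside the scored set).
#' @export
plateZScores <- function(normWells, robust = FALSE) {
  out <- normWells
  out$z <- NA_real_
  for (g in unique(paste(out$replicate, out$plate_id))) {
    in_g <- paste(out$replicate, out$plate_id) == g
    base <- in_g & out$role == "experimental" & out$viable &
      is.finite(out$log2N)
    if (sum(base) < 10)
      stop("plate group ", g, ": fewer than 10 usable experimental wells")
    x <- out$log2N[base]
    if (robust) {
      center <- median(x); scale <- mad(x)  # mad() includes the 1.4826
    } else {
      center <- mean(x); scale <- sd(x)
    }
    if (scale == 0)
      stop("degenerate plate group ", g, ": zero spread in log2N")
    out$z[base] <- (x - center) / scale
  }
  out
}

#' Primary SMARTpool hit calling
#'
#' Applies the replicate-concordance hit rule to a SMARTpool screen:
#' after dropping (plate, replicate) pairs that fail Z' QC and wells that
#' fail the 30% viability gate, a gene is called `down` if its per-plate
#' z-score is `<= zLow` in at least `minReplicates` replicates, `up` if
#' `>= zHigh` in at least `minReplicates` (both thresholds inclusive).
#' A gene crossing both thresholds in different replicates is never a
#' hit; it is reported as `none` with `discordant = TRUE`. Genes covered
#' by fewer than `minReplicates` QC-passing replicates are marked
#' `callable = FALSE` rather than dropped.
#'
#' The defaults (-2, +3) follow the asymmetric rule used to assemble the
#' published primary hit list; both cutoffs are configurable.
#'
#' @param ps a smartpool-mode [PlateSet].
#' @param zLow,zHigh inclusive z-score cutoffs for down/up calls.
#' @param minReplicates replicates that must agree (default 2 of 3).
#' @param qcMetric,qcThreshold passed to [qcPlates()]; failing plate
#'   replicates are excluded before scoring.
#' @param robust passed to [plateZScores()].
#' @return a hit-table data.frame with one row per gene: per-replicate
#'   z-scores (`z_1`, ...), viability flags (`viable_1`, ...), support
#'   counts, `discordant`, `callable` and `primary_call` in
#'   `c("up", "down", "none")`.
#' @examples
#' sim <- simulateScreen(screenSimConfig(n_genes = 320, seed = 1))
#' hits <- callPrimary(sim$plates)
#' table(hits$primary_call)
#' @export
callPrimary <- function(ps, zLow = -2, zHigh = 3, minReplicates = 2,
                        qcMetric = "normalized_N", qcThreshold = 0.2,
                        robust = FALSE) {
  if (screenMode(ps) != "smartpool")
    stop("callPrimary() expects a smartpool-mode PlateSet")
  qc <- qcPlates(ps, metric = qcMetric, threshold = qcThreshold)
  ok_pr <- paste(qc$replicate, qc$plate_id)[qc$pass]
  nw <- normalizePlates(ps)
  nw <- nw[paste(nw$replicate, nw$plate_id) %in% ok_pr, , drop = FALSE]
  if (!nrow(nw)) stop("no plate passed QC")
  nw <- plateZScores(nw, robust = robust)
  ex <- nw[nw$role == "experimental", , drop = FALSE]

  genes <- sort(unique(plateLayout(ps)$gene[
    plateLayout(ps)$role == "experimental"]))
  reps <- seq_len(ncol(ps))
  zmat <- matrix(NA_real_, length(genes), length(reps),
                 dimnames = list(genes, reps))
  vmat <- matrix(NA, length(genes), length(reps),
                 dimnames = list(genes, reps))
  idx <- cbind(match(ex$gene, genes), ex$replicate)
  zmat[idx] <- ex$z
  vmat[idx] <- ex$viable
  # replicates whose plate covered the gene and passed QC
  gene_plate <- plateLayout(ps)$plate_id[
    match(genes, plateLayout(ps)$gene)]
  qc_pass_n <- vapply(seq_along(genes), function(i)
    sum(paste(reps, gene_plate[i]) %in% ok_pr), integer(1))

  n_down <- rowSums(zmat <= zLow, na.rm = TRUE)
  n_up <- rowSums(zmat >= zHigh, na.rm = TRUE)
  discordant <- rowSums(zmat <= zLow, na.rm = TRUE) > 0 &
    rowSums(zmat >= zHigh, na.rm = TRUE) > 0
  call <- rep("none", length(genes))
  call[n_down >= minReplicates & !discordant] <- "down"
  call[n_up >= minReplicates & !discordant] <- "up"
  callable <- qc_pass_n >= minReplicates
  call[!callable] <- "none"

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (r in reps) out[[paste0("z_", r)]] <- zmat[, r]
  for (r in reps) out[[paste0("viable_", r)]] <- vmat[, r]
  out$n_down <- as.integer(n_down)
  out$n_up <- as.integer(n_up)
  out$n_supporting <- as.integer(ifelse(call == "down", n_down,
                                        ifelse(call == "up", n_up, 0L)))
  out$discordant <- discordant
  out$callable <- callable
  out$primary_call <- call
  rownames(out) <- NULL
  out
}

#' Secondary (deconvolution) hit confirmation
#'
#' Confirms genes from a 4-duplex deconvolution screen. Per duplex, the
#' activity ratio is `N / mean(N of the plate's negative controls)`,
#' averaged across replicates. A duplex passes downward if its ratio is
#' at most `1 - changeFraction` (reporter reduced by 60% at the default)
#' AND falls outside `mean +/- sdMult * SD` of the negative-control
#' ratios (both conditions are required; they are presented as one
#' criterion), AND its viability loss does not exceed
#' `maxViabilityLoss`; upward passes are symmetric. A gene is confirmed
#' when at least `minDuplexes` duplexes pass in the same direction;
#' duplexes passing in opposite directions set `discordant = TRUE`.
#'
#' @param ps a deconvolution-mode [PlateSet].
#' @param changeFraction required fractional change in reporter activity
#'   (default 0.6).
#' @param sdMult width of the negative-control band in SDs (default 2).
#' @param minDuplexes duplexes that must agree (default 2 of 4).
#' @param maxViabilityLoss maximum tolerated viability loss (default
#'   0.3).
#' @param strict error (rather than warn) on genes without exactly 4
#'   duplexes.
#' @return a hit-table data.frame: per-duplex ratios and pass flags,
#'   pass counts per direction, `direction`, `discordant`, `confirmed`.
#' @examples
#' cfg <- screenSimConfig(seed = 3)
#' sim <- simulateDeconvolution(cfg, sprintf("G%04d", 1:20), 4)
#' sum(callSecondary(sim$plates)$confirmed)
#' @export
callSecondary <- function(ps, changeFraction = 0.6, sdMult = 2,
                          minDuplexes = 2, maxViabilityLoss = 0.3,
                          strict = TRUE) {
  if (screenMode(ps) != "deconvolution")
    stop("callSecondary() expects a deconvolution-mode PlateSet")
  nw <- normalizePlates(ps)
  # negative-control activity ratios pooled across replicates, per plate
  neg <- nw[nw$role == "negative_control" & nw$valid, , drop = FALSE]
  neg_meanN <- tapply(neg$N, neg$plate_id, mean)
  neg_ratio_sd <- vapply(names(neg_meanN), function(p)
    sd(neg$N[neg$plate_id == p] / neg_meanN[[p]]), numeric(1))

  ex <- nw[nw$role == "experimental" & nw$valid, , drop = FALSE]
  ex$ratio <- ex$N / as.numeric(neg_meanN[ex$plate_id])
  # per-duplex aggregation across replicates
  agg <- aggregate(cbind(ratio, viability_ratio) ~ gene + sirna_id + plate_id,
                   data = ex, FUN = mean)
  n_dup <- table(agg$gene)
  if (any(n_dup != 4L)) {
    msg <- paste0("genes without exactly 4 duplexes: ",
                  paste(names(n_dup)[n_dup != 4L], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  band <- sdMult * as.numeric(neg_ratio_sd[agg$plate_id])
  viable_ok <- (1 - agg$viability_ratio) <= maxViabilityLoss
  agg$pass_down <- agg$ratio <= (1 - changeFraction) &
    agg$ratio < (1 - band) & viable_ok
  agg$pass_up <- agg$ratio >= (1 + changeFraction) &
    agg$ratio > (1 + band) & viable_ok

  genes <- sort(unique(agg$gene))
  out <- do.call(rbind, lapply(genes, function(g) {
    d <- agg[agg$gene == g, , drop = FALSE]
    d <- d[order(d$sirna_id), , drop = FALSE]
    nd <- sum(d$pass_down); nu <- sum(d$pass_up)
    direction <- if (nd == 0 && nu == 0) "none"
                 else if (nd >= nu) "down" else "up"
    row <- data.frame(gene = g, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(d))) {
      row[[paste0("ratio_", k)]] <- d$ratio[k]
      row[[paste0("pass_", k)]] <-
        if (direction == "up") d$pass_up[k] else d$pass_down[k]
    }
    row$n_pass_down <- nd
    row$n_pass_up <- nu
    row$direction <- direction
    row$discordant <- nd > 0 && nu > 0
    row$confirmed <- max(nd, nu) >= minDuplexes
    row
  }))
  rownames(out) <- NULL
  out
}
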