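#' Z'-factor of a control separation
#'
#' The HTS assay-window statistic
#' `Z' = 1 - 3 * (SD_pos + SD_neg) / |mean_pos - mean_neg|`,
#' computed with sample standard deviations (n-1 denominator, the HTS
#' community convention). `Z' = 1` for noise-free, separated controls;
#' values above the acceptance threshold (0.2 here) indicate a usable
#' window; overlapping controls give negative values.
#'
#' @param pos,neg numeric readouts of the positive and negative control
#'   wells (at least 2 each).
#' @return the Z' value (dimensionless, always <= 1).
#' @examples
#' zPrime(c(90, 100, 110), c(0, 10, 20))  # 1/3
#' @export
zPrime <- function(pos, neg) {
  pos <- pos[is.finite(pos)]
  neg <- neg[is.finite(neg)]
  if (length(pos) < 2 || length(neg) < 2)
    stop("insufficient controls: need at least 2 finite values per group")
  sep <- abs(mean(pos) - mean(neg))
  if (sep == 0)
    stop("undefined separation: control means are equal")
  1 - 3 * (sd(pos) + sd(neg)) / sep
}

#' Per-plate Z' quality control of a PlateSet
#'
#' Computes the Z' factor for every (plate, replicate) pair from its
#' positive- and negative-control wells and applies the acceptance gate.
#' The comparison is strict: a plate passes only if `zprime > threshold`.
#' By default the metric is the viability-normalized ratio N = Lucia/CTG
#' (the quantity hit calling operates on); `metric = "raw_lucia"` uses
#' the raw reporter channel instead.
#'
#' @param ps a [PlateSet].
#' @param metric `"normalized_N"` or `"raw_lucia"`.
#' @param threshold acceptance threshold (default 0.2; plates with Z'
#'   above it are considered acceptable for high-throughput screening).
#' @return data.frame with one row per plate x replicate: `plate_id`,
#'   `replicate`, `zprime`, `pass`, `n_pos`, `n_neg`.
#' @examples
#' sim <- simulateScreen(screenSimConfig(n_genes = 320, seed = 1))
#' qcPlates(sim$plates)
#' @export
qcPlates <- function(ps, metric = c("normalized_N", "raw_lucia"),
                     threshold = 0.2) {
  metric <- match.arg(metric)
  lay <- plateLayout(ps)
  lu <- assay(ps, "lucia")
  val <- if (metric == "normalized_N") lu / assay(ps, "ctg") else lu
  out <- do.call(rbind, lapply(plateIds(ps), function(p) {
    pos_i <- which(lay$plate_id == p & lay$role == "positive_control")
    neg_i <- which(lay$plate_id == p & lay$role == "negative_control")
    if (length(pos_i) < 2 || length(neg_i) < 2)
      stop("plate ", p, " lacks the control wells required for Z'")
    do.call(rbind, lapply(seq_len(ncol(ps)), function(r) {
      zp <- zPrime(val[pos_i, r], val[neg_i, r])
      data.frame(plate_id = p, replicate = r, zprime = zp,
                 pass = zp > threshold,
                 n_pos = length(pos_i), n_neg = length(neg_i))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise replicate concordance (R-squared)
#'
#' Squared Pearson correlation of a per-well statistic between every
#' unordered pair of replicates, computed over experimental wells only.
#' High pairwise R-squared across the replicate plate sets indicates a
#' reproducible screen.
#'
#' @param ps a [PlateSet] with at least 2 replicates.
#' @param on `"log2N"` (log2 of the Lucia/CTG ratio, the scale hit
#'   calling works on) or `"z"` (per-plate z-scores; [plateZScores()]
#'   viability gating applies, so only wells scored in both replicates
#'   enter).
#' @return data.frame with `rep_i`, `rep_j`, `r_squared`, `n_wells`.
#' @export
replicateR2 <- function(ps, on = c("log2N", "z")) {
  on <- match.arg(on)
  if (ncol(ps) < 2) stop("need at least 2 replicates")
  nw <- normalizePlates(ps)
  if (on == "z") nw <- plateZScores(nw)
  stat <- if (on == "z") nw$z else nw$log2N
  keep <- nw$role == "experimental"
  key <- paste(nw$plate_id, nw$well)[keep]
  reps <- sort(unique(nw$replicate))
  wide <- matrix(NA_real_, length(unique(key)), length(reps),
                 dimnames = list(unique(key), reps))
  wide[cbind(match(key, rownames(wide)), match(nw$replicate[keep], reps))] <-
    stat[keep]
  pairs <- utils::combn(seq_along(reps), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    x <- wide[, i]; y <- wide[, j]
    ok <- is.finite(x) & is.finite(y)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      stop("undefined correlation: zero variance in replicate ",
           reps[i], " or ", reps[j])
    data.frame(rep_i = reps[i], rep_j = reps[j],
               r_squared = cor(x[ok], y[ok])^2, n_wells = sum(ok))
  }))
  rownames(out) <- NULL
  out
}
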