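# Hand-built PlateSets with exactly controlled well values (no noise),
# used to exercise normalization, z-scoring and the hit rules against
# values computable by hand.

# One plate, genes placed from column 3 onward row-major; 4 negative and
# 4 positive control wells with per-replicate lucia values. `gene_mult`
# is a genes x replicates matrix of multipliers on baseline lucia;
# ctg is constant so N is proportional to the multiplier.
make_manual_plateset <- function(gene_mult,
                                 neg_lucia = c(900, 950, 1050, 1100),
                                 pos_lucia = c(180, 190, 210, 220),
                                 baseline_lucia = 1000, ctg = 2000,
                                 plate_id = "T01") {
  n_genes <- nrow(gene_mult)
  n_rep <- ncol(gene_mult)
  stopifnot(n_genes <= 320)
  genes <- rownames(gene_mult)
  if (is.null(genes)) genes <- sprintf("GENE%03d", seq_len(n_genes))
  ctrl <- data.frame(plate_id = plate_id,
                     row = rep(LETTERS[1:4], 2),
                     column = rep(1:2, each = 4),
                     role = rep(c("negative_control", "positive_control"),
                                each = 4),
                     gene = NA_character_, sirna_id = NA_character_)
  grid <- expand.grid(column = 3:22, row = LETTERS[1:16],
                      stringsAsFactors = FALSE)[seq_len(n_genes),
                                                c("row", "column")]
  expd <- data.frame(plate_id = plate_id, row = grid$row,
                     column = grid$column, role = "experimental",
                     gene = genes, sirna_id = NA_character_)
  layout <- rbind(ctrl, expd)
  ctrl_vals <- function(v) if (is.matrix(v)) v else matrix(v, 4, n_rep)
  lucia <- rbind(ctrl_vals(neg_lucia), ctrl_vals(pos_lucia),
                 baseline_lucia * gene_mult)
  ctgm <- matrix(ctg, nrow(layout), n_rep)
  PlateSet(lucia, ctgm, layout, "smartpool")
}

# Deconvolution analogue: `duplex_mult` is a (genes*4) x replicates
# matrix (rows grouped by gene, duplexes d1..d4) of activity multipliers.
make_manual_deconv <- function(genes, duplex_mult,
                               neg_lucia = c(950, 975, 1025, 1050),
                               pos_lucia = c(190, 195, 205, 210),
                               baseline_lucia = 1000, ctg = 2000,
                               ctg_mult = NULL, plate_id = "TD1") {
  n_rep <- ncol(duplex_mult)
  gene_vec <- rep(genes, each = 4)
  duplex <- sprintf("%s_d%d", gene_vec, rep(1:4, length(genes)))
  ctrl <- data.frame(plate_id = plate_id,
                     row = rep(LETTERS[1:4], 2),
                     column = rep(1:2, each = 4),
                     role = rep(c("negative_control", "positive_control"),
                                each = 4),
                     gene = NA_character_, sirna_id = NA_character_)
  grid <- expand.grid(column = 3:22, row = LETTERS[1:16],
                      stringsAsFactors = FALSE)[seq_along(gene_vec),
                                                c("row", "column")]
  expd <- data.frame(plate_id = plate_id, row = grid$row,
                     column = grid$column, role = "experimental",
                     gene = gene_vec, sirna_id = duplex)
  layout <- rbind(ctrl, expd)
  ctrl_vals <- function(v) if (is.matrix(v)) v else matrix(v, 4, n_rep)
  lucia <- rbind(ctrl_vals(neg_lucia), ctrl_vals(pos_lucia),
                 baseline_lucia * duplex_mult)
  ctgm <- matrix(ctg, nrow(layout), n_rep)
  if (!is.null(ctg_mult))
    ctgm[8 + seq_len(nrow(duplex_mult)), ] <- ctg * ctg_mult
  PlateSet(lucia, ctgm, layout, "deconvolution")
}

# Independent re-implementation of the primary hit rule, used as a
# brute-force oracle against callPrimary(): operates on a plain z matrix.
oracle_primary_call <- function(zmat, z_low = -2, z_high = 3, min_rep = 2) {
  apply(zmat, 1, function(z) {
    nd <- sum(z <= z_low, na.rm = TRUE)
    nu <- sum(z >= z_high, na.rm = TRUE)
    if (nd > 0 && nu > 0) return("none")
    if (nd >= min_rep) return("down")
    if (nu >= min_rep) return("up")
    "none"
  })
}

# Small AP-MS matrix with fully specified counts.
make_manual_scm <- function(bait_mock, bait_stim, controls) {
  counts <- cbind(bait_mock, bait_stim, controls)
  n_mock <- ncol(as.matrix(bait_mock))
  n_stim <- ncol(as.matrix(bait_stim))
  n_ctrl <- ncol(as.matrix(controls))
  runs <- data.frame(
    run_id = c(sprintf("bm%d", seq_len(n_mock)),
               sprintf("bs%d", seq_len(n_stim)),
               sprintf("c%03d", seq_len(n_ctrl))),
    kind = c(rep("bait", n_mock + n_stim), rep("control", n_ctrl)),
    condition = c(rep("mock", n_mock), rep("stimulated", n_stim),
                  rep("na", n_ctrl)),
    replicate = c(seq_len(n_mock), seq_len(n_stim), seq_len(n_ctrl)))
  SpectralCountMatrix(counts, runs)
}
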