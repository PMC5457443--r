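# 384-well geometry and the well roles a valid screening plate may carry.
PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
WELL_ROLES <- c("experimental", "negative_control", "positive_control",
                "toxicity_control", "empty")
LAYOUT_COLUMNS <- c("plate_id", "row", "column", "role", "gene", "sirna_id")

#' PlateSet: replicated, annotated 384-well screening plates
#'
#' A `PlateSet` holds the paired Lucia-luciferase (reporter) and
#' CellTiter-Glo (viability) readouts of one screening run. It extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are wells (all plates
#' stacked), columns are screen replicates, and the two assays are `lucia`
#' and `ctg`. The plate layout (plate id, row letter A-P, column 1-24, well
#' role, targeted gene, siRNA duplex id) lives in `rowData`, so replicates
#' share one layout by construction, as in an arrayed screen.
#'
#' Validity requires: rows A-P and columns 1-24; unique (plate, row,
#' column) addresses; at least 4 negative-control and 4 positive-control
#' wells per plate (needed for the Z' factor and the 2xSD secondary rule);
#' a gene annotation on every experimental well; finite `lucia >= 0` and
#' `ctg > 0` on every non-empty well; and, in deconvolution mode, exactly
#' 4 distinct duplexes per gene.
#'
#' @param lucia,ctg numeric well-by-replicate matrices of raw luminescence
#'   (relative light units).
#' @param layout data.frame with columns `plate_id`, `row`, `column`,
#'   `role`, `gene`, `sirna_id`, one row per well, aligned with the assay
#'   rows.
#' @param screenMode `"smartpool"` (1 gene/well primary screen) or
#'   `"deconvolution"` (4 duplex wells/gene secondary screen).
#' @param x a `PlateSet`.
#'
#' @return `PlateSet()` returns a validated `PlateSet`. `plateLayout()`
#'   returns the layout as a plain data.frame, `plateIds()` the plate
#'   identifiers, `nReplicates()` the number of replicate plate sets and
#'   `screenMode()` the screen mode string.
#' @examples
#' ps <- simulateScreen(screenSimConfig(n_genes = 320, seed = 1))$plates
#' ps
#' head(plateLayout(ps))
#' @aliases PlateSet
#' @export PlateSet
#' @exportClass PlateSet
setClass("PlateSet", contains = "SummarizedExperiment")

.validPlateSet <- function(object) {
  msg <- character()
  if (!all(c("lucia", "ctg") %in% assayNames(object)))
    return("assays 'lucia' and 'ctg' are required")
  lay <- rowData(object)
  if (!all(LAYOUT_COLUMNS %in% colnames(lay)))
    return(paste0("rowData must contain: ",
                  paste(LAYOUT_COLUMNS, collapse = ", ")))
  mode <- metadata(object)$screen_mode
  if (is.null(mode) || !mode %in% c("smartpool", "deconvolution"))
    msg <- c(msg, "metadata screen_mode must be 'smartpool' or 'deconvolution'")
  if (!all(lay$row %in% PLATE_ROWS))
    msg <- c(msg, "well rows must be letters A-P")
  if (!all(lay$column %in% PLATE_COLS))
    msg <- c(msg, "well columns must be integers 1-24")
  addr <- paste(lay$plate_id, lay$row, lay$column)
  if (anyDuplicated(addr))
    msg <- c(msg, paste0("duplicate well address: ",
                         addr[duplicated(addr)][1L]))
  if (!all(lay$role %in% WELL_ROLES))
    msg <- c(msg, paste0("unknown well role(s): ",
                         paste(setdiff(unique(lay$role), WELL_ROLES),
                               collapse = ", ")))
  exper <- lay$role == "experimental"
  if (any(exper & (is.na(lay$gene) | lay$gene == "")))
    msg <- c(msg, "every experimental well must carry a gene annotation")
  for (p in unique(lay$plate_id)) {
    on_p <- lay$plate_id == p
    if (sum(on_p & lay$role == "negative_control") < 4L)
      msg <- c(msg, paste0("plate ", p, ": fewer than 4 negative-control wells"))
    if (sum(on_p & lay$role == "positive_control") < 4L)
      msg <- c(msg, paste0("plate ", p, ": fewer than 4 positive-control wells"))
  }
  nonempty <- lay$role != "empty"
  lu <- assay(object, "lucia")[nonempty, , drop = FALSE]
  ct <- assay(object, "ctg")[nonempty, , drop = FALSE]
  if (any(!is.finite(lu)) || any(lu < 0))
    msg <- c(msg, "lucia must be finite and >= 0 on all non-empty wells")
  if (any(!is.finite(ct)) || any(ct <= 0))
    msg <- c(msg, "ctg must be finite and > 0 on all non-empty wells")
  if (identical(mode, "deconvolution")) {
    genes <- lay$gene[exper]
    ids <- lay$sirna_id[exper]
    if (any(is.na(ids)))
      msg <- c(msg, "deconvolution wells must carry sirna_id")
    else {
      per_gene <- tapply(ids, genes, function(v) length(unique(v)))
      bad <- names(per_gene)[per_gene != 4L]
      if (length(bad))
        msg <- c(msg, paste0("deconvolution genes without exactly 4 duplexes: ",
                             paste(utils::head(bad, 3L), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("PlateSet", .validPlateSet)

PlateSet <- function(lucia, ctg, layout,
                     screenMode = c("smartpool", "deconvolution")) {
  screenMode <- match.arg(screenMode)
  lucia <- as.matrix(lucia)
  ctg <- as.matrix(ctg)
  storage.mode(lucia) <- "double"
  storage.mode(ctg) <- "double"
  layout <- as.data.frame(layout)
  rownames(layout) <- NULL
  if (!all(LAYOUT_COLUMNS %in% colnames(layout)))
    stop("layout must contain columns: ",
         paste(LAYOUT_COLUMNS, collapse = ", "))
  layout$column <- as.integer(layout$column)
  if (nrow(lucia) != nrow(layout) || !identical(dim(lucia), dim(ctg)))
    stop("lucia/ctg dimensions must agree with the layout")
  well <- sprintf("%s%02d", layout$row, layout$column)
  rn <- paste(layout$plate_id, well, sep = ":")
  dimnames(lucia) <- list(rn, paste0("rep", seq_len(ncol(lucia))))
  dimnames(ctg) <- dimnames(lucia)
  se <- SummarizedExperiment(
    assays = list(lucia = lucia, ctg = ctg),
    rowData = DataFrame(layout[, LAYOUT_COLUMNS], well = well),
    colData = DataFrame(replicate = seq_len(ncol(lucia)),
                        row.names = colnames(lucia)))
  metadata(se)$screen_mode <- screenMode
  new("PlateSet", se)
}

#' @rdname PlateSet-class
#' @export
setMethod("screenMode", "PlateSet", function(x) metadata(x)$screen_mode)

#' @rdname PlateSet-class
#' @export
setMethod("plateLayout", "PlateSet",
          function(x) as.data.frame(rowData(x)))

#' @rdname PlateSet-class
#' @export
setMethod("plateIds", "PlateSet",
          function(x) unique(rowData(x)$plate_id))

#' @rdname PlateSet-class
#' @export
setMethod("nReplicates", "PlateSet", function(x) ncol(x))

setMethod("show", "PlateSet", function(object) {
  lay <- rowData(object)
  cat("PlateSet (", metadata(object)$screen_mode, " screen)\n", sep = "")
  cat("  plates: ", length(unique(lay$plate_id)),
      "  replicates: ", ncol(object),
      "  wells/replicate: ", nrow(object), "\n", sep = "")
  tab <- table(factor(lay$role, levels = WELL_ROLES))
  cat("  wells by role:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  ngene <- length(unique(lay$gene[lay$role == "experimental"]))
  cat("  genes targeted: ", ngene, "\n", sep = "")
})

#' GroundTruth: the spiked truth behind a simulated data set
#'
#' Returned alongside simulated plates or spectral-count matrices, a
#' `GroundTruth` records which genes were spiked as reporter activators
#' (`trueUpGenes`), repressors (`trueDownGenes`) or cytotoxic wells
#' (`toxicGenes`), and which preys are genuine bait interactors
#' (`trueInteractors`), with the stimulation-enhanced subset
#' (`enhancedInteractors`). The three gene sets are disjoint and the
#' enhanced set is contained in the true-interactor set.
#'
#' @param x a `GroundTruth`.
#' @aliases GroundTruth
#' @export GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(trueUp = "character", trueDown = "character",
                        toxic = "character", interactors = "character",
                        enhanced = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  g <- c(object@trueUp, object@trueDown, object@toxic)
  if (anyDuplicated(g))
    msg <- c(msg, "up/down/toxic gene sets must be disjoint")
  if (!all(object@enhanced %in% object@interactors))
    msg <- c(msg, "enhanced preys must be a subset of true interactors")
  if (length(msg)) msg else TRUE
})

GroundTruth <- function(trueUp = character(), trueDown = character(),
                        toxic = character(), interactors = character(),
                        enhanced = character()) {
  new("GroundTruth", trueUp = trueUp, trueDown = trueDown, toxic = toxic,
      interactors = interactors, enhanced = enhanced)
}

#' @rdname GroundTruth-class
#' @export
setMethod("trueUpGenes", "GroundTruth", function(x) x@trueUp)
#' @rdname GroundTruth-class
#' @export
setMethod("trueDownGenes", "GroundTruth", function(x) x@trueDown)
#' @rdname GroundTruth-class
#' @export
setMethod("toxicGenes", "GroundTruth", function(x) x@toxic)
#' @rdname GroundTruth-class
#' @export
setMethod("trueInteractors", "GroundTruth", function(x) x@interactors)
#' @rdname GroundTruth-class
#' @export
setMethod("enhancedInteractors", "GroundTruth", function(x) x@enhanced)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      length(object@trueUp), "up,",
      length(object@trueDown), "down,",
      length(object@toxic), "toxic genes;",
      length(object@interactors), "true interactors (",
      length(object@enhanced), "enhanced )\n")
})

#' SpectralCountMatrix: AP-MS spectral counts, bait runs and controls
#'
#' Prey-by-run spectral counts from affinity-purification mass
#' spectrometry, as a [SummarizedExperiment::SummarizedExperiment] with a
#' single integer assay `counts`. Column metadata annotates each run with
#' `run_id`, `kind` (`"bait"` or `"control"`), `condition` (`"mock"`,
#' `"stimulated"` or `"na"` for control purifications) and `replicate`.
#' Run annotation is always user-supplied, never inferred from run names.
#'
#' @param counts non-negative integer matrix, preys in rows, runs in
#'   columns.
#' @param runInfo data.frame with columns `run_id`, `kind`, `condition`,
#'   `replicate`, one row per run.
#' @param x a `SpectralCountMatrix`.
#' @return `SpectralCountMatrix()` returns a validated object; `runInfo()`
#'   returns the run annotation as a data.frame.
#' @examples
#' sim <- simulateApms(apmsSimConfig(n_preys = 50, n_controls = 10, seed = 1))
#' sim$counts
#' @aliases SpectralCountMatrix
#' @export SpectralCountMatrix
#' @exportClass SpectralCountMatrix
setClass("SpectralCountMatrix", contains = "SummarizedExperiment")

.validScm <- function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cd <- colData(object)
  need <- c("run_id", "kind", "condition", "replicate")
  if (!all(need %in% colnames(cd)))
    return(paste0("colData must contain: ", paste(need, collapse = ", ")))
  k <- assay(object, "counts")
  if (any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
    msg <- c(msg, "counts must be non-negative integers")
  if (!all(cd$kind %in% c("bait", "control")))
    msg <- c(msg, "run kind must be 'bait' or 'control'")
  if (!all(cd$condition %in% c("mock", "stimulated", "na")))
    msg <- c(msg, "condition must be 'mock', 'stimulated' or 'na'")
  if (!any(cd$kind == "control"))
    msg <- c(msg, "at least one negative-control run is required")
  if (!any(cd$kind == "bait"))
    msg <- c(msg, "at least one bait run is required")
  if (length(msg)) msg else TRUE
}

setValidity("SpectralCountMatrix", .validScm)

SpectralCountMatrix <- function(counts, runInfo) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  runInfo <- as.data.frame(runInfo)
  if (nrow(runInfo) != ncol(counts))
    stop("runInfo must have one row per run (column of counts)")
  colnames(counts) <- runInfo$run_id
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(runInfo,
                                                 row.names = runInfo$run_id))
  new("SpectralCountMatrix", se)
}

#' @rdname SpectralCountMatrix-class
#' @export
setMethod("runInfo", "SpectralCountMatrix",
          function(x) as.data.frame(colData(x)))

setMethod("show", "SpectralCountMatrix", function(object) {
  cd <- colData(object)
  cat("SpectralCountMatrix: ", nrow(object), " preys x ", ncol(object),
      " runs\n", sep = "")
  cat("  bait runs:",
      paste(cd$run_id[cd$kind == "bait"], collapse = ", "), "\n")
  cat("  control runs: ", sum(cd$kind == "control"), "\n", sep = "")
})
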