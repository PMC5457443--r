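# Parse "A5" / "A05" well labels into row letter + column, with bounds
# checking against 384-well geometry.
.parseWell <- function(well) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-Z][0-9]{1,2}$", well)
  if (any(!ok))
    stop("malformed well label(s): ", paste(unique(well[!ok]), collapse = ", "))
  row <- substr(well, 1L, 1L)
  column <- as.integer(substring(well, 2L))
  bad <- !(row %in% PLATE_ROWS) | !(column %in% PLATE_COLS)
  if (any(bad))
    stop("well address out of 384-well bounds (rows A-P, columns 1-24): ",
         paste(unique(well[bad]), collapse = ", "))
  list(row = row, column = column)
}

# Full-precision numeric formatting so that CSV round trips are bit-exact
# for finite doubles.
.fmtNum <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out
}

#' Read a plate readout CSV plus layout CSV into a PlateSet
#'
#' The readout CSV has columns `plate`, `replicate`, `well`, `lucia`,
#' `ctg` (one row per well per replicate, comma-separated, header
#' required, "." decimal). The layout CSV has columns `plate`, `well`,
#' `role`, `gene`, `sirna_id` and describes every well of every plate
#' once; wells without sample are listed with `role = "empty"` rather
#' than omitted. Every readout row must match a layout entry; duplicate
#' wells, unknown layout entries, out-of-bounds addresses and
#' non-numeric readouts are rejected with a well-addressed message.
#'
#' @param readoutPath,layoutPath paths to the two CSV files.
#' @param screenMode `"smartpool"` or `"deconvolution"`.
#' @return a validated [PlateSet].
#' @seealso [writePlateSet()]
#' @export
readPlateSet <- function(readoutPath, layoutPath,
                         screenMode = c("smartpool", "deconvolution")) {
  screenMode <- match.arg(screenMode)
  rd <- read.csv(readoutPath, stringsAsFactors = FALSE,
                 colClasses = "character", na.strings = NULL)
  lay <- read.csv(layoutPath, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = NULL)
  need_rd <- c("plate", "replicate", "well", "lucia", "ctg")
  if (!all(need_rd %in% colnames(rd)))
    stop("readout CSV must have columns: ", paste(need_rd, collapse = ", "))
  need_lay <- c("plate", "well", "role", "gene", "sirna_id")
  if (!all(need_lay %in% colnames(lay)))
    stop("layout CSV must have columns: ", paste(need_lay, collapse = ", "))

  lw <- .parseWell(lay$well)
  layout <- data.frame(plate_id = lay$plate, row = lw$row, column = lw$column,
                       role = lay$role,
                       gene = ifelse(lay$gene == "" | lay$gene == "NA",
                                     NA_character_, lay$gene),
                       sirna_id = ifelse(lay$sirna_id == "" |
                                           lay$sirna_id == "NA",
                                         NA_character_, lay$sirna_id),
                       stringsAsFactors = FALSE)
  key_lay <- sprintf("%s:%s%02d", layout$plate_id, layout$row, layout$column)
  if (anyDuplicated(key_lay))
    stop("duplicate layout well: ", key_lay[duplicated(key_lay)][1L])

  rw <- .parseWell(rd$well)
  rep_idx <- suppressWarnings(as.integer(rd$replicate))
  if (any(is.na(rep_idx)))
    stop("non-integer replicate index in readout CSV")
  key_rd <- sprintf("%s:%s%02d", rd$plate, rw$row, rw$column)
  unmatched <- setdiff(key_rd, key_lay)
  if (length(unmatched))
    stop("readout wells missing from layout: ",
         paste(utils::head(unmatched, 3L), collapse = ", "))
  dup <- duplicated(paste(key_rd, rep_idx))
  if (any(dup))
    stop("duplicate readout well: ", key_rd[dup][1L],
         " (replicate ", rep_idx[dup][1L], ")")

  num <- function(v, what) {
    x <- suppressWarnings(as.numeric(v))
    bad <- is.na(x) & !(v %in% c("NA", ""))
    if (any(bad))
      stop("non-numeric ", what, " at well ", key_rd[bad][1L])
    x
  }
  lucia_v <- num(rd$lucia, "lucia")
  ctg_v <- num(rd$ctg, "ctg")

  reps <- sort(unique(rep_idx))
  n <- nrow(layout)
  lucia <- matrix(NA_real_, n, length(reps))
  ctg <- matrix(NA_real_, n, length(reps))
  ridx <- match(key_rd, key_lay)
  cidx <- match(rep_idx, reps)
  lucia[cbind(ridx, cidx)] <- lucia_v
  ctg[cbind(ridx, cidx)] <- ctg_v
  PlateSet(lucia, ctg, layout, screenMode)
}

#' Write a PlateSet back to readout + layout CSVs
#'
#' Inverse of [readPlateSet()]: numeric values are written at full
#' precision so a write/read round trip reproduces every finite value
#' bit-exactly.
#'
#' @param ps a [PlateSet].
#' @param readoutPath,layoutPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writePlateSet <- function(ps, readoutPath, layoutPath) {
  lay <- plateLayout(ps)
  layout_out <- data.frame(plate = lay$plate_id, well = lay$well,
                           role = lay$role,
                           gene = ifelse(is.na(lay$gene), "NA", lay$gene),
                           sirna_id = ifelse(is.na(lay$sirna_id), "NA",
                                             lay$sirna_id))
  write.csv(layout_out, layoutPath, row.names = FALSE, quote = FALSE)
  lu <- assay(ps, "lucia")
  ct <- assay(ps, "ctg")
  reps <- seq_len(ncol(ps))
  rows <- do.call(rbind, lapply(reps, function(r) {
    data.frame(plate = lay$plate_id, replicate = r, well = lay$well,
               lucia = .fmtNum(lu[, r]), ctg = .fmtNum(ct[, r]))
  }))
  write.csv(rows, readoutPath, row.names = FALSE, quote = FALSE)
  invisible(c(readoutPath, layoutPath))
}

#' Write / read a hit table CSV
#'
#' Hit tables ([callPrimary()], [callSecondary()]) are plain data.frames;
#' these writers serialise them losslessly (full numeric precision,
#' `TRUE`/`FALSE` logicals, `NA` markers), so write -> read -> write is
#' byte-identical.
#'
#' @param hits a hit-table data.frame.
#' @param path CSV path.
#' @return `writeHitTable()` returns the path invisibly; `readHitTable()`
#'   returns the data.frame with column types restored.
#' @export
writeHitTable <- function(hits, path) {
  out <- hits
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v) && !is.integer(v)) out[[j]] <- .fmtNum(v)
    else if (is.logical(v)) out[[j]] <- ifelse(is.na(v), "NA",
                                               ifelse(v, "TRUE", "FALSE"))
    else out[[j]] <- ifelse(is.na(v), "NA", as.character(v))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  df
}
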