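#' Overlap between the proteomics and RNAi hit lists
#'
#' Normalizes both identifier sets to upper-case gene symbols, applies
#' an optional alias map (e.g. `c(COPS1 = "GPS1")`), and intersects
#' them. Commutative and idempotent; empty inputs warn rather than
#' error.
#'
#' @param proteomics,rnai character vectors of gene symbols.
#' @param aliasMap named character vector mapping alias -> canonical
#'   symbol (applied after upper-casing).
#' @return list of class `HitSetOverlap` with the normalized sets, the
#'   intersection and their sizes.
#' @examples
#' hitOverlap(c("NXF1", "WDR77", "GPS1"), c("NXF1", "GPS1", "MYD88"))
#' @export
hitOverlap <- function(proteomics, rnai, aliasMap = NULL) {
  norm <- function(x) {
    x <- toupper(trimws(as.character(x)))
    x <- x[!is.na(x) & x != ""]
    if (!is.null(aliasMap)) {
      names(aliasMap) <- toupper(names(aliasMap))
      hit <- x %in% names(aliasMap)
      x[hit] <- toupper(aliasMap[x[hit]])
    }
    sort(unique(x))
  }
  p <- norm(proteomics)
  r <- norm(rnai)
  if (!length(p) || !length(r))
    warning("empty hit set supplied to hitOverlap()")
  ov <- intersect(p, r)
  structure(list(proteomics_hits = p, rnai_hits = r, overlap = ov,
                 n_proteomics = length(p), n_rnai = length(r),
                 n_overlap = length(ov)),
            class = "HitSetOverlap")
}

#' @export
print.HitSetOverlap <- function(x, ...) {
  cat("HitSetOverlap: ", x$n_proteomics, " proteomics x ", x$n_rnai,
      " RNAi hits -> ", x$n_overlap, " shared\n", sep = "")
  if (x$n_overlap)
    cat("  shared: ", paste(x$overlap, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Re-apply the published filters to a result table
#'
#' Given a CSV result table (e.g. a supplementary dataset or this
#' package's own hit tables) and a user-supplied column map, re-applies
#' one stage's hit filter and reports the surviving records. Because
#' external tables do not share one schema, the reader is entirely
#' column-map-driven and degrades gracefully: filters whose columns are
#' not mapped or not present are skipped and reported in
#' `missing_columns` / `filters_applied`.
#'
#' Stage filters:
#' * `apms` — AvgP at least `avgpThreshold` (inclusive). Map: `avgp`.
#' * `primary` — z-score at most `zLow` or at least `zHigh` in at least
#'   `minReplicates` replicates, discordant genes excluded; replicates
#'   failing the viability gate (logical `FALSE`, or numeric ratio
#'   below 0.7) contribute no z. Map: `z` (vector of per-replicate
#'   column names), optional `viability` (same length).
#' * `secondary` — at least `minDuplexes` duplex activity ratios changed
#'   by `changeFraction` in the same direction, optionally also outside
#'   `mean +/- sdMult * SD` of negative controls (needs `neg_mean`,
#'   `neg_sd` scalar values in the map) and viability-gated. Map:
#'   `ratio` (per-duplex columns), optional `viability`, `neg_mean`,
#'   `neg_sd`.
#'
#' @param path CSV file to filter.
#' @param columnMap named list, see above; also `id` for the identifier
#'   column (defaults to the first column).
#' @param stage `"apms"`, `"primary"` or `"secondary"`.
#' @param avgpThreshold,zLow,zHigh,minReplicates,changeFraction,sdMult,
#'   minDuplexes,maxViabilityLoss filter parameters, defaulting to the
#'   published values.
#' @return list of class `SupplementaryReport`: `stage`, `n_records`,
#'   `n_survivors`, `survivors` (ids), `filters_applied`,
#'   `missing_columns`, `records` (per-record pass/fail data.frame).
#' @export
reproduceSupplementary <- function(path, columnMap,
                                   stage = c("apms", "primary", "secondary"),
                                   avgpThreshold = 0.89,
                                   zLow = -2, zHigh = 3, minReplicates = 2,
                                   changeFraction = 0.6, sdMult = 2,
                                   minDuplexes = 2, maxViabilityLoss = 0.3) {
  stage <- match.arg(stage)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  id_col <- columnMap$id %||% colnames(tab)[1L]
  ids <- as.character(tab[[id_col]])
  applied <- character()
  missing <- character()

  getCols <- function(nm) {
    cols <- columnMap[[nm]]
    if (is.null(cols)) return(NULL)
    absent <- setdiff(cols, colnames(tab))
    if (length(absent)) {
      missing <<- c(missing, absent)
      return(NULL)
    }
    as.matrix(tab[, cols, drop = FALSE])
  }
  viabilityGate <- function(vmat) {
    # TRUE = replicate usable; logical columns taken as-is, numeric as
    # ratio >= 1 - maxViabilityLoss
    if (is.null(vmat)) return(NULL)
    if (is.logical(vmat[1])) vmat == TRUE
    else vmat >= (1 - maxViabilityLoss)
  }

  if (stage == "apms") {
    avgp <- getCols("avgp")
    if (is.null(avgp))
      stop("columnMap$avgp must name an existing AvgP column")
    applied <- sprintf("avgp >= %s", avgpThreshold)
    survives <- as.numeric(avgp[, 1]) >= avgpThreshold
  } else if (stage == "primary") {
    z <- getCols("z")
    if (is.null(z)) stop("columnMap$z must name existing z-score columns")
    viab <- viabilityGate(getCols("viability"))
    if (!is.null(viab)) {
      z[!viab] <- NA_real_
      applied <- c(applied, sprintf("viability loss <= %s", maxViabilityLoss))
    }
    n_down <- rowSums(z <= zLow, na.rm = TRUE)
    n_up <- rowSums(z >= zHigh, na.rm = TRUE)
    discord <- n_down > 0 & n_up > 0
    applied <- c(applied,
                 sprintf("z <= %s or z >= %s in >= %d replicates",
                         zLow, zHigh, minReplicates))
    survives <- !discord & (n_down >= minReplicates | n_up >= minReplicates)
  } else {
    ratio <- getCols("ratio")
    if (is.null(ratio))
      stop("columnMap$ratio must name existing duplex activity columns")
    viab <- viabilityGate(getCols("viability"))
    down <- ratio <= (1 - changeFraction)
    up <- ratio >= (1 + changeFraction)
    applied <- sprintf("activity changed by >= %s", changeFraction)
    if (!is.null(columnMap$neg_mean) && !is.null(columnMap$neg_sd)) {
      lo <- columnMap$neg_mean - sdMult * columnMap$neg_sd
      hi <- columnMap$neg_mean + sdMult * columnMap$neg_sd
      down <- down & ratio < lo
      up <- up & ratio > hi
      applied <- c(applied, sprintf("outside mean +/- %s SD of negatives",
                                    sdMult))
    }
    if (!is.null(viab)) {
      down <- down & viab
      up <- up & viab
      applied <- c(applied, sprintf("viability loss <= %s", maxViabilityLoss))
    }
    survives <- rowSums(down, na.rm = TRUE) >= minDuplexes |
      rowSums(up, na.rm = TRUE) >= minDuplexes
  }

  structure(list(stage = stage, n_records = nrow(tab),
                 n_survivors = sum(survives),
                 survivors = ids[survives],
                 filters_applied = applied,
                 missing_columns = unique(missing),
                 records = data.frame(id = ids, survives = survives,
                                      stringsAsFactors = FALSE)),
            class = "SupplementaryReport")
}

#' @export
print.SupplementaryReport <- function(x, ...) {
  cat("SupplementaryReport [", x$stage, "]: ", x$n_survivors, " of ",
      x$n_records, " records survive\n", sep = "")
  cat("  filters:", paste(x$filters_applied, collapse = "; "), "\n")
  if (length(x$missing_columns))
    cat("  unmapped/missing columns skipped:",
        paste(x$missing_columns, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the bait-centred interaction/regulator network
#'
#' Builds a star network around the bait: one node per passing AP-MS
#' interactor and per called RNAi regulator, categorised `interactor`,
#' `regulator` or `both`; one edge per node to the bait, with evidence
#' `apms`, `rnai` or `both` and a `condition_enhanced` flag taken from
#' the enhancement classification. `edge_csv` writes an edge list to
#' `path` and a node table next to it (`*_nodes.csv`); `graphml` writes
#' a GraphML file loadable by standard graph tools.
#'
#' @param apmsScores output of [scoreInteractions()] (optionally after
#'   [classifyEnhancement()]; any `enhancement` column is carried over).
#' @param hits a primary or secondary hit table (genes with
#'   `primary_call != "none"` or `confirmed == TRUE` become regulator
#'   nodes); may be `NULL`.
#' @param path output file path.
#' @param format `"edge_csv"` or `"graphml"`.
#' @param bait bait node identifier.
#' @return invisibly, a list with the `nodes` and `edges` data.frames.
#' @export
exportNetwork <- function(apmsScores, hits, path,
                          format = c("edge_csv", "graphml"),
                          bait = "IRF5") {
  format <- match.arg(format)
  interactors <- character()
  enh <- character()
  if (!is.null(apmsScores) && nrow(apmsScores)) {
    pass <- if ("passes" %in% colnames(apmsScores)) apmsScores$passes
            else apmsScores$passes_mock | apmsScores$passes_stim
    interactors <- toupper(apmsScores$prey[pass])
    e <- if ("enhancement" %in% colnames(apmsScores))
      apmsScores$enhancement[pass] else rep("na", sum(pass))
    enh <- setNames(e, interactors)
  }
  regulators <- character()
  if (!is.null(hits) && nrow(hits)) {
    called <- if ("confirmed" %in% colnames(hits)) hits$confirmed
              else hits$primary_call != "none"
    regulators <- toupper(hits$gene[called])
  }
  ids <- sort(unique(c(interactors, regulators)))
  category <- ifelse(ids %in% interactors & ids %in% regulators, "both",
                     ifelse(ids %in% interactors, "interactor", "regulator"))
  nodes <- data.frame(id = c(bait, ids),
                      category = c("bait", category),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = rep(bait, length(ids)), target = ids,
                      evidence = ifelse(category == "both", "both",
                                        ifelse(category == "interactor",
                                               "apms", "rnai")),
                      condition_enhanced =
                        unname(!is.na(enh[ids]) & enh[ids] == "enhanced"),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  if (format == "edge_csv") {
    write.csv(edges, path, row.names = FALSE, quote = FALSE)
    write.csv(nodes, sub("\\.csv$", "_nodes.csv", path),
              row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(list(nodes = nodes, edges = edges))
}
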