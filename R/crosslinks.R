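#' Read a cross-link table
#'
#' Parses a CSV/TSV table of cross-linking-MS identifications into a
#' [CrossLinkSet-class]. Non-canonical exports (e.g. xQuest/xProphet result
#' tables) are supported through a column-mapping dialect: a named list (or a
#' YAML file holding one) mapping the canonical names \code{protein1},
#' \code{residue1}, \code{protein2}, \code{residue2}, \code{id_score},
#' \code{delta_s}, \code{fdr} (and optionally \code{linker}) to the column
#' names of the file.
#'
#' Rows whose residue positions cannot be parsed as positive integers are
#' skipped and logged in the provenance. Duplicate unordered residue pairs are
#' collapsed, keeping the record with the highest id score, so each pair
#' contributes a single spatial restraint.
#'
#' @param path path to a CSV (comma) or TSV (tab) file; the delimiter is taken
#'   from the file extension (\code{.tsv}/\code{.tab} means tab).
#' @param dialect named list mapping canonical column names to file column
#'   names, or the path of a YAML file with such a mapping; \code{NULL} for
#'   the canonical layout.
#' @return a [CrossLinkSet-class]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(protein1 = "A", residue1 = c(10, 20),
#'                      protein2 = "A", residue2 = c(50, 60),
#'                      linker = "DSS", id_score = c(35, 31),
#'                      delta_s = 0.5, fdr = 0.01),
#'           f, row.names = FALSE)
#' readCrossLinks(f)
#' @export
readCrossLinks <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("cross-link file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0) stop("cross-link file is empty: ", path)
  if (is.character(dialect) && length(dialect) == 1)
    dialect <- yaml::read_yaml(dialect)
  mandatory <- c("protein1", "residue1", "protein2", "residue2",
                 "id_score", "delta_s", "fdr")
  colmap <- stats::setNames(as.list(c(mandatory, "linker")),
                            c(mandatory, "linker"))
  for (nm in names(dialect)) colmap[[nm]] <- dialect[[nm]]
  for (nm in mandatory)
    if (!colmap[[nm]] %in% names(raw))
      stop("missing mandatory column: ", colmap[[nm]],
           " (canonical field '", nm, "')")

  df <- data.frame(protein1 = as.character(raw[[colmap$protein1]]),
                   residue1 = suppressWarnings(as.integer(raw[[colmap$residue1]])),
                   protein2 = as.character(raw[[colmap$protein2]]),
                   residue2 = suppressWarnings(as.integer(raw[[colmap$residue2]])),
                   id_score = as.numeric(raw[[colmap$id_score]]),
                   delta_s = as.numeric(raw[[colmap$delta_s]]),
                   fdr = as.numeric(raw[[colmap$fdr]]),
                   stringsAsFactors = FALSE)
  df$linker <- if (colmap$linker %in% names(raw))
    .normalizeLinker(raw[[colmap$linker]]) else "other"

  bad <- is.na(df$residue1) | is.na(df$residue2) | df$residue1 < 1 | df$residue2 < 1
  log <- character()
  if (any(bad)) {
    log <- sprintf("row %d skipped: unparseable residue position", which(bad))
    message(sum(bad), " row(s) with unparseable residue positions skipped")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no parseable cross-link rows in ", path)
  df$link_class <- ifelse(df$protein1 == df$protein2, "intra", "inter")

  # dedup unordered pairs, keeping max id_score
  key <- .xlPairKey(df)
  ord <- order(key, -df$id_score)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$protein1, df$residue1, df$protein2, df$residue2), ,
           drop = FALSE]
  rownames(df) <- NULL
  new("CrossLinkSet", records = df[, .xlCanonicalCols],
      provenance = list(source = path, dialect = dialect, parse_log = log))
}

.normalizeLinker <- function(x) {
  x <- toupper(as.character(x))
  ifelse(x %in% c("DSS", "DSG", "DSSO"), x, "other")
}

#' Construct a cross-link set from a data.frame
#'
#' Programmatic counterpart of [readCrossLinks()]: validates, fills optional
#' columns and deduplicates unordered residue pairs (keeping max id score).
#'
#' @param records data.frame with at least \code{protein1}, \code{residue1},
#'   \code{protein2}, \code{residue2}; missing quality columns default to
#'   \code{NA}, missing linker to \code{"other"}.
#' @param provenance optional provenance list.
#' @return a [CrossLinkSet-class]
#' @export
CrossLinkSet <- function(records, provenance = list()) {
  for (nm in c("id_score", "delta_s", "fdr"))
    if (is.null(records[[nm]])) records[[nm]] <- NA_real_
  if (is.null(records$linker)) records$linker <- "other"
  records$linker <- .normalizeLinker(records$linker)
  records$residue1 <- as.integer(records$residue1)
  records$residue2 <- as.integer(records$residue2)
  records$link_class <- ifelse(records$protein1 == records$protein2,
                               "intra", "inter")
  key <- .xlPairKey(records)
  ord <- order(key, -records$id_score)
  records <- records[ord, , drop = FALSE]
  records <- records[!duplicated(key[ord]), , drop = FALSE]
  rownames(records) <- NULL
  new("CrossLinkSet", records = records[, .xlCanonicalCols],
      provenance = provenance)
}

#' Quality-filter a cross-link set
#'
#' Retains records with \code{id_score > minIdScore}, \code{delta_s <
#' maxDeltaS} and \code{fdr < maxFdr}. All three inequalities are strict, so
#' records sitting exactly on a threshold are removed. Defaults are the
#' standard xQuest/xProphet acceptance thresholds for modelling-grade
#' identifications. Records with missing quality values fail the filter.
#'
#' @param xls a [CrossLinkSet-class]
#' @param minIdScore minimum id score (exclusive), default 28.
#' @param maxDeltaS maximum deltaS (exclusive), default 0.95.
#' @param maxFdr maximum FDR (exclusive), default 0.05.
#' @return the filtered [CrossLinkSet-class]; its provenance gains a
#'   \code{filter} entry with per-criterion counts (see [xlFilterReport()]).
#' @export
filterCrossLinks <- function(xls, minIdScore = 28, maxDeltaS = 0.95,
                             maxFdr = 0.05) {
  stopifnot(is(xls, "CrossLinkSet"),
            is.finite(minIdScore), is.finite(maxDeltaS), is.finite(maxFdr))
  df <- xls@records
  passScore <- !is.na(df$id_score) & df$id_score > minIdScore
  passDeltaS <- !is.na(df$delta_s) & df$delta_s < maxDeltaS
  passFdr <- !is.na(df$fdr) & df$fdr < maxFdr
  keep <- passScore & passDeltaS & passFdr
  if (!any(keep)) warning("all cross-links removed by the quality filter")
  report <- list(n_in = nrow(df), n_out = sum(keep),
                 thresholds = list(min_id_score = minIdScore,
                                   max_delta_s = maxDeltaS, max_fdr = maxFdr),
                 failed_id_score = sum(!passScore),
                 failed_delta_s = sum(!passDeltaS),
                 failed_fdr = sum(!passFdr))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("CrossLinkSet", records = out,
      provenance = c(xls@provenance, list(filter = report)))
}

#' Filter report of a cross-link set
#'
#' @param xls a [CrossLinkSet-class] returned by [filterCrossLinks()]
#' @return list with counts in/out and per-criterion failure counts, or
#'   \code{NULL} when no filter has been applied.
#' @export
xlFilterReport <- function(xls) {
  stopifnot(is(xls, "CrossLinkSet"))
  xls@provenance$filter
}

#' Write a cross-link set
#'
#' Writes the canonical CSV layout; a round trip through
#' [readCrossLinks()] reproduces all fields. Optionally writes the JSON
#' filter report next to it.
#'
#' @param xls a [CrossLinkSet-class]
#' @param path output CSV path
#' @param reportPath optional path for a JSON filter report
#' @return \code{path}, invisibly
#' @export
writeCrossLinks <- function(xls, path, reportPath = NULL) {
  stopifnot(is(xls, "CrossLinkSet"))
  utils::write.csv(xls@records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(reportPath)) {
    rep <- xlFilterReport(xls)
    if (is.null(rep)) rep <- list(n_in = nrow(xls@records),
                                  n_out = nrow(xls@records))
    jsonlite::write_json(rep, reportPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
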