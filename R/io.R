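#' @include significance.R
NULL

#' Convert percent viability to fractional inhibition (and back)
#'
#' `viabilityToInhibition()` maps percent viability `v` to fractional
#' inhibition `(100 - v)/100`; no clamping is applied, so a negative
#' viability yields an inhibition above 1 and is retained as observed.
#' `inhibitionToViability()` is the inverse.
#'
#' @param v percent viability values.
#' @param y fractional inhibition values.
#' @return numeric vector on the other scale.
#' @examples
#' viabilityToInhibition(c(100, 0, -10))  # 0, 1, 1.1
#' @export
viabilityToInhibition <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  (100 - v) / 100
}

#' @rdname viabilityToInhibition
#' @export
inhibitionToViability <- function(y) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  100 * (1 - y)
}

.longCols <- c("block_id", "drug_row", "drug_col", "conc_row", "conc_col",
               "response", "conc_unit_row", "conc_unit_col")

.toInternal <- function(values, responseType) {
  # files carry percent scales; internal responses are inhibition fractions
  if (responseType == "viability") viabilityToInhibition(values)
  else values / 100
}

.fromInternal <- function(values, responseType) {
  if (responseType == "viability") inhibitionToViability(values)
  else 100 * values
}

.buildBlock <- function(df, responseType) {
  id <- df$block_id[1]
  if (length(unique(df$drug_row)) != 1L || length(unique(df$drug_col)) != 1L)
    stop(sprintf("block '%s': drug names are not constant within the block", id))
  if (length(unique(df$conc_unit_row)) != 1L || length(unique(df$conc_unit_col)) != 1L)
    stop(sprintf("block '%s': concentration units are not constant within the block", id))
  cr <- sort(unique(df$conc_row)); cc <- sort(unique(df$conc_col))
  if (cr[1] != 0 || cc[1] != 0)
    stop(sprintf("block '%s': missing monotherapy data (no zero-dose row/column)", id))
  resp <- matrix(NA_real_, length(cr), length(cc))
  cnt <- matrix(0L, length(cr), length(cc))
  i <- match(df$conc_row, cr); j <- match(df$conc_col, cc)
  for (k in seq_len(nrow(df))) {
    cnt[i[k], j[k]] <- cnt[i[k], j[k]] + 1L
    resp[i[k], j[k]] <- if (cnt[i[k], j[k]] == 1L) df$response[k]
                        else resp[i[k], j[k]] + df$response[k]
  }
  if (any(cnt == 0L)) {
    hole <- which(cnt == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("block '%s': missing well at (conc_row = %g, conc_col = %g)",
                 id, cr[hole[1]], cc[hole[2]]))
  }
  if (any(cnt > 1L)) {
    message(sprintf("block '%s': %d duplicated wells averaged",
                    id, sum(cnt > 1L)))
    resp <- resp / cnt
  }
  doseResponseMatrix(.toInternal(resp, responseType), cr, cc,
                     drugRow = df$drug_row[1], drugCol = df$drug_col[1],
                     unitRow = df$conc_unit_row[1], unitCol = df$conc_unit_col[1],
                     blockId = id)
}

.readLong <- function(path, responseType) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e))))
  missing <- setdiff(.longCols, names(df))
  if (length(missing))
    stop(sprintf("'%s': missing required columns: %s", path,
                 paste(missing, collapse = ", ")))
  bad <- which(!is.finite(df$response) | !is.finite(df$conc_row) |
               !is.finite(df$conc_col))
  if (length(bad))
    stop(sprintf("'%s': non-numeric or missing value near line %d", path,
                 bad[1] + 1L))
  lapply(split(df, df$block_id), .buildBlock, responseType = responseType)
}

.readMatrixDialect <- function(path, responseType) {
  lines <- readLines(path)
  # blocks are separated by blank lines; metadata in '# key: value' lines
  groups <- split(lines, cumsum(grepl("^\\s*$", lines)))
  groups <- lapply(groups, function(g) g[!grepl("^\\s*$", g)])
  groups <- Filter(length, groups)
  out <- list()
  for (g in groups) {
    metaLines <- grep("^#", g, value = TRUE)
    meta <- list()
    for (ml in metaLines) {
      kv <- sub("^#\\s*", "", ml)
      key <- trimws(sub(":.*$", "", kv))
      meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
    }
    body <- grep("^#", g, value = TRUE, invert = TRUE)
    if (length(body) < 3L)
      stop(sprintf("'%s': matrix block needs a header and >= 2 dose rows", path))
    con <- textConnection(body)
    tab <- utils::read.csv(con, header = TRUE, check.names = FALSE)
    close(con)
    cc <- as.numeric(names(tab)[-1])
    cr <- as.numeric(tab[[1]])
    if (any(is.na(cc)) || any(is.na(cr)))
      stop(sprintf("'%s': non-numeric concentration header in block '%s'",
                   path, meta$block_id %||% "?"))
    resp <- as.matrix(tab[, -1, drop = FALSE])
    ord_r <- order(cr); ord_c <- order(cc)
    resp <- resp[ord_r, ord_c, drop = FALSE]
    cr <- cr[ord_r]; cc <- cc[ord_c]
    if (any(!is.finite(resp)))
      stop(sprintf("block '%s': missing well in matrix body",
                   meta$block_id %||% "?"))
    id <- meta$block_id %||% sprintf("block%d", length(out) + 1L)
    out[[id]] <- doseResponseMatrix(
      .toInternal(resp, responseType), cr, cc,
      drugRow = meta$drug_row %||% "drugRow",
      drugCol = meta$drug_col %||% "drugCol",
      unitRow = meta$conc_unit_row %||% "uM",
      unitCol = meta$conc_unit_col %||% "uM",
      blockId = id)
  }
  out
}

#' Read a combination-screen table
#'
#' Parses a plain-text dose-response combination screen into a list of
#' [DoseResponseMatrix-class] blocks. Two dialects are supported:
#'
#' * `"long"` — CSV with one row per well and columns `block_id,
#'   drug_row, drug_col, conc_row, conc_col, response, conc_unit_row,
#'   conc_unit_col`.
#' * `"matrix"` — one or more blocks of `# key: value` metadata lines
#'   (`block_id`, `drug_row`, `drug_col`, `conc_unit_row`,
#'   `conc_unit_col`) followed by a CSV grid whose header holds the
#'   column-drug concentrations and whose first column holds the row-drug
#'   concentrations; blocks are separated by blank lines.
#'
#' The response scale is never guessed: `responseType` must state whether
#' the file carries percent viability or percent inhibition; viability is
#' converted on read. Every block must include the zero-dose monotherapy
#' row and column; a missing well is a structured error naming the hole,
#' and duplicated wells are averaged with a message.
#'
#' @param path file path.
#' @param dialect `"long"` or `"matrix"`.
#' @param responseType `"viability"` or `"inhibition"` (percent scales).
#' @return named list of [DoseResponseMatrix-class] objects, one per block.
#' @seealso [writeCombinationTable()]
#' @export
readCombinationTable <- function(path, dialect = c("long", "matrix"),
                                 responseType = c("viability", "inhibition")) {
  dialect <- match.arg(dialect)
  responseType <- match.arg(responseType)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (dialect == "long") .readLong(path, responseType)
  else .readMatrixDialect(path, responseType)
}

#' Write combination blocks to a plain-text table
#'
#' Inverse of [readCombinationTable()]: serializes blocks in either
#' dialect, with responses converted back to the requested percent scale.
#' A read/write round trip preserves every well value.
#'
#' @param mats a [DoseResponseMatrix-class] or list of them.
#' @param path output file path.
#' @inheritParams readCombinationTable
#' @return `path`, invisibly.
#' @export
writeCombinationTable <- function(mats, path, dialect = c("long", "matrix"),
                                  responseType = c("viability", "inhibition")) {
  dialect <- match.arg(dialect)
  responseType <- match.arg(responseType)
  if (is(mats, "DoseResponseMatrix")) mats <- list(mats)
  stopifnot(all(vapply(mats, is, logical(1), "DoseResponseMatrix")))
  if (dialect == "long") {
    rows <- lapply(mats, function(m) {
      grid <- expand.grid(i = seq_along(m@concRow), j = seq_along(m@concCol))
      data.frame(block_id = m@blockId, drug_row = m@drugRow,
                 drug_col = m@drugCol,
                 conc_row = m@concRow[grid$i], conc_col = m@concCol[grid$j],
                 response = .fromInternal(m@response[cbind(grid$i, grid$j)],
                                          responseType),
                 conc_unit_row = m@unitRow, conc_unit_col = m@unitCol,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (m in mats) {
      writeLines(c(sprintf("# block_id: %s", m@blockId),
                   sprintf("# drug_row: %s", m@drugRow),
                   sprintf("# drug_col: %s", m@drugCol),
                   sprintf("# conc_unit_row: %s", m@unitRow),
                   sprintf("# conc_unit_col: %s", m@unitCol),
                   sprintf("# response_type: %s", responseType)), con)
      writeLines(paste(c("conc", format(m@concCol, digits = 15, trim = TRUE)),
                       collapse = ","), con)
      vals <- .fromInternal(m@response, responseType)
      for (i in seq_along(m@concRow)) {
        writeLines(paste(c(format(m@concRow[i], digits = 15, trim = TRUE),
                           format(vals[i, ], digits = 15, trim = TRUE)),
                         collapse = ","), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}
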