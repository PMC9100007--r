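#' Validate an in-memory expression matrix
#'
#' Expression matrices are plain numeric matrices with samples as rows and
#' genes as columns (the transpose of the on-disk Xena layout). Row and
#' column names carry the identifiers and must be unique; all values must
#' be finite.
#'
#' @param values numeric matrix, samples x genes
#' @param sampleIds,geneIds optional identifier vectors; defaults to the
#'   existing dimnames
#' @return the validated matrix with dimnames set
#' @export
expressionMatrix <- function(values, sampleIds = rownames(values),
                             geneIds = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(sampleIds) || is.null(geneIds))
    stop("sample and gene identifiers are required")
  if (length(sampleIds) != nrow(values))
    stop("sampleIds length does not match row count")
  if (length(geneIds) != ncol(values))
    stop("geneIds length does not match column count")
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifiers: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifiers: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values; empty cells are ",
         "rejected rather than imputed")
  dimnames(values) <- list(as.character(sampleIds), as.character(geneIds))
  values
}

#' Validate a clinical survival table
#'
#' @param sampleIds character identifiers, unique
#' @param time positive follow-up times (days)
#' @param event 0/1 event indicator (1 = death observed, 0 = right-censored)
#' @return data.frame with columns `sample`, `time`, `event`
#' @export
survivalTable <- function(sampleIds, time, event) {
  sampleIds <- as.character(sampleIds)
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifiers in clinical table: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(sampleIds) || length(event) != length(sampleIds))
    stop("sample, time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and > 0")
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (death observed)")
  data.frame(sample = sampleIds, time = time, event = event,
             stringsAsFactors = FALSE)
}

# fread with built-in gzip handling (no optional-package dependency)
.freadMaybeGz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- paste(readLines(con), collapse = "\n")
    data.table::fread(text = txt, sep = "\t", header = TRUE,
                      data.table = FALSE, showProgress = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE,
                      data.table = FALSE, showProgress = FALSE)
  }
}

#' Read a Xena-dialect expression TSV
#'
#' On disk the matrix is genes-as-rows: a header of sample identifiers
#' preceded by one identifier field, then one row per gene. The result is
#' transposed to the in-memory samples x genes orientation. Plain or
#' gzip-compressed paths are accepted.
#'
#' @param path TSV file path
#' @return samples x genes numeric matrix (see [expressionMatrix()])
#' @export
readExpression <- function(path) {
  dt <- .freadMaybeGz(path)
  if (ncol(dt) < 1L) stop("empty expression file: ", path)
  geneIds <- as.character(dt[[1L]])
  sampleIds <- colnames(dt)[-1L]
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))
      if (length(bad))
        stop(sprintf(
          "non-numeric expression value '%s' at gene '%s', sample '%s'",
          vals[[j]][bad[1L]], geneIds[bad[1L]], sampleIds[j]))
      vals[[j]] <- num
    }
  }
  m <- t(as.matrix(vals))
  expressionMatrix(m, sampleIds = sampleIds, geneIds = geneIds)
}

#' Write an expression matrix as Xena-dialect TSV
#'
#' @param expr samples x genes matrix
#' @param path destination; a `.gz` suffix writes gzip
#' @param idColumn name of the gene-identifier header field
#' @return `path`, invisibly
#' @export
writeExpression <- function(expr, path, idColumn = "sample") {
  expr <- expressionMatrix(expr)
  out <- data.table::data.table(.id = colnames(expr))
  data.table::setnames(out, ".id", idColumn)
  tm <- t(expr)
  for (i in seq_len(nrow(expr))) out[[rownames(expr)[i]]] <- tm[, i]
  data.table::fwrite(out, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a clinical survival TSV
#'
#' Column names follow the Xena survival dialect by default and are
#' configurable.
#'
#' @param path TSV file path
#' @param sampleCol,timeCol,eventCol column names
#' @return a survival table (see [survivalTable()])
#' @export
readClinical <- function(path, sampleCol = "sample", timeCol = "OS.time",
                         eventCol = "OS") {
  dt <- .freadMaybeGz(path)
  for (col in c(sampleCol, timeCol, eventCol))
    if (!col %in% colnames(dt))
      stop("clinical file lacks column '", col, "': ", path)
  survivalTable(dt[[sampleCol]], dt[[timeCol]], dt[[eventCol]])
}

#' Write a clinical survival TSV
#'
#' @param surv survival table
#' @param path destination
#' @inheritParams readClinical
#' @return `path`, invisibly
#' @export
writeClinical <- function(surv, path, sampleCol = "sample",
                          timeCol = "OS.time", eventCol = "OS") {
  stopifnot(all(c("sample", "time", "event") %in% colnames(surv)))
  out <- data.table::data.table(a = surv$sample, b = surv$time,
                                c = as.integer(surv$event))
  data.table::setnames(out, c(sampleCol, timeCol, eventCol))
  data.table::fwrite(out, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Restrict expression and clinical data to their common samples
#'
#' Both objects are subset to the intersection of their sample identifiers
#' and returned in the same (expression-file) order.
#'
#' @param expr samples x genes matrix
#' @param surv survival table
#' @return list with elements `expr` and `surv`
#' @export
alignCohort <- function(expr, surv) {
  expr <- expressionMatrix(expr)
  common <- intersect(rownames(expr), surv$sample)
  if (length(common) == 0L)
    stop("no samples shared between expression and clinical tables")
  expr2 <- expr[common, , drop = FALSE]
  surv2 <- surv[match(common, surv$sample), , drop = FALSE]
  rownames(surv2) <- NULL
  list(expr = expr2, surv = surv2)
}

#' Genes present in every matrix of a list
#'
#' Returns the genes shared by all supplied expression matrices, in the
#' gene order of the first. Mirrors the intersection step that pools
#' cohorts onto one common gene universe before pretraining.
#'
#' @param matrices list of expression matrices
#' @return character vector of shared gene identifiers
#' @export
intersectGenes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need at least one expression matrix")
  genes <- colnames(matrices[[1L]])
  for (m in matrices[-1L]) genes <- genes[genes %in% colnames(m)]
  if (length(genes) == 0L) stop("gene intersection is empty")
  genes
}
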