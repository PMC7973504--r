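# Tabular I/O. All tables are TSV with a header; numeric columns are
# serialized with "%.17g" so write/read round-trips are bit-exact.

.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

.writeTsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

.pgCols <- c("Protein IDs", "Gene names", "Reverse",
             "Potential contaminant", "Only identified by site")

#' Write a MaxQuant-style protein-groups TSV
#'
#' Columns: `Protein IDs`, `Gene names`, the three filter flags (`+` when
#' set, empty otherwise) and one `LFQ intensity <sample>` column per sample;
#' missing entries are written as 0, the convention of LFQ exports.
#'
#' @param x an [IntensityExperiment-class] (gene names taken from
#'   `rowData(x)$geneName` when present, else row names).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeProteinGroups <- function(x, file) {
  m <- intensities(x)
  gn <- rowData(x)$geneName
  if (is.null(gn)) gn <- rownames(m)
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = rownames(m), `Gene names` = gn,
    Reverse = "", `Potential contaminant` = "",
    `Only identified by site` = "")
  vals <- m
  vals[is.na(vals)] <- 0
  for (j in seq_len(ncol(vals)))
    df[[paste("LFQ intensity", colnames(vals)[j])]] <- .fmtNum(vals[, j])
  .writeTsv(df, file)
  invisible(file)
}

#' Read a MaxQuant-style protein-groups TSV
#'
#' Performs no filtering; see [cleanProteinGroups()] for flag-based row
#' removal and zero-to-missing conversion.
#'
#' @param file path to a protein-groups TSV.
#' @return a data.frame with the identification columns and one numeric
#'   `LFQ intensity <sample>` column per sample.
#' @export
readProteinGroups <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(.pgCols, colnames(df))
  if (length(missing))
    stop("protein-groups file lacks required column(s): ",
         paste(sQuote(missing), collapse = ", "))
  lfq <- grep("^LFQ intensity ", colnames(df), value = TRUE)
  if (!length(lfq)) stop("no 'LFQ intensity <sample>' columns found")
  for (cc in lfq) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Write / read a features-by-samples intensity matrix TSV
#'
#' First column `featureId`, then one numeric column per sample; missing
#' entries are written as `NA`.
#'
#' @param x an [IntensityExperiment-class].
#' @param file path.
#' @return `writeMirnaMatrix`: `file`, invisibly.
#' @export
writeMirnaMatrix <- function(x, file) {
  m <- intensities(x)
  df <- data.frame(featureId = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- .fmtNum(m[, j])
  .writeTsv(df, file)
  invisible(file)
}

#' @rdname writeMirnaMatrix
#' @param groups per-sample group labels; when NULL they are inferred by
#'   stripping a trailing `_<replicate>` from the sample column names.
#' @return `readMirnaMatrix`: an [IntensityExperiment-class].
#' @export
readMirnaMatrix <- function(file, groups = NULL) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (is.null(groups)) groups <- sub("_[0-9]+$", "", colnames(m))
  IntensityExperiment(m, groups)
}

#' Write / read a miRNA-to-gene target map TSV
#'
#' Columns `mirnaId`, `geneSymbol`, `evidence`.
#'
#' @param map a [TargetMap-class].
#' @param file path.
#' @return `writeTargetMap`: `file`, invisibly; `readTargetMap`: a
#'   `TargetMap`.
#' @export
writeTargetMap <- function(map, file) {
  .writeTsv(as.data.frame(targetEdges(map)), file)
  invisible(file)
}

#' @rdname writeTargetMap
#' @export
readTargetMap <- function(file) {
  TargetMap(read.delim(file, check.names = FALSE, stringsAsFactors = FALSE))
}

#' Write / read a qPCR CT table TSV
#'
#' Long format, columns `sampleId`, `group`, `target`, `ct` (cycles).
#'
#' @param ct a CT table data.frame (see [simulateCTTable()]).
#' @param file path.
#' @return `writeCTTable`: `file`, invisibly; `readCTTable`: a data.frame.
#' @export
writeCTTable <- function(ct, file) {
  df <- ct
  df$ct <- .fmtNum(df$ct)
  .writeTsv(df, file)
  invisible(file)
}

#' @rdname writeCTTable
#' @export
readCTTable <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sampleId", "group", "target", "ct")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("CT table lacks required column(s): ",
         paste(sQuote(missing), collapse = ", "))
  df$ct <- as.numeric(df$ct)
  df
}
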