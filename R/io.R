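# Plain-text readers/writers for the pipeline's tabular interchange
# formats. Interval formats (BED/narrowPeak/GTF) live in regulome.R.

#' Read a log2 expression matrix from TSV
#'
#' First column = probe id, remaining columns = samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (sample_id, tissue, study_id) from TSV
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_sample_sheet(sheet)
  sheet
}

#' Read a probe-to-gene map (probe_id, gene_id) from TSV
#' @param path TSV path.
#' @return Data frame.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(pm)))
    stop("probe map needs probe_id and gene_id columns")
  pm
}

#' Read a differential-expression table (gene_id, log2fc, q) from TSV
#'
#' Malformed rows (missing gene id, non-numeric or out-of-range q) are
#' rejected with their line number.
#'
#' @param path TSV path with a header line.
#' @return Data frame with `gene_id`, `log2fc`, `q`.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "q") %in% names(df)))
    stop("DEG table needs gene_id and q columns")
  bad <- which(is.na(df$gene_id) | df$gene_id == "" |
                 is.na(suppressWarnings(as.numeric(df$q))) |
                 df$q < 0 | df$q > 1)
  if (length(bad)) stop("malformed DEG row at line ", bad[1] + 1L)
  df
}

#' Write a generic data frame to TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write NanoString-style raw counts to CSV
#'
#' Layout: `gene`, `class` (`Endogenous`/`Positive`/`Negative`/
#' `Housekeeping`), then one column per sample. The sample sheet is written
#' alongside with suffix `.samples.csv`.
#'
#' @param raw A [nanostring_raw()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nanostring_csv <- function(raw, path) {
  stopifnot(inherits(raw, "nanostring_raw"))
  df <- data.frame(gene = rownames(raw$counts), class = raw$gene_class,
                   raw$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(raw$samples, sub("\\.csv$", ".samples.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read NanoString-style raw counts from CSV
#' @param path CSV written by [write_nanostring_csv()] (the matching
#'   `.samples.csv` must sit next to it).
#' @return A [nanostring_raw()] object.
#' @export
read_nanostring_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene
  samples <- utils::read.csv(sub("\\.csv$", ".samples.csv", path),
                             stringsAsFactors = FALSE)
  samples$patient_id <- as.character(samples$patient_id)
  nanostring_raw(counts, df$class, samples)
}
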