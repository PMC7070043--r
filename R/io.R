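#' Write a count matrix as MTX plus TSV sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket sparse), `genes.tsv`, `barcodes.tsv`
#' and, when cell metadata is present, `metadata.tsv`.
#'
#' @param sim a `dex_sim` object or a plain genes x cells matrix.
#' @param dir output directory (created if needed).
#' @export
write_counts_mtx <- function(sim, dir) {
  counts <- if (is.list(sim)) sim$counts else sim
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (is.list(sim) && !is.null(sim$cell_meta)) {
    utils::write.table(sim$cell_meta, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `metadata.tsv`.
#' @return a `dex_sim`-shaped list with `counts` (dense integer matrix) and
#'   `cell_meta` (or `NULL`).
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  structure(list(counts = m, cell_meta = meta), class = "dex_sim")
}

#' Write reads as FASTQ
#'
#' @param reads data frame with `read_id` and `sequence` columns.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  # BStringSet: the trailing gene tag is an opaque label, not nucleotides
  x <- Biostrings::BStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file into a read data frame
#'
#' @param path FASTQ path.
#' @return data frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write peak intervals as BED
#'
#' @param peaks data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file of peaks
#'
#' @param path BED path.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)[, 1:3]
  names(x) <- c("chrom", "start", "end")
  x
}

#' Write / read a TSS annotation table
#'
#' Tab-separated with columns chrom, pos, strand, gene_id.
#'
#' @param tss data frame with `chrom`, `pos`, `strand`, `gene_id`.
#' @param path file path.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("chrom", "pos", "strand", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss
#' @export
read_tss <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
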