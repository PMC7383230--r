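# Plain-text interchange: MatrixMarket counts with TSV sidecars, signature
# lists, ground truth.

#' Write / read a counts matrix as MatrixMarket + TSV sidecars
#'
#' The matrix is stored features-by-cells (`matrix.mtx`) with `genes.tsv`
#' and `barcodes.tsv` sidecars, the droplet-platform convention.
#'
#' @param mat A `screen_matrix`.
#' @param dir Output directory (created if missing).
#' @return `read_counts_mtx` returns a `screen_matrix`.
#' @export
write_counts_mtx <- function(mat, dir) {
  stop_if_not(inherits(mat, "screen_matrix"), "mat must be a screen_matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(t(mat$counts), sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(mat$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mat$cell_meta, file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mat$repeat_counts)) {
    r <- methods::as(Matrix::Matrix(t(mat$repeat_counts), sparse = TRUE),
                     "generalMatrix")
    Matrix::writeMM(r, file.path(dir, "repeats.mtx"))
    writeLines(colnames(mat$repeat_counts),
               file.path(dir, "repeat_families.tsv"))
  }
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  gene_meta <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  cell_meta <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  counts <- t(m)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_meta$barcode, gene_meta$gene_id)
  repeat_counts <- NULL
  rp <- file.path(dir, "repeats.mtx")
  if (file.exists(rp)) {
    repeat_counts <- t(as.matrix(Matrix::readMM(rp)))
    storage.mode(repeat_counts) <- "integer"
    dimnames(repeat_counts) <- list(
      cell_meta$barcode,
      readLines(file.path(dir, "repeat_families.tsv")))
  }
  screen_matrix(counts, repeat_counts, cell_meta, gene_meta)
}

#' Write / read a gene signature as TSV
#'
#' One gene id per line, with a header.
#'
#' @param signature Character vector of gene ids.
#' @param path File path.
#' @return `read_signature` returns a character vector.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(data.frame(gene_id = signature), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)$gene_id
}

#' Write ground truth tables as TSV
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(truth$true_hit_sgrnas, file.path(dir, "truth_hits.tsv"))
  write_signature(truth$signature_genes,
                  file.path(dir, "truth_signature.tsv"))
  invisible(dir)
}
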