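#' Write a count matrix as MTX plus gene/cell sidecars and metadata CSV
#'
#' Market-matrix convention: genes in rows, cells in columns, with
#' `genes.tsv` / `barcodes.tsv` sidecars and the colData as
#' `cell_metadata.csv`.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  write.csv(cbind(cell = rownames(cd), cd),
            file.path(dir, "cell_metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an MTX-format count matrix into a SingleCellExperiment
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `cell_metadata.csv`.
#' @return a SingleCellExperiment with a sparse `counts` assay.
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_metadata.csv")
  cd <- if (file.exists(meta_path)) {
    md <- read.csv(meta_path, stringsAsFactors = FALSE)
    rownames(md) <- md$cell
    S4Vectors::DataFrame(md[colnames(m), setdiff(names(md), "cell"),
                            drop = FALSE])
  } else S4Vectors::DataFrame(row.names = colnames(m))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}
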