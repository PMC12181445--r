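# Plain-text interchange: MTX triplet + TSV sidecars for cell-level counts,
# TSV for bulk matrices and result tables.

#' Write single-cell counts as MTX plus TSV sidecars
#'
#' Writes \code{matrix.mtx} (sparse triplet, genes x cells),
#' \code{genes.tsv} (one symbol per line) and \code{cells.tsv} (cell
#' metadata with a \code{cell_id} column) into a directory.
#'
#' @param sce A \link[SingleCellExperiment]{SingleCellExperiment} (or
#'   SummarizedExperiment) with a \code{counts} assay.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @seealso [readCellCounts()]
#' @export
writeCellCounts <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    counts <- methods::as(assayMatrix(sce, "counts", "writeCellCounts input"),
                          "CsparseMatrix")
    Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "genes.tsv"))
    meta <- cbind(cell_id = colnames(counts), cellMeta(sce))
    utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read single-cell counts from MTX plus TSV sidecars
#'
#' @param dir Directory written by [writeCellCounts()] (or following the
#'   same layout).
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a sparse
#'   \code{counts} assay and the sidecar metadata as colData.
#' @export
readCellCounts <- function(dir) {
    counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                          "CsparseMatrix")
    genes <- readLines(file.path(dir, "genes.tsv"))
    meta <- utils::read.delim(file.path(dir, "cells.tsv"),
                              stringsAsFactors = FALSE)
    stopifnot(nrow(counts) == length(genes), ncol(counts) == nrow(meta))
    dimnames(counts) <- list(genes, meta$cell_id)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta[setdiff(colnames(meta), "cell_id")],
                                       row.names = meta$cell_id))
}

#' Write a gene-by-sample matrix with group labels as TSV
#'
#' The first column is the gene name; a leading comment line
#' (\code{#groups:}) records one group label per sample column.
#'
#' @param se A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay and a \code{group} colData column.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeBulkCounts <- function(se, path) {
    m <- as.matrix(assayMatrix(se, "counts", "writeBulkCounts input"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#groups:\t", paste(se$group, collapse = "\t")), con)
    utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene-by-sample matrix with group labels from TSV
#'
#' @param path TSV written by [writeBulkCounts()].
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay and \code{group} colData.
#' @export
readBulkCounts <- function(path) {
    header <- readLines(path, n = 1L)
    if (!startsWith(header, "#groups:"))
        stop("missing '#groups:' header line in ", path)
    groups <- strsplit(header, "\t", fixed = TRUE)[[1L]][-1L]
    tab <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    stopifnot(length(groups) == ncol(m))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(group = groups,
                                       sample_id = colnames(m),
                                       row.names = colnames(m)))
}
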