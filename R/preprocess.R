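#' Log-normalize counts
#'
#' Library-size normalization followed by a log transform:
#' \code{value(g, c) = ln(1 + count(g, c) / total(c) * scale)} with
#' \code{scale = 1e4} by default (the convention widely used for scRNA-seq
#' log-normalization). Cells whose total count is zero are dropped with a
#' warning rather than imputed.
#'
#' @param x A \link[SingleCellExperiment]{SingleCellExperiment} /
#'   \link[SummarizedExperiment]{SummarizedExperiment} with a \code{counts}
#'   assay, or a genes-by-cells (sparse) matrix of nonnegative counts.
#' @param scale Scale factor applied after library-size division.
#' @return Same container as the input with a \code{logcounts} assay added
#'   (zero-total cells removed), or a dense matrix for matrix input.
#' @examples
#' m <- matrix(c(10, 0, 5, 5), 2, 2, dimnames = list(c("g1", "g2"), NULL))
#' logNormalize(m)
#' @export
logNormalize <- function(x, scale = 1e4) {
    counts <- assayMatrix(x, "counts", "logNormalize input")
    if (min(counts) < 0) stop("counts must be nonnegative")
    totals <- Matrix::colSums(counts)
    if (any(totals == 0)) {
        warning(sprintf("dropping %d cell(s) with zero total counts",
                        sum(totals == 0)))
        keep <- totals > 0
        x <- x[, keep]
        counts <- counts[, keep, drop = FALSE]
        totals <- totals[keep]
    }
    norm <- log1p(sweep(as.matrix(counts), 2L, totals, "/") * scale)
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "logcounts") <- norm
        x
    } else norm
}

#' Per-gene z-scores
#'
#' Standardizes each gene (row) to mean 0 and standard deviation 1 across
#' cells, the preparation step for the composite senescence score. Genes with
#' zero variance become all-zero rows. The sample standard deviation
#' (\code{n - 1} denominator) is the default; the population denominator is
#' available and changes scores only by a constant factor, never orderings.
#'
#' @param x A container with a \code{logcounts} assay (e.g. output of
#'   [logNormalize()]) or a genes-by-cells matrix of finite values.
#' @param denom \code{"sample"} (default) or \code{"population"} standard
#'   deviation.
#' @return Input container with a dense \code{zscore} assay added, or a dense
#'   matrix for matrix input.
#' @export
zscoreGenes <- function(x, denom = c("sample", "population")) {
    denom <- match.arg(denom)
    vals <- as.matrix(assayMatrix(x, "logcounts", "zscoreGenes input"))
    if (!all(is.finite(vals))) stop("input contains non-finite values")
    n <- ncol(vals)
    mu <- rowMeans(vals)
    ss <- rowSums((vals - mu)^2)
    sd <- sqrt(ss / (if (denom == "sample") max(n - 1L, 1L) else n))
    z <- (vals - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "zscore") <- z
        x
    } else z
}

#' Pseudobulk aggregation of single-cell counts
#'
#' Sums raw counts over groups of cells (by sample, cell type, or both) to
#' form bulk-like expression columns, as used to feed the inter-gene
#' correlation clustering. Group columns are ordered deterministically
#' (sorted by key). Aggregating the mean of log-normalized values is offered
#' as an alternative.
#'
#' @param x A \link[SingleCellExperiment]{SingleCellExperiment} (or
#'   SummarizedExperiment) whose colData contains the grouping keys.
#' @param groupby Character vector of colData column names; groups are the
#'   observed combinations of the key values.
#' @param aggregate \code{"sum_counts"} (default) or \code{"mean_lognorm"}
#'   (requires a \code{logcounts} assay).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} (genes x
#'   groups) with a \code{pseudobulk} assay and colData carrying the key
#'   values plus \code{n_cells}.
#' @examples
#' sce <- simulateCells(simConfig(nGenes = 100,
#'                                cellsPerType = c(Fibroblast = 20),
#'                                nSamplesPerCondition = 2, seed = 1))
#' pb <- pseudobulk(sce, "sample_id")
#' ncol(pb)
#' @export
pseudobulk <- function(x, groupby = "sample_id",
                       aggregate = c("sum_counts", "mean_lognorm")) {
    aggregate <- match.arg(aggregate)
    stopifnot(is(x, "SummarizedExperiment"))
    meta <- cellMeta(x)
    missing <- setdiff(groupby, colnames(meta))
    if (length(missing))
        stop("unknown grouping key(s): ", paste(missing, collapse = ", "))
    keys <- do.call(paste, c(meta[groupby], sep = "."))
    levels <- sort(unique(keys))
    fac <- factor(keys, levels = levels)
    vals <- assayMatrix(x, if (aggregate == "sum_counts") "counts" else "logcounts",
                        "pseudobulk input")
    out <- sapply(levels, function(l) {
        cols <- which(fac == l)
        v <- Matrix::rowSums(vals[, cols, drop = FALSE])
        if (aggregate == "mean_lognorm") v <- v / length(cols)
        v
    })
    out <- as.matrix(out)
    rownames(out) <- rownames(vals)
    keyMeta <- meta[match(levels, keys), groupby, drop = FALSE]
    rownames(keyMeta) <- levels
    SummarizedExperiment::SummarizedExperiment(
        assays = setNames(list(out), "pseudobulk"),
        colData = S4Vectors::DataFrame(keyMeta,
                                       n_cells = as.integer(table(fac)[levels])))
}
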