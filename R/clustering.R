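# Inter-gene correlation clustering of pseudobulk expression: skewness-gated
# log transform, per-gene standardization, Pearson (or Spearman)
# correlation, complete-linkage agglomeration on d = 1 - r.

#' Sample skewness
#'
#' Third standardized moment of a numeric vector. The default is the adjusted
#' Fisher-Pearson estimator \code{G1 = g1 * sqrt(n(n-1))/(n-2)} (the common
#' default in statistical software); the uncorrected \code{g1 = m3/m2^(3/2)}
#' and the \code{b1} variant (s in the denominator) are available because a
#' skewness-threshold rule can depend on the estimator.
#'
#' @param x Numeric vector, length >= 3.
#' @param method One of \code{"adjusted"}, \code{"g1"}, \code{"b1"}.
#' @return The skewness; 0 with a warning for degenerate input (length < 3
#'   or zero variance).
#' @examples
#' geneSkewness(c(-1, 0, 1))   # 0
#' geneSkewness(c(0, 0, 0, 10))
#' @export
geneSkewness <- function(x, method = c("adjusted", "g1", "b1")) {
    method <- match.arg(method)
    x <- as.numeric(x)
    if (length(x) < 3L || stats::var(x) == 0) {
        warning("skewness undefined for length < 3 or zero variance; returning 0")
        return(0)
    }
    type <- c(adjusted = 2L, g1 = 1L, b1 = 3L)[[method]]
    e1071::skewness(x, type = type)
}

#' Skewness-gated log transform of pseudobulk expression
#'
#' Computes per-gene skewness across pseudobulk columns and, if any gene
#' exceeds the threshold (default 2), applies \code{ln(1 + x)}. In the
#' default \code{"global"} mode the transform is applied to every gene once
#' any gene triggers — the rule under which "nine genes with skewness above
#' 2" log-transforms the whole matrix; \code{"per_gene"} transforms only the
#' triggering genes.
#'
#' @param pb A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{pseudobulk} assay (see [pseudobulk()]) or a nonnegative
#'   genes-by-groups matrix.
#' @param threshold Skewness threshold.
#' @param mode \code{"global"} or \code{"per_gene"}.
#' @param method Skewness estimator passed to [geneSkewness()].
#' @return Same container as the input with transformed values; the attribute
#'   (or metadata entry) \code{triggered} lists the genes whose skewness
#'   exceeded the threshold, and \code{transformed} says whether the log was
#'   applied.
#' @export
gatedLogTransform <- function(pb, threshold = 2, mode = c("global", "per_gene"),
                              method = "adjusted") {
    mode <- match.arg(mode)
    vals <- as.matrix(assayMatrix(pb, "pseudobulk", "gatedLogTransform input"))
    if (min(vals) < 0) stop("values must be nonnegative")
    skew <- apply(vals, 1L, function(x)
        suppressWarnings(geneSkewness(x, method = method)))
    triggered <- rownames(vals)[skew > threshold]
    out <- vals
    if (length(triggered)) {
        if (mode == "global") out <- log1p(vals)
        else out[skew > threshold, ] <- log1p(vals[skew > threshold, , drop = FALSE])
    }
    if (is(pb, "SummarizedExperiment")) {
        SummarizedExperiment::assay(pb, "pseudobulk") <- out
        S4Vectors::metadata(pb)$triggered <- triggered
        S4Vectors::metadata(pb)$transformed <- length(triggered) > 0L
        pb
    } else {
        attr(out, "triggered") <- triggered
        attr(out, "transformed") <- length(triggered) > 0L
        out
    }
}

#' Inter-gene correlation matrix
#'
#' Pearson (default) or Spearman correlation between gene rows across
#' pseudobulk columns. Standardization of rows does not change Pearson
#' correlations, so the matrix equals the correlation of standardized
#' expression. Zero-variance genes get correlation 0 with every other gene
#' and 1 with themselves, and are reported in the \code{flagged} attribute.
#'
#' @param pb A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{pseudobulk} assay, or a genes-by-groups matrix with at least 3
#'   columns.
#' @param genes Optional subset of genes (case-insensitive match).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
geneCorrelation <- function(pb, genes = NULL,
                            method = c("pearson", "spearman")) {
    method <- match.arg(method)
    vals <- as.matrix(assayMatrix(pb, "pseudobulk", "geneCorrelation input"))
    if (ncol(vals) < 3L)
        stop("at least 3 pseudobulk columns are required for correlations")
    if (!is.null(genes)) {
        idx <- matchGenes(genes, rownames(vals))
        if (anyNA(idx))
            stop("genes not found: ",
                 paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
        vals <- vals[idx, , drop = FALSE]
    }
    corr <- suppressWarnings(stats::cor(t(vals), method = method))
    flagged <- rownames(vals)[apply(vals, 1L, stats::var) == 0]
    corr[is.na(corr)] <- 0
    diag(corr) <- 1
    attr(corr, "flagged") <- flagged
    corr
}

#' Complete-linkage clustering of genes from a correlation matrix
#'
#' Agglomerative clustering on the distance \code{d = 1 - r} (sign
#' preserved: anticorrelated genes are far apart) with complete linkage, cut
#' into \code{k} clusters (default 5). Cluster labels are ordered by
#' dendrogram position, so cluster 1 is the leftmost block of the dendrogram
#' and each cluster is contiguous along it.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (e.g. from
#'   [geneCorrelation()]).
#' @param k Number of clusters, between 1 and the number of genes.
#' @return A [GeneClustering-class] object.
#' @examples
#' pbm <- matrix(rnorm(40), 8, 5,
#'               dimnames = list(paste0("g", 1:8), NULL))
#' cl <- completeLinkage(geneCorrelation(pbm), k = 3)
#' clusterAssignments(cl)
#' @export
completeLinkage <- function(corr, k = 5L) {
    stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
    n <- nrow(corr)
    if (k < 1L || k > n) stop("'k' must be between 1 and the number of genes")
    if (is.null(rownames(corr)))
        rownames(corr) <- colnames(corr) <- paste0("g", seq_len(n))
    attr(corr, "flagged") <- NULL
    if (n == 1L)
        return(new("GeneClustering", genes = rownames(corr), corr = corr,
                   hclust = NULL, k = 1L,
                   assignment = setNames(1L, rownames(corr)), order = 1L))
    hc <- stats::hclust(stats::as.dist(1 - corr), method = "complete")
    raw <- stats::cutree(hc, k = k)
    # relabel so clusters are numbered by dendrogram position
    relabel <- match(raw, unique(raw[hc$order]))
    assignment <- setNames(as.integer(relabel), rownames(corr))
    new("GeneClustering", genes = rownames(corr), corr = corr, hclust = hc,
        k = as.integer(k), assignment = assignment,
        order = as.integer(hc$order))
}
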