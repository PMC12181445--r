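#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Signed gene set
#'
#' A gene set whose members are annotated as expected up-regulated or expected
#' down-regulated under the condition of interest (here: cellular senescence).
#' The two lists are disjoint, symbols are unique within each list
#' (case-insensitively), and the union is non-empty.
#'
#' @slot name Single character, the set name.
#' @slot upGenes Character vector of expected up-regulated gene symbols.
#' @slot downGenes Character vector of expected down-regulated gene symbols.
#'
#' @seealso [builtinSenSkin()], [readSignedGmt()], [compositeScore()]
#' @export
setClass("SignedGeneSet",
         representation(name = "character",
                        upGenes = "character",
                        downGenes = "character"))

setValidity("SignedGeneSet", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    for (side in c("upGenes", "downGenes")) {
        g <- slot(object, side)
        if (anyNA(g) || any(!nzchar(g)))
            msg <- c(msg, sprintf("'%s' contains NA or empty symbols", side))
        else if (anyDuplicated(toupper(g)))
            msg <- c(msg, sprintf("'%s' contains duplicate symbols", side))
    }
    if (length(object@upGenes) + length(object@downGenes) == 0L)
        msg <- c(msg, "gene set is empty")
    if (length(intersect(toupper(object@upGenes), toupper(object@downGenes))))
        msg <- c(msg, "'upGenes' and 'downGenes' must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Construct a SignedGeneSet
#'
#' @param name Set name.
#' @param upGenes Character vector of expected up-regulated symbols.
#' @param downGenes Character vector of expected down-regulated symbols
#'   (may be empty).
#'
#' @return A [SignedGeneSet-class] object. Symbols are whitespace-trimmed;
#'   case is preserved as given.
#' @examples
#' SignedGeneSet("demo", upGenes = c("JUN", "FOS"), downGenes = "LMNB1")
#' @export
SignedGeneSet <- function(name, upGenes = character(0), downGenes = character(0)) {
    new("SignedGeneSet",
        name = as.character(name),
        upGenes = trimws(as.character(upGenes)),
        downGenes = trimws(as.character(downGenes)))
}

#' Simulation configuration for synthetic skin RNA-seq data
#'
#' Parameters of the negative-binomial generator used by [simulateCells()] and
#' [simulateBulk()]. The two conditions emulate a UV-protected versus
#' UV-exposed (or young versus old) contrast; in the second condition a
#' fraction of cells per cell type carries the senescence program: up-gene
#' log-means shifted by \code{+effectDelta}, down-gene log-means by
#' \code{-downDelta}.
#'
#' @slot nGenes Number of genes in the simulated universe (signature genes are
#'   added if the universe would not contain them).
#' @slot cellsPerType Named integer vector: cells per cell type per condition.
#' @slot conditions Two condition labels; the second carries the program.
#' @slot nSamplesPerCondition Donors/samples per condition (24 matches the
#'   young-versus-old bulk design this emulates).
#' @slot effectDelta Log-scale mean shift added to up-genes in affected cells.
#' @slot affectedFraction Fraction of condition-2 cells per cell type that
#'   carry the program; scalar or named per cell type.
#' @slot downDelta Log-scale mean shift subtracted from down-genes.
#' @slot nbDispersion Negative-binomial dispersion (1/size).
#' @slot libsizeLognormal Numeric (meanlog, sdlog) of the per-cell library
#'   size factor.
#' @slot seed Integer seed; a fixed seed gives bit-identical output.
#' @export
setClass("SimulationConfig",
         representation(nGenes = "integer",
                        cellsPerType = "integer",
                        conditions = "character",
                        nSamplesPerCondition = "integer",
                        effectDelta = "numeric",
                        affectedFraction = "numeric",
                        downDelta = "numeric",
                        nbDispersion = "numeric",
                        libsizeLognormal = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (object@nGenes < 1L) msg <- c(msg, "'nGenes' must be positive")
    if (length(object@cellsPerType) < 1L || any(object@cellsPerType < 1L) ||
        is.null(names(object@cellsPerType)) || anyDuplicated(names(object@cellsPerType)))
        msg <- c(msg, "'cellsPerType' must be a named vector of positive counts with unique names")
    if (length(object@conditions) != 2L || anyDuplicated(object@conditions))
        msg <- c(msg, "'conditions' must be exactly two distinct labels")
    if (object@nSamplesPerCondition < 1L)
        msg <- c(msg, "'nSamplesPerCondition' must be positive")
    if (object@effectDelta < 0) msg <- c(msg, "'effectDelta' must be nonnegative")
    if (object@downDelta < 0) msg <- c(msg, "'downDelta' must be nonnegative")
    af <- object@affectedFraction
    if (any(af < 0) || any(af > 1))
        msg <- c(msg, "'affectedFraction' must lie in [0, 1]")
    if (length(af) > 1L && !all(names(af) %in% names(object@cellsPerType)))
        msg <- c(msg, "names of 'affectedFraction' must be cell types from 'cellsPerType'")
    if (object@nbDispersion <= 0) msg <- c(msg, "'nbDispersion' must be positive")
    if (length(object@libsizeLognormal) != 2L || object@libsizeLognormal[2L] < 0)
        msg <- c(msg, "'libsizeLognormal' must be (meanlog, sdlog) with sdlog >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the study designs the analysis targets: six skin cell
#' types with two conditions (UV-protected versus UV-exposed) for the
#' single-cell generator, and 24 samples per group (young versus old) for the
#' bulk generator.
#'
#' @param nGenes Simulated gene universe size.
#' @param cellsPerType Named vector, cells per cell type per condition.
#' @param conditions Two condition labels, the second condition carries the
#'   injected senescence program.
#' @param nSamplesPerCondition Donors (single-cell) or samples (bulk) per
#'   condition.
#' @param effectDelta,downDelta Log-mean shifts applied to the signed set's
#'   up- and down-genes in affected cells (comparable to the natural-log
#'   fold-change scale used by the differential-expression cutoff).
#' @param affectedFraction Fraction of condition-2 cells per cell type that
#'   carry the program (scalar, or named per cell type; unnamed types get 0
#'   when a named vector is supplied).
#' @param nbDispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param libsizeLognormal Numeric (meanlog, sdlog) for per-cell/sample
#'   library-size factors.
#' @param seed Integer seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 500, effectDelta = 1)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L,
                      cellsPerType = c(Fibroblast = 120L, Keratinocyte = 120L,
                                       TCell = 120L, Macrophage = 120L,
                                       Pericyte = 120L, VascularEC = 120L),
                      conditions = c("UVprotected", "UVexposed"),
                      nSamplesPerCondition = 24L,
                      effectDelta = 1,
                      affectedFraction = 1,
                      downDelta = 1,
                      nbDispersion = 0.4,
                      libsizeLognormal = c(0, 0.35),
                      seed = 1L) {
    cpt <- as.integer(cellsPerType)
    names(cpt) <- names(cellsPerType)
    new("SimulationConfig",
        nGenes = as.integer(nGenes),
        cellsPerType = cpt,
        conditions = as.character(conditions),
        nSamplesPerCondition = as.integer(nSamplesPerCondition),
        effectDelta = as.numeric(effectDelta),
        affectedFraction = setNames(as.numeric(affectedFraction),
                                    names(affectedFraction)),
        downDelta = as.numeric(downDelta),
        nbDispersion = as.numeric(nbDispersion),
        libsizeLognormal = as.numeric(libsizeLognormal),
        seed = as.integer(seed))
}

#' Gene clustering result
#'
#' Complete-linkage agglomerative clustering of genes on the distance
#' \code{1 - r} derived from an inter-gene correlation matrix, cut into
#' \code{k} clusters. Cluster ids are relabelled so that cluster 1 appears
#' first in dendrogram order; each cluster occupies a contiguous block of the
#' dendrogram.
#'
#' @slot genes Character vector of gene names (input order).
#' @slot corr Symmetric correlation matrix with unit diagonal.
#' @slot hclust The \code{stats::hclust} merge tree.
#' @slot k Number of clusters.
#' @slot assignment Named integer vector, gene -> cluster id in 1..k.
#' @slot order Integer permutation of genes (dendrogram leaf order).
#' @seealso [completeLinkage()]
#' @export
setClass("GeneClustering",
         representation(genes = "character",
                        corr = "matrix",
                        hclust = "ANY",
                        k = "integer",
                        assignment = "integer",
                        order = "integer"))

setValidity("GeneClustering", function(object) {
    msg <- character(0)
    n <- length(object@genes)
    if (!identical(dim(object@corr), c(n, n)))
        msg <- c(msg, "'corr' dimensions do not match 'genes'")
    else {
        if (max(abs(object@corr - t(object@corr))) > 1e-8)
            msg <- c(msg, "'corr' is not symmetric")
        if (max(abs(diag(object@corr) - 1)) > 1e-8)
            msg <- c(msg, "'corr' diagonal is not 1")
        if (any(object@corr < -1 - 1e-8) || any(object@corr > 1 + 1e-8))
            msg <- c(msg, "'corr' entries outside [-1, 1]")
    }
    if (object@k < 1L || object@k > n)
        msg <- c(msg, "'k' out of range")
    if (length(object@assignment) != n ||
        !setequal(unique(object@assignment), seq_len(object@k)))
        msg <- c(msg, sprintf("'assignment' must use exactly %d non-empty clusters", object@k))
    if (!identical(sort(object@order), seq_len(n)))
        msg <- c(msg, "'order' is not a permutation of the genes")
    else {
        # clusters must be contiguous blocks along the dendrogram
        along <- object@assignment[object@order]
        if (sum(diff(along) != 0) != length(unique(along)) - 1L)
            msg <- c(msg, "clusters are not contiguous in dendrogram order")
    }
    if (length(msg)) msg else TRUE
})
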