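# Negative-binomial simulators for skin RNA-seq designs. Counts are
# NB(mu, size = 1/dispersion) with gene-specific baseline log-means,
# cell-type marker boosts, lognormal library-size factors and a mild
# per-donor factor. In the second condition, affected cells/samples carry
# the senescence program: up-genes +effectDelta and down-genes -downDelta
# on the log-mean scale, so deltas are directly comparable to natural-log
# fold changes.

# Gene universe containing all signature genes plus synthetic filler names.
simUniverse <- function(config, set) {
    setGenes <- unionGenes(set)
    nFiller <- max(config@nGenes - length(setGenes), 0L)
    c(setGenes, sprintf("GENE%05d", seq_len(nFiller)))
}

# Per-cell-type affected fraction resolved from scalar or named vector.
resolveAffected <- function(config) {
    types <- names(config@cellsPerType)
    af <- config@affectedFraction
    if (length(af) == 1L && is.null(names(af)))
        return(setNames(rep(af, length(types)), types))
    out <- setNames(rep(0, length(types)), types)
    out[names(af)] <- af
    out
}

#' Simulate a single-cell skin RNA-seq experiment
#'
#' Generates a cell-by-gene count matrix (genes in rows, Bioconductor
#' convention) for two conditions across several skin cell types, with the
#' signed senescence signature embedded as ground truth: in the second
#' condition, a configured fraction of cells per cell type has up-gene
#' log-means shifted by \code{+effectDelta} and down-gene log-means by
#' \code{-downDelta}. The \code{truth_affected} column records exactly which
#' cells carry the program, so downstream recovery can be measured without
#' re-deriving truth. A fixed seed yields bit-identical output.
#'
#' @param config A [SimulationConfig-class].
#' @param set The embedded [SignedGeneSet-class] (default the packaged
#'   SenSkin signature). Its genes are always included in the gene universe.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a sparse
#'   \code{counts} assay and colData columns \code{cell_type},
#'   \code{condition}, \code{sample_id}, \code{truth_affected}.
#' @examples
#' sce <- simulateCells(simConfig(nGenes = 300,
#'                                cellsPerType = c(Fibroblast = 40),
#'                                seed = 7))
#' table(sce$condition)
#' @export
simulateCells <- function(config, set = builtinSenSkin()) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    withSeed(config@seed, {
        genes <- simUniverse(config, set)
        nG <- length(genes)
        upIdx <- which(!is.na(matchGenes(genes, upGenes(set))))
        dnIdx <- which(!is.na(matchGenes(genes, downGenes(set))))
        types <- names(config@cellsPerType)
        conds <- config@conditions
        affFrac <- resolveAffected(config)

        logMu <- stats::rnorm(nG, mean = log(0.5), sd = 1.2)
        # cell-type markers drawn outside the signature so the embedded
        # program is the only systematic condition difference
        nonSet <- setdiff(seq_len(nG), c(upIdx, dnIdx))
        nMark <- min(length(nonSet), max(1L, round(0.05 * nG)))
        markers <- lapply(types, function(t) sort(sample(nonSet, nMark)))
        names(markers) <- types

        donors <- lapply(conds, function(cn)
            sprintf("%s_donor%02d", cn, seq_len(config@nSamplesPerCondition)))
        names(donors) <- conds
        donorFactor <- lapply(conds, function(cn)
            setNames(exp(stats::rnorm(config@nSamplesPerCondition, 0, 0.1)),
                     donors[[cn]]))
        names(donorFactor) <- conds

        nCells <- sum(config@cellsPerType) * 2L
        counts <- matrix(0L, nrow = nG, ncol = nCells)
        cellType <- character(nCells); cond <- character(nCells)
        sampleId <- character(nCells); affected <- logical(nCells)
        size <- 1 / config@nbDispersion

        j <- 0L
        for (t in types) {
            boost <- numeric(nG)
            boost[markers[[t]]] <- 1
            for (ci in 1:2) {
                cn <- conds[ci]
                n <- config@cellsPerType[[t]]
                lib <- exp(stats::rnorm(n, config@libsizeLognormal[1L],
                                        config@libsizeLognormal[2L]))
                dn <- rep_len(donors[[cn]], n)
                aff <- rep(FALSE, n)
                if (ci == 2L) {
                    nAff <- round(affFrac[[t]] * n)
                    if (nAff > 0L) aff[sample(n, nAff)] <- TRUE
                }
                baseMu <- exp(logMu + boost)
                shiftMu <- baseMu
                shiftMu[upIdx] <- shiftMu[upIdx] * exp(config@effectDelta)
                shiftMu[dnIdx] <- shiftMu[dnIdx] * exp(-config@downDelta)
                for (i in seq_len(n)) {
                    j <- j + 1L
                    mu <- (if (aff[i]) shiftMu else baseMu) *
                        lib[i] * donorFactor[[cn]][[dn[i]]]
                    counts[, j] <- stats::rnbinom(nG, mu = mu, size = size)
                    cellType[j] <- t; cond[j] <- cn
                    sampleId[j] <- dn[i]; affected[j] <- aff[i]
                }
            }
        }
        dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(nCells)))
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = methods::as(counts, "CsparseMatrix")),
            colData = S4Vectors::DataFrame(cell_type = cellType,
                                           condition = cond,
                                           sample_id = sampleId,
                                           truth_affected = affected,
                                           row.names = colnames(counts)))
        S4Vectors::metadata(sce) <- list(config = config,
                                         geneSet = geneSetName(set),
                                         markerGenes = lapply(markers, function(i) genes[i]))
        sce
    })
}

#' Simulate a bulk RNA-seq experiment
#'
#' Generates a gene-by-sample negative-binomial count matrix for two groups
#' (default 24 versus 24 samples, the young-versus-old epidermis design this
#' emulates). All samples of the second group carry the signed-set shift:
#' up-genes \code{+effectDelta}, down-genes \code{-downDelta} on the log-mean
#' scale.
#'
#' @inheritParams simulateCells
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay and colData columns \code{group} and
#'   \code{sample_id}.
#' @examples
#' se <- simulateBulk(simConfig(nGenes = 300, seed = 3))
#' table(se$group)
#' @export
simulateBulk <- function(config, set = builtinSenSkin()) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    withSeed(config@seed, {
        genes <- simUniverse(config, set)
        nG <- length(genes)
        upIdx <- which(!is.na(matchGenes(genes, upGenes(set))))
        dnIdx <- which(!is.na(matchGenes(genes, downGenes(set))))
        conds <- config@conditions
        nS <- config@nSamplesPerCondition
        size <- 1 / config@nbDispersion

        logMu <- stats::rnorm(nG, mean = log(100), sd = 1.2)
        counts <- matrix(0L, nrow = nG, ncol = 2L * nS)
        group <- rep(conds, each = nS)
        sampleId <- sprintf("%s_s%02d", group, rep(seq_len(nS), 2L))
        for (j in seq_len(2L * nS)) {
            lib <- exp(stats::rnorm(1, config@libsizeLognormal[1L],
                                    config@libsizeLognormal[2L]))
            mu <- exp(logMu)
            if (group[j] == conds[2L]) {
                mu[upIdx] <- mu[upIdx] * exp(config@effectDelta)
                mu[dnIdx] <- mu[dnIdx] * exp(-config@downDelta)
            }
            counts[, j] <- stats::rnbinom(nG, mu = mu * lib, size = size)
        }
        dimnames(counts) <- list(genes, sampleId)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(group = group,
                                           sample_id = sampleId,
                                           row.names = sampleId))
        S4Vectors::metadata(se) <- list(config = config,
                                        geneSet = geneSetName(set))
        se
    })
}
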