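#' @rdname SignedGeneSet-class
#' @param object,x A \code{SignedGeneSet} or \code{GeneClustering} object.
#' @export
setGeneric("geneSetName", function(object) standardGeneric("geneSetName"))

#' @rdname SignedGeneSet-class
#' @export
setGeneric("upGenes", function(object) standardGeneric("upGenes"))

#' @rdname SignedGeneSet-class
#' @export
setGeneric("downGenes", function(object) standardGeneric("downGenes"))

#' @rdname SignedGeneSet-class
#' @export
setGeneric("unionGenes", function(object) standardGeneric("unionGenes"))

#' @rdname GeneClustering-class
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))

#' @rdname GeneClustering-class
#' @export
setGeneric("dendrogramOrder", function(object) standardGeneric("dendrogramOrder"))

#' @rdname GeneClustering-class
#' @export
setGeneric("geneCorrelations", function(object) standardGeneric("geneCorrelations"))

setMethod("geneSetName", "SignedGeneSet", function(object) object@name)
setMethod("upGenes", "SignedGeneSet", function(object) object@upGenes)
setMethod("downGenes", "SignedGeneSet", function(object) object@downGenes)
setMethod("unionGenes", "SignedGeneSet",
          function(object) c(object@upGenes, object@downGenes))

#' @rdname SignedGeneSet-class
#' @export
setMethod("length", "SignedGeneSet",
          function(x) length(x@upGenes) + length(x@downGenes))

setMethod("show", "SignedGeneSet", function(object) {
    cat(sprintf("SignedGeneSet '%s': %d genes (%d up, %d down)\n",
                object@name, length(object),
                length(object@upGenes), length(object@downGenes)))
    preview <- function(g) {
        if (!length(g)) return("<none>")
        shown <- paste(utils::head(g, 6L), collapse = ", ")
        if (length(g) > 6L) shown <- paste0(shown, ", ...")
        shown
    }
    cat("  up:   ", preview(object@upGenes), "\n")
    cat("  down: ", preview(object@downGenes), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  genes: %d | conditions: %s vs %s | samples/condition: %d\n",
                object@nGenes, object@conditions[1L], object@conditions[2L],
                object@nSamplesPerCondition))
    cat(sprintf("  cell types: %s\n",
                paste(sprintf("%s(%d)", names(object@cellsPerType),
                              object@cellsPerType), collapse = ", ")))
    cat(sprintf("  effectDelta: %g | downDelta: %g | affectedFraction: %s\n",
                object@effectDelta, object@downDelta,
                paste(format(object@affectedFraction), collapse = ",")))
    cat(sprintf("  nbDispersion: %g | libsize meanlog/sdlog: %g/%g | seed: %d\n",
                object@nbDispersion, object@libsizeLognormal[1L],
                object@libsizeLognormal[2L], object@seed))
})

setMethod("clusterAssignments", "GeneClustering", function(object) object@assignment)
setMethod("dendrogramOrder", "GeneClustering", function(object) object@order)
setMethod("geneCorrelations", "GeneClustering", function(object) object@corr)

#' @rdname GeneClustering-class
#' @export
setMethod("length", "GeneClustering", function(x) length(x@genes))

setMethod("show", "GeneClustering", function(object) {
    sizes <- table(object@assignment)
    cat(sprintf("GeneClustering: %d genes, complete linkage on 1 - r, k = %d\n",
                length(object@genes), object@k))
    cat("  cluster sizes:", paste(sprintf("%s:%d", names(sizes), sizes),
                                  collapse = " "), "\n")
})
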