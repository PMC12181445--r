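#' The SenSkin skin-specific cellular senescence gene set
#'
#' Returns the packaged SenSkin signature: 164 genes expected to be
#' up-regulated in senescent skin cells and one gene expected to be
#' down-regulated (LMNB1), 165 symbols in total. The signature was curated
#' from the skin-senescence literature; symbols are packaged verbatim in
#' \code{inst/extdata/senskin_genes.tsv} (one symbol per line with an
#' up/down column) and guarded by a checksum test so transcription drift
#' cannot pass silently.
#'
#' @return A [SignedGeneSet-class] named \code{"SenSkin"}.
#' @examples
#' ss <- builtinSenSkin()
#' length(ss)            # 165
#' downGenes(ss)         # "LMNB1"
#' @export
builtinSenSkin <- function() {
    path <- system.file("extdata", "senskin_genes.tsv",
                        package = "SenSkinTools", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    SignedGeneSet("SenSkin",
                  upGenes = tab$symbol[tab$direction == "up"],
                  downGenes = tab$symbol[tab$direction == "down"])
}

#' Read signed gene sets from a GMT file
#'
#' Standard GMT has no direction field, so a signed dialect is used: a pair of
#' lines named \code{<NAME>_UP} and \code{<NAME>_DN} merges into one
#' [SignedGeneSet-class]; a line without either suffix yields a set whose
#' genes are all treated as up-regulated (empty down list). Each line is
#' tab-separated: name, description, then at least one gene symbol.
#'
#' @param path Path to a GMT file.
#' @return A list of [SignedGeneSet-class] objects, in order of first
#'   appearance of each set name. Duplicate symbols within a line are dropped
#'   with a warning.
#' @seealso [writeSignedGmt()]
#' @export
readSignedGmt <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) return(list())

    up <- list(); dn <- list(); order <- character(0)
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        fields <- trimws(fields)
        if (length(fields) < 3L)
            stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields, got %d",
                         lineno[i], length(fields)))
        name <- fields[1L]
        genes <- fields[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(toupper(genes))) {
            warning(sprintf("GMT line %d ('%s'): duplicate symbols removed", lineno[i], name))
            genes <- genes[!duplicated(toupper(genes))]
        }
        if (grepl("_UP$", name)) {
            stem <- sub("_UP$", "", name)
            up[[stem]] <- c(up[[stem]], genes)
        } else if (grepl("_DN$", name)) {
            stem <- sub("_DN$", "", name)
            dn[[stem]] <- c(dn[[stem]], genes)
        } else {
            stem <- name
            up[[stem]] <- c(up[[stem]], genes)
        }
        if (!stem %in% order) order <- c(order, stem)
    }
    lapply(order, function(nm) {
        SignedGeneSet(nm,
                      upGenes = if (is.null(up[[nm]])) character(0) else up[[nm]],
                      downGenes = if (is.null(dn[[nm]])) character(0) else dn[[nm]])
    })
}

#' Write signed gene sets to a GMT file
#'
#' Emits the signed dialect read by [readSignedGmt()]: one \code{<NAME>_UP}
#' line per set with up-genes and one \code{<NAME>_DN} line when the set has
#' down-genes. Reading the file back reproduces the sets exactly.
#'
#' @param sets A [SignedGeneSet-class] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSignedGmt <- function(sets, path) {
    if (is(sets, "SignedGeneSet")) sets <- list(sets)
    lines <- character(0)
    for (s in sets) {
        stopifnot(is(s, "SignedGeneSet"))
        validObject(s)
        if (length(upGenes(s)))
            lines <- c(lines, paste(c(paste0(geneSetName(s), "_UP"), ".",
                                      upGenes(s)), collapse = "\t"))
        if (length(downGenes(s)))
            lines <- c(lines, paste(c(paste0(geneSetName(s), "_DN"), ".",
                                      downGenes(s)), collapse = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Overlap between two signed gene sets
#'
#' Case-insensitive intersection of the unions (up and down combined) of two
#' sets, the operation used to compare a signature against other published
#' senescence sets.
#'
#' @param a,b [SignedGeneSet-class] objects.
#' @return A list with \code{count} (integer) and \code{shared} (symbols as
#'   spelled in `a`, in `a`'s order).
#' @examples
#' s1 <- SignedGeneSet("s1", c("A2M", "JUN"))
#' s2 <- SignedGeneSet("s2", c("jun", "TP53"))
#' geneOverlap(s1, s2)$count  # 1
#' @export
geneOverlap <- function(a, b) {
    stopifnot(is(a, "SignedGeneSet"), is(b, "SignedGeneSet"))
    ga <- unionGenes(a)
    shared <- ga[!is.na(matchGenes(ga, unionGenes(b)))]
    list(count = length(shared), shared = shared)
}

#' Coverage of a signed gene set in a measured gene universe
#'
#' Reports how many signature genes are present in a dataset's gene universe
#' (case-insensitive), and which are missing — e.g. a bulk platform may carry
#' only 145 of the 165 SenSkin genes.
#'
#' @param set A [SignedGeneSet-class].
#' @param universe Character vector of measured gene symbols.
#' @return A list with \code{n_total}, \code{n_present} and
#'   \code{missing_genes}; \code{n_present + length(missing_genes) == n_total}.
#' @export
geneCoverage <- function(set, universe) {
    stopifnot(is(set, "SignedGeneSet"))
    genes <- unionGenes(set)
    present <- !is.na(matchGenes(genes, universe))
    structure(list(n_total = length(genes),
                   n_present = sum(present),
                   missing_genes = genes[!present]),
              class = "CoverageReport")
}

#' @export
print.CoverageReport <- function(x, ...) {
    cat(sprintf("CoverageReport: %d/%d genes present, %d missing\n",
                x$n_present, x$n_total, length(x$missing_genes)))
    if (length(x$missing_genes))
        cat("  missing:", paste(utils::head(x$missing_genes, 10L), collapse = ", "),
            if (length(x$missing_genes) > 10L) "..." else "", "\n")
    invisible(x)
}
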