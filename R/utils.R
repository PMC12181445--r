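# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Extract a named assay as a base or sparse matrix from SE/SCE input,
# or pass a matrix through. `what` is used in error messages.
assayMatrix <- function(x, assay = "counts", what = "input") {
    if (is(x, "SummarizedExperiment")) {
        if (!assay %in% SummarizedExperiment::assayNames(x))
            stop(sprintf("%s has no '%s' assay", what, assay))
        return(SummarizedExperiment::assay(x, assay))
    }
    if (is.matrix(x) || is(x, "Matrix")) return(x)
    stop(sprintf("%s must be a matrix or SummarizedExperiment", what))
}

# Cell-level metadata as a data.frame (empty frame for bare matrices).
cellMeta <- function(x) {
    if (is(x, "SummarizedExperiment"))
        return(as.data.frame(SummarizedExperiment::colData(x)))
    data.frame(row.names = colnames(x))
}

# Row (gene-wise) sample standard deviations of a dense matrix.
rowSds <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1L))
}

# Case-insensitive membership of `genes` in `pool`; returns indices into
# `pool` (NA where absent). Whitespace is trimmed on both sides.
matchGenes <- function(genes, pool) {
    match(toupper(trimws(genes)), toupper(trimws(pool)))
}
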