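# Independent oracles and small fixture builders used across tests. These
# deliberately avoid the package's own code paths: loops instead of cumsum,
# explicit pair scans instead of hclust.

# Brute-force running-sum enrichment score: walk the ranked list position by
# position and track the signed maximum deviation by scanning every prefix.
oracleEs <- function(metric, genes, setGenes, p = 1) {
    N <- length(metric)
    hits <- toupper(genes) %in% toupper(setGenes)
    Nh <- sum(hits)
    NR <- sum(abs(metric[hits])^p)
    run <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        cur <- if (hits[i]) {
            cur + (if (NR > 0) abs(metric[i])^p / NR else 1 / Nh)
        } else cur - 1 / (N - Nh)
        run[i] <- cur
    }
    maxP <- run[1]; minN <- run[1]
    for (i in seq_len(N)) {
        if (run[i] > maxP) maxP <- run[i]
        if (run[i] < minN) minN <- run[i]
    }
    # shared tie rule: the positive extremum wins (near-)ties
    if (maxP + minN >= -1e-9) maxP else minN
}

# Naive O(n^3) complete-linkage agglomeration on a distance matrix.
# Returns merge heights in order and the k-cluster partition. Ties break on
# the lowest-index pair, matching the documented determinism contract.
oracleCompleteLinkage <- function(d, k) {
    n <- nrow(d)
    clusters <- lapply(seq_len(n), identity)
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            dd <- max(d[clusters[[i]], clusters[[j]]])
            if (dd < bestD - 1e-12) { bestD <- dd; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
        clusters <- clusters[-best[2L]]
        if (length(clusters) == k) partition <- clusters
    }
    if (k == n) partition <- lapply(seq_len(n), identity)
    if (k == 1L) partition <- list(seq_len(n))
    assign <- integer(n)
    for (ci in seq_along(partition)) assign[partition[[ci]]] <- ci
    list(heights = heights, assignment = assign)
}

# Two clusterings agree up to label permutation?
samePartition <- function(a, b) {
    length(unique(paste(a, b))) == length(unique(a)) &&
        length(unique(a)) == length(unique(b))
}

# Random symmetric correlation-like matrix with unit diagonal via a random
# Gram matrix (guarantees entries in [-1, 1] and positive semi-definiteness).
randomCorr <- function(n, seed) {
    set.seed(seed)
    x <- matrix(rnorm(n * (n + 2L)), nrow = n)
    r <- suppressWarnings(cor(t(x)))
    dimnames(r) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
    r
}

# A small z-score container (matrix with gene names) for scoring tests.
zmat <- function(values, genes, cells = NULL) {
    m <- matrix(values, nrow = length(genes), byrow = TRUE)
    rownames(m) <- genes
    colnames(m) <- if (is.null(cells)) paste0("c", seq_len(ncol(m))) else cells
    m
}

# Compact simulation config used where defaults would be slower than the
# property under test needs.
smallConfig <- function(..., nGenes = 300L,
                        cellsPerType = c(Fibroblast = 40L, TCell = 40L),
                        nSamplesPerCondition = 3L) {
    simConfig(nGenes = nGenes, cellsPerType = cellsPerType,
              nSamplesPerCondition = nSamplesPerCondition, ...)
}
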