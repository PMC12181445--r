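# Phenotype-permutation gene set enrichment, Wilcoxon rank-sum differential
# expression and hypergeometric over-representation analysis. The GSEA
# engine pins the classic tool's defaults explicitly: signal-to-noise
# ranking with standard-deviation floors, weighted Kolmogorov-Smirnov
# running sum with weight exponent 1, sample-label (phenotype) permutation,
# sign-stratified normalization (NES) and FDR. "No collapse": gene
# identifiers are used as-is, with no probe-to-gene mapping.

#' Signal-to-noise ranking of genes between two groups
#'
#' For each gene, \code{s2n = (mean_A - mean_B) / (sd_A + sd_B)} where A is
#' the first group level, with the classic floors on each standard
#' deviation: \code{sd <- max(sd, 0.2 * |mean|)}, and 0.2 when that is still
#' zero. Genes are returned sorted by decreasing metric (ties keep input
#' order), so positive values mean higher expression in the first level.
#'
#' @param expr Genes-by-samples numeric matrix (or SummarizedExperiment with
#'   a \code{counts} assay).
#' @param groups Vector of two group labels, one per sample; order of levels
#'   follows factor levels or first appearance.
#' @return Named numeric vector of metrics, sorted non-increasing.
#' @export
rankSignalToNoise <- function(expr, groups) {
    m <- as.matrix(assayMatrix(expr, "counts", "rankSignalToNoise input"))
    g <- if (is.factor(groups)) droplevels(groups) else
        factor(groups, levels = unique(as.character(groups)))
    if (nlevels(g) != 2L) stop("exactly two groups are required")
    if (any(table(g) < 3L))
        stop("each group needs at least 3 samples for the signal-to-noise ",
             "metric; use a fold-change style metric for smaller designs")
    if (is.null(rownames(m))) stop("expression matrix must have gene names")
    a <- m[, g == levels(g)[1L], drop = FALSE]
    b <- m[, g == levels(g)[2L], drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    s2n <- (ma - mb) / (flooredSd(rowSds(a), ma) + flooredSd(rowSds(b), mb))
    s2n[order(-s2n)]
}

# GSEA's guard against vanishing denominators: each sd is floored at
# 0.2 * |mean|, and at 0.2 outright when both sd and mean are zero.
flooredSd <- function(s, mu) {
    s <- pmax(s, 0.2 * abs(mu))
    s[s == 0] <- 0.2
    s
}

# ES from a ranked walk given hit weights already in list order; shares the
# running-sum definition with enrichmentScore() but skips name matching, for
# the permutation inner loop.
esFromOrdered <- function(w, hits, p = 1) {
    N <- length(w)
    Nh <- sum(hits)
    wp <- if (p == 1) w else w^p
    NR <- sum(wp[hits])
    steps <- numeric(N)
    steps[hits] <- if (NR > 0) wp[hits] / NR else 1 / Nh
    steps[!hits] <- -1 / (N - Nh)
    run <- cumsum(steps)
    maxP <- max(run); minN <- min(run)
    if (maxP + minN >= -1e-9) maxP else minN
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating \code{|metric|^p / NR} at each set
#' gene ("hit", \code{NR} the sum over hits) and \code{-1/(N - Nh)} at each
#' non-member. The enrichment score is the running sum's signed maximum
#' deviation from zero (a tie between the positive and negative extremum
#' resolves to the positive one, for determinism); the leading edge is the
#' set genes at or before the extremum (after it, for negative scores).
#' Gene matching is case-insensitive.
#'
#' @param ranked Named numeric vector sorted non-increasing (see
#'   [rankSignalToNoise()]).
#' @param setGenes Character vector of set gene symbols (or a
#'   [SignedGeneSet-class], whose union is used).
#' @param p Weight exponent on \code{|metric|} (1 is the classic default;
#'   0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @return List with \code{es}, \code{running} (vector along the list) and
#'   \code{leadingEdge}.
#' @examples
#' r <- sort(c(A = 3, B = 2, C = 1, D = -1), decreasing = TRUE)
#' enrichmentScore(r, c("A"))$es   # 1 for the top-ranked singleton
#' @export
enrichmentScore <- function(ranked, setGenes, p = 1) {
    if (is(setGenes, "SignedGeneSet")) setGenes <- unionGenes(setGenes)
    if (is.unsorted(-ranked)) stop("'ranked' must be sorted non-increasing")
    N <- length(ranked)
    hits <- !is.na(matchGenes(names(ranked), setGenes))
    Nh <- sum(hits)
    if (Nh == 0L) stop("no set gene is present in the ranked list")
    if (Nh == N) stop("the set covers the whole ranked list; no misses to walk")
    w <- abs(ranked)^p
    NR <- sum(w[hits])
    steps <- numeric(N)
    steps[hits] <- if (NR > 0) w[hits] / NR else 1 / Nh
    steps[!hits] <- -1 / (N - Nh)
    running <- cumsum(steps)
    # signed maximum deviation; a (near-)tie between the positive and
    # negative extremum resolves to the positive one, deterministically
    maxP <- max(running); minN <- min(running)
    if (maxP + minN >= -1e-9) {
        es <- maxP
        i <- which.max(running)
        le <- names(ranked)[hits & seq_len(N) <= i]
    } else {
        es <- minN
        i <- which.min(running)
        le <- names(ranked)[hits & seq_len(N) >= i]
    }
    list(es = es, running = unname(running), leadingEdge = le)
}

#' Phenotype-permutation GSEA
#'
#' For each gene set: the observed enrichment score on the
#' signal-to-noise-ranked list, a null distribution from \code{nPerm} random
#' relabelings of the samples (phenotype permutation), the normalized
#' enrichment score \code{NES = ES / mean(|null ES| of matching sign)}, a
#' one-sided nominal p (fraction of matching-sign null scores at least as
#' extreme, with add-one correction, so p is never 0), and a sign-stratified
#' FDR q computed from the pooled normalized null as in the classic
#' procedure. Results are deterministic for a fixed seed, which is recorded
#' in the output.
#'
#' @inheritParams rankSignalToNoise
#' @param sets A [SignedGeneSet-class], a list of them (unions are used), or
#'   a named list of character vectors.
#' @param nPerm Number of label permutations (>= 10).
#' @param seed Integer seed for the permutation stream.
#' @param p Weight exponent of [enrichmentScore()].
#' @return A \link[S4Vectors]{DataFrame} with one row per set: \code{set},
#'   \code{size} (set genes present), \code{es}, \code{nes},
#'   \code{p_nominal}, \code{fdr_q}, \code{leading_edge}
#'   (\link[IRanges]{CharacterList}), \code{n_perm}, \code{seed}. \code{nes}
#'   and \code{fdr_q} are \code{NA} when no matching-sign null score exists.
#' @examples
#' se <- simulateBulk(simConfig(nGenes = 200, nSamplesPerCondition = 6,
#'                              effectDelta = 1, seed = 2))
#' gseaPhenotype(SummarizedExperiment::assay(se), se$group,
#'               builtinSenSkin(), nPerm = 50, seed = 1)
#' @export
gseaPhenotype <- function(expr, groups, sets, nPerm = 1000L, seed = 1L, p = 1) {
    if (is(sets, "SignedGeneSet")) sets <- list(sets)
    if (is.null(names(sets)))
        names(sets) <- vapply(seq_along(sets), function(i) {
            s <- sets[[i]]
            if (is(s, "SignedGeneSet")) geneSetName(s) else paste0("set", i)
        }, character(1))
    setGenes <- lapply(sets, function(s)
        if (is(s, "SignedGeneSet")) unionGenes(s) else as.character(s))
    if (nPerm < 10L) stop("'nPerm' must be at least 10")
    m <- as.matrix(assayMatrix(expr, "counts", "gseaPhenotype input"))
    g <- if (is.factor(groups)) droplevels(groups) else
        factor(groups, levels = unique(as.character(groups)))

    ranked <- rankSignalToNoise(m, g)
    obs <- lapply(setGenes, function(s) enrichmentScore(ranked, s, p = p))
    esObs <- vapply(obs, `[[`, numeric(1), "es")

    # phenotype permutation: group-A sums and sums of squares for all
    # permutations come from two matrix products, then each permutation is a
    # vectorized metric + single ranked walk
    member <- lapply(setGenes, function(s)
        !is.na(matchGenes(rownames(m), s)))
    nS <- ncol(m)
    nA <- sum(g == levels(g)[1L])
    m2 <- m^2
    totals <- rowSums(m); totSq <- rowSums(m2)
    nullEs <- withSeed(seed, {
        ind <- matrix(0, nS, nPerm)
        for (b in seq_len(nPerm)) ind[sample(nS, nA), b] <- 1
        sumsA <- m %*% ind
        sqA <- m2 %*% ind
        es <- matrix(NA_real_, length(sets), nPerm,
                     dimnames = list(names(sets), NULL))
        for (b in seq_len(nPerm)) {
            mA <- sumsA[, b] / nA
            mB <- (totals - sumsA[, b]) / (nS - nA)
            vA <- pmax(sqA[, b] - nA * mA^2, 0) / (nA - 1L)
            vB <- pmax((totSq - sqA[, b]) - (nS - nA) * mB^2, 0) / (nS - nA - 1L)
            s2n <- (mA - mB) / (flooredSd(sqrt(vA), mA) + flooredSd(sqrt(vB), mB))
            o <- order(-s2n)
            w <- abs(s2n)[o]
            for (i in seq_along(sets))
                es[i, b] <- esFromOrdered(w, member[[i]][o], p)
        }
        es
    })

    nes <- pNom <- rep(NA_real_, length(sets))
    nesNull <- matrix(NA_real_, nrow = length(sets), ncol = nPerm)
    for (i in seq_along(sets)) {
        null <- nullEs[i, ]
        es <- esObs[[i]]
        same <- if (es >= 0) null[null > 0] else null[null < 0]
        pNom[i] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        posMean <- mean(null[null > 0]); negMean <- mean(abs(null[null < 0]))
        v <- if (es >= 0) es / posMean else es / negMean
        nes[i] <- if (is.finite(v)) v else NA_real_  # no matching-sign null
        if (is.finite(posMean)) nesNull[i, null > 0] <- null[null > 0] / posMean
        if (is.finite(negMean)) nesNull[i, null < 0] <- null[null < 0] / negMean
    }
    pooled <- nesNull[!is.na(nesNull)]
    fdr <- vapply(seq_along(sets), function(i) {
        v <- nes[i]
        if (is.na(v)) return(NA_real_)
        if (v >= 0) {
            num <- if (sum(pooled >= 0)) sum(pooled >= v) / sum(pooled >= 0) else NA_real_
            den <- if (sum(nes >= 0, na.rm = TRUE))
                sum(nes >= v, na.rm = TRUE) / sum(nes >= 0, na.rm = TRUE) else NA_real_
        } else {
            num <- if (sum(pooled < 0)) sum(pooled <= v) / sum(pooled < 0) else NA_real_
            den <- if (sum(nes < 0, na.rm = TRUE))
                sum(nes <= v, na.rm = TRUE) / sum(nes < 0, na.rm = TRUE) else NA_real_
        }
        if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
        min(1, num / den)
    }, numeric(1))

    S4Vectors::DataFrame(
        set = names(sets),
        size = vapply(setGenes, function(s)
            sum(!is.na(matchGenes(names(ranked), s))), numeric(1)),
        es = esObs, nes = nes, p_nominal = pNom, fdr_q = fdr,
        leading_edge = IRanges::CharacterList(lapply(obs, `[[`, "leadingEdge")),
        n_perm = as.integer(nPerm), seed = as.integer(seed),
        row.names = names(sets))
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-group test on log-normalized expression with the cutoffs
#' used for single-cell marker detection: natural-log fold change at least
#' \code{lnfcCutoff} (default 0.25) and Bonferroni-adjusted p below
#' \code{alpha} (default 0.05). The default fold change follows the
#' shifted-mean convention for log-normalized data,
#' \code{ln(mean(expm1(x_A)) + 1) - ln(mean(expm1(x_B)) + 1)} with A the
#' first group level; \code{fcMode = "diff"} uses the plain difference of
#' mean log values instead.
#'
#' @param norm Genes-by-cells matrix of log-normalized values (or a
#'   container with a \code{logcounts} assay).
#' @param groups Two group labels per cell (first level is the test class).
#' @param lnfcCutoff Natural-log fold-change cutoff.
#' @param alpha Bonferroni-adjusted p-value cutoff.
#' @param fcMode \code{"seurat"} (shifted means of de-logged values) or
#'   \code{"diff"}.
#' @return data.frame with \code{gene}, \code{ln_fc}, \code{p},
#'   \code{p_bonferroni} (= \code{min(1, p * n_genes)}) and \code{passes}.
#' @export
wilcoxonDE <- function(norm, groups, lnfcCutoff = 0.25, alpha = 0.05,
                       fcMode = c("seurat", "diff")) {
    fcMode <- match.arg(fcMode)
    m <- as.matrix(assayMatrix(norm, "logcounts", "wilcoxonDE input"))
    g <- if (is.factor(groups)) droplevels(groups) else
        factor(groups, levels = unique(as.character(groups)))
    if (nlevels(g) != 2L || any(table(g) < 2L))
        stop("two groups with at least 2 observations each are required")
    ia <- which(g == levels(g)[1L]); ib <- which(g == levels(g)[2L])
    lnFc <- if (fcMode == "seurat")
        log(rowMeans(expm1(m[, ia, drop = FALSE])) + 1) -
        log(rowMeans(expm1(m[, ib, drop = FALSE])) + 1)
    else rowMeans(m[, ia, drop = FALSE]) - rowMeans(m[, ib, drop = FALSE])
    pv <- vapply(seq_len(nrow(m)), function(i)
        suppressWarnings(stats::wilcox.test(m[i, ia], m[i, ib])$p.value),
        numeric(1))
    pb <- stats::p.adjust(pv, method = "bonferroni")
    data.frame(gene = rownames(m), ln_fc = unname(lnFc), p = pv,
               p_bonferroni = pb,
               passes = abs(lnFc) >= lnfcCutoff & pb < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each pathway, against a gene universe, with Benjamini-Hochberg FDR
#' across pathways. Query genes outside the universe are dropped with a
#' warning; pathway genes outside the universe do not count toward pathway
#' size. Matching is case-insensitive.
#'
#' @param query Character vector of query gene symbols.
#' @param pathways Named list of character vectors (or of
#'   [SignedGeneSet-class] objects, whose unions are used).
#' @param universe Character vector of all measurable genes.
#' @param fdrAlpha FDR threshold for the \code{significant} flag.
#' @return data.frame sorted by p: \code{pathway}, \code{k_overlap},
#'   \code{K_pathway}, \code{n_query}, \code{N_universe}, \code{p},
#'   \code{fdr}, \code{significant}.
#' @examples
#' ora(query = c("A", "B"), pathways = list(P = c("A", "B", "C")),
#'     universe = LETTERS[1:20])
#' @export
ora <- function(query, pathways, universe, fdrAlpha = 0.05) {
    if (!length(universe)) stop("empty universe")
    uni <- unique(toupper(trimws(universe)))
    q <- unique(toupper(trimws(query)))
    out <- !q %in% uni
    if (any(out)) {
        warning(sprintf("%d query gene(s) outside the universe dropped", sum(out)))
        q <- q[!out]
    }
    pw <- lapply(pathways, function(s) {
        g <- if (is(s, "SignedGeneSet")) unionGenes(s) else as.character(s)
        intersect(unique(toupper(trimws(g))), uni)
    })
    if (is.null(names(pw))) names(pw) <- paste0("pathway", seq_along(pw))
    N <- length(uni); n <- length(q)
    res <- data.frame(
        pathway = names(pw),
        k_overlap = vapply(pw, function(s) length(intersect(q, s)), integer(1)),
        K_pathway = vapply(pw, length, integer(1)),
        n_query = n, N_universe = N, row.names = NULL,
        stringsAsFactors = FALSE)
    res$p <- stats::phyper(res$k_overlap - 1L, res$K_pathway,
                           N - res$K_pathway, n, lower.tail = FALSE)
    res$fdr <- stats::p.adjust(res$p, method = "BH")
    res$significant <- res$fdr < fdrAlpha
    res[order(res$p, res$pathway), , drop = FALSE]
}
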