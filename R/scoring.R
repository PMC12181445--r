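#' Composite signed-signature score per cell
#'
#' The per-cell senescence statistic: the sum of z-scores over the
#' signature's up-genes divided by the number of up-genes used, minus the sum
#' of z-scores over the down-genes divided by the number of down-genes used.
#' With the full SenSkin signature present this is
#' \code{mean(z[164 up-genes]) - z[LMNB1]}. Signature genes absent from the
#' matrix are excluded and the divisor is the number of genes actually used;
#' the exclusion counts are recorded in the result's metadata. If no
#' down-gene is present the second term is zero (with a warning).
#'
#' @param x A container with a \code{zscore} assay (see [zscoreGenes()]) or a
#'   genes-by-cells z-score matrix.
#' @param set A [SignedGeneSet-class].
#' @return A \link[S4Vectors]{DataFrame} with one row per cell: \code{score}
#'   plus any cell metadata columns carried through. Its metadata records
#'   \code{n_up_used}, \code{n_down_used} and the missing symbols.
#' @examples
#' z <- matrix(c(1, -1, 0, 2, 0, 1), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("c1", "c2")))
#' compositeScore(z, SignedGeneSet("demo", c("A", "B"), "C"))
#' @export
compositeScore <- function(x, set = builtinSenSkin()) {
    stopifnot(is(set, "SignedGeneSet"))
    z <- as.matrix(assayMatrix(x, "zscore", "compositeScore input"))
    if (is.null(rownames(z))) stop("z-score matrix must have gene row names")
    upIdx <- matchGenes(upGenes(set), rownames(z))
    dnIdx <- matchGenes(downGenes(set), rownames(z))
    missUp <- upGenes(set)[is.na(upIdx)]
    missDn <- downGenes(set)[is.na(dnIdx)]
    upIdx <- upIdx[!is.na(upIdx)]
    dnIdx <- dnIdx[!is.na(dnIdx)]
    if (length(upIdx) + length(dnIdx) == 0L)
        stop(sprintf("no gene of set '%s' is present in the matrix",
                     geneSetName(set)))
    score <- if (length(upIdx)) colMeans(z[upIdx, , drop = FALSE]) else
        rep(0, ncol(z))
    if (length(dnIdx)) {
        score <- score - colMeans(z[dnIdx, , drop = FALSE])
    } else if (length(downGenes(set))) {
        warning(sprintf("no down-gene of set '%s' present; down term is 0",
                        geneSetName(set)))
    }
    out <- S4Vectors::DataFrame(score = unname(score), cellMeta(x),
                                row.names = colnames(z))
    S4Vectors::metadata(out) <- list(set = geneSetName(set),
                                     n_up_used = length(upIdx),
                                     n_down_used = length(dnIdx),
                                     missing_up = missUp,
                                     missing_down = missDn)
    out
}

#' Per-cell-type condition contrasts of composite scores
#'
#' For each cell type, compares the composite score between the two
#' conditions with an unpaired Wilcoxon rank-sum (Mann-Whitney) test and
#' adjusts p-values across cell types (Bonferroni by default). The direction
#' is taken from the difference of medians among significant cell types. Cell
#' types with fewer than two cells in either condition are flagged
#' \code{"insufficient"} and excluded from testing and adjustment. A paired
#' signed-rank variant is available for paired designs.
#'
#' @param scores Output of [compositeScore()] (or any data.frame with a
#'   \code{score} column and the metadata keys).
#' @param conditionKey,celltypeKey Column names holding condition and cell
#'   type.
#' @param alpha Significance level applied to adjusted p-values.
#' @param adjust Multiplicity adjustment across cell types
#'   (\code{stats::p.adjust} method).
#' @param paired Use the paired signed-rank test (observations must align).
#' @return A data.frame with one row per cell type: group sizes, medians and
#'   means per condition, test statistic, \code{p_value}, \code{p_adjusted},
#'   and \code{direction} in \code{up}/\code{down}/\code{ns}/
#'   \code{insufficient}; \code{up} means the second condition is higher,
#'   where condition order follows factor levels (or order of appearance for
#'   character input).
#' @export
contrastByCellType <- function(scores, conditionKey = "condition",
                               celltypeKey = "cell_type", alpha = 0.05,
                               adjust = "bonferroni", paired = FALSE) {
    df <- as.data.frame(scores)
    for (k in c("score", conditionKey, celltypeKey))
        if (!k %in% colnames(df)) stop("missing column: ", k)
    cv <- df[[conditionKey]]
    conds <- if (is.factor(cv)) levels(droplevels(cv)) else unique(as.character(cv))
    if (length(conds) != 2L)
        stop("exactly two condition labels are required, found ",
             length(conds))
    types <- sort(unique(as.character(df[[celltypeKey]])))
    res <- lapply(types, function(t) {
        s1 <- df$score[df[[celltypeKey]] == t & df[[conditionKey]] == conds[1L]]
        s2 <- df$score[df[[celltypeKey]] == t & df[[conditionKey]] == conds[2L]]
        row <- data.frame(cell_type = t, n_1 = length(s1), n_2 = length(s2),
                          median_1 = stats::median(s1), median_2 = stats::median(s2),
                          mean_1 = mean(s1), mean_2 = mean(s2),
                          statistic = NA_real_, p_value = NA_real_,
                          p_adjusted = NA_real_, direction = "insufficient",
                          stringsAsFactors = FALSE)
        if (length(s1) >= 2L && length(s2) >= 2L) {
            wt <- suppressWarnings(stats::wilcox.test(s2, s1, paired = paired))
            row$statistic <- unname(wt$statistic)
            row$p_value <- wt$p.value
            row$direction <- "ns"
        }
        row
    })
    res <- do.call(rbind, res)
    tested <- !is.na(res$p_value)
    res$p_adjusted[tested] <- stats::p.adjust(res$p_value[tested], method = adjust)
    sig <- tested & res$p_adjusted < alpha
    res$direction[sig] <- ifelse(res$median_2[sig] >= res$median_1[sig],
                                 "up", "down")
    attr(res, "conditions") <- conds
    res
}
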