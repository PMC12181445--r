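test_that("signal-to-noise ranking matches hand-computed metrics", {
    expr <- rbind(
        flat  = c(1, 1, 1, 2, 2, 2) * 0 + 5,       # identical in both groups
        clean = c(2, 2, 2, 1, 1, 1),               # means 2 vs 1, sd 0
        noisy = c(1.5, 2.0, 2.5, 0.5, 1.0, 1.5),   # sds 0.5 both
        dn    = c(1, 1, 1, 3, 3, 3))
    colnames(expr) <- paste0("s", 1:6)
    groups <- rep(c("A", "B"), each = 3)
    r <- rankSignalToNoise(expr, groups)

    expect_equal(r[["flat"]], 0)
    # sd floored at 0.2*|mean|: (2-1)/(0.4+0.2) for the zero-variance gene
    expect_equal(r[["clean"]], 1 / 0.6)
    expect_equal(r[["noisy"]], 1.0)  # (2-1)/(0.5+0.5)
    expect_true(all(diff(unname(r)) <= 0))  # sorted non-increasing
    expect_identical(names(r)[1], "clean")

    # reversing which group is the test class negates every metric
    r2 <- rankSignalToNoise(expr, factor(groups, levels = c("B", "A")))
    expect_equal(r2[names(r)], -r, ignore_attr = TRUE)

    expect_error(rankSignalToNoise(expr[, 1:4], groups[1:4]), "3 samples")
})

test_that("enrichment score matches the running-sum definition", {
    # single top-ranked gene: full hit weight before any miss -> ES = 1
    r <- c(A = 3, B = 2, C = 1, D = -1)
    expect_equal(enrichmentScore(r, "A")$es, 1)
    expect_identical(enrichmentScore(r, "A")$leadingEdge, "A")

    # 10-gene list with a 3-gene set vs the exhaustive oracle
    set.seed(8)
    metric <- sort(rnorm(10), decreasing = TRUE)
    names(metric) <- paste0("g", 1:10)
    set <- c("g2", "g5", "g9")
    got <- enrichmentScore(metric, set)
    expect_equal(got$es, oracleEs(metric, names(metric), set))
    # running sum ends at 0 up to numerical error
    expect_equal(got$running[10], 0, tolerance = 1e-12)

    # no set gene present / set covering everything are errors
    expect_error(enrichmentScore(r, c("X", "Y")), "no set gene")
    expect_error(enrichmentScore(r, names(r)), "whole ranked list")
    expect_error(enrichmentScore(c(A = 1, B = 2), "A"), "non-increasing")

    # scale invariance of the weighted statistic
    expect_equal(enrichmentScore(metric * 7, set)$es, got$es)

    # weight p = 0 gives the unweighted KS form
    es0 <- enrichmentScore(metric, set, p = 0)$es
    expect_equal(es0, oracleEs(metric, names(metric), set, p = 0))
})

test_that("enrichment score agrees with fgsea on random instances", {
    skip_if_not_installed("fgsea")
    set.seed(99)
    for (i in 1:50) {
        N <- sample(10:50, 1)
        metric <- sort(rnorm(N), decreasing = TRUE)
        names(metric) <- paste0("g", seq_len(N))
        idx <- sort(sample(N, sample(2:min(8, N - 1), 1)))
        got <- enrichmentScore(metric, names(metric)[idx])
        # fgsea zeroes exact ties between the extrema; our rule prefers the
        # positive one, so only unambiguous instances are compared
        if (abs(max(got$running) + min(got$running)) < 1e-6) next
        ref <- fgsea::calcGseaStat(metric, selectedStats = idx, gseaParam = 1)
        expect_equal(got$es, ref, tolerance = 1e-10)
    }
})

test_that("phenotype-permutation GSEA is seeded, bounded and sign-coherent", {
    se <- simulateBulk(simConfig(nGenes = 200L, nSamplesPerCondition = 6L,
                                 effectDelta = 1, seed = 2L))
    expr <- SummarizedExperiment::assay(se)
    groups <- factor(se$group, levels = rev(unique(se$group)))
    a <- gseaPhenotype(expr, groups, builtinSenSkin(), nPerm = 10L, seed = 4L)
    b <- gseaPhenotype(expr, groups, builtinSenSkin(), nPerm = 10L, seed = 4L)
    expect_identical(as.data.frame(a[, 1:6]), as.data.frame(b[, 1:6]))

    expect_gte(a$p_nominal, 1 / 11)
    expect_equal(unname(sign(a$es)), unname(sign(a$nes)))
    expect_true(all(unlist(a$leading_edge) %in% unionGenes(builtinSenSkin())))
    expect_true(is.na(a$fdr_q) || (a$fdr_q >= 0 && a$fdr_q <= 1))
    # strong injected signal ranks the signature at the top
    expect_gt(a$es, 0)

    # label swap negates the observed ES
    swapped <- gseaPhenotype(expr, factor(groups, levels = rev(levels(groups))),
                             builtinSenSkin(), nPerm = 10L, seed = 4L)
    expect_equal(swapped$es, -a$es)

    expect_error(gseaPhenotype(expr, groups, builtinSenSkin(), nPerm = 5L),
                 "at least 10")
})

test_that("rank-sum DE applies the ln fold-change and Bonferroni rules", {
    m <- rbind(
        null = c(1, 2, 3, 1, 2, 3),
        up   = c(3, 4, 5, 0.5, 0.6, 0.7))
    colnames(m) <- paste0("c", 1:6)
    g <- rep(c("A", "B"), each = 3)
    de <- wilcoxonDE(m, g)
    expect_equal(de$ln_fc[de$gene == "null"], 0)
    expect_false(de$passes[de$gene == "null"])
    # Seurat-convention fold change for the shifted gene
    expect_equal(de$ln_fc[de$gene == "up"],
                 log(mean(expm1(c(3, 4, 5))) + 1) -
                 log(mean(expm1(c(0.5, 0.6, 0.7))) + 1))
    # {3,4,5} vs {.5,.6,.7} is the extreme labeling: exact p = 0.1
    expect_equal(de$p[de$gene == "up"], 0.1)
    expect_equal(de$p_bonferroni, pmin(1, de$p * 2))

    # Bonferroni multiplies by the number of tested genes
    m10 <- matrix(rnorm(60), nrow = 10,
                  dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
    de10 <- wilcoxonDE(m10, g)
    expect_equal(de10$p_bonferroni, pmin(1, de10$p * 10))

    # plain difference-of-log-means option
    ded <- wilcoxonDE(m, g, fcMode = "diff")
    expect_equal(ded$ln_fc[ded$gene == "up"], mean(c(3, 4, 5)) - 0.6)

    expect_error(wilcoxonDE(m, c("A", "A", "A", "A", "A", "B")), "at least 2")
})

test_that("hypergeometric ORA matches closed-form tails", {
    uni <- paste0("u", 1:20)
    # query of 5 fully inside a pathway of 5: p = 1/C(20,5)
    res <- ora(uni[1:5], list(hit = uni[1:5], empty = uni[11:14]), uni)
    expect_equal(res$p[res$pathway == "hit"], 1 / choose(20, 5))
    expect_equal(res$p[res$pathway == "hit"],
                 phyper(4, 5, 15, 5, lower.tail = FALSE))
    # zero overlap with a small pathway -> p (and fdr) near 1
    expect_gt(res$p[res$pathway == "empty"], 0.5)
    expect_identical(res$pathway[1], "hit")  # sorted by p
    expect_true(res$significant[res$pathway == "hit"])

    # degenerate: query = pathway = universe
    deg <- ora(uni, list(all = uni), uni)
    expect_equal(deg$p, 1)
    expect_identical(deg$k_overlap, 20L)

    # out-of-universe query genes are dropped with a warning
    expect_warning(res2 <- ora(c(uni[1:3], "zzz"), list(hit = uni[1:5]), uni),
                   "dropped")
    expect_identical(res2$n_query[1], 3L)

    expect_error(ora("a", list(p = "a"), character(0)), "empty universe")
})
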