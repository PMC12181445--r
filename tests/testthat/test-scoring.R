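test_that("composite score equals the signed mean-of-z formula", {
    set <- SignedGeneSet("toy", c("A", "B", "C"), "D")

    # null z-matrix scores 0 everywhere
    z0 <- zmat(rep(0, 10), c("A", "B", "C", "D", "E"))
    expect_true(all(compositeScore(z0, set)$score == 0))

    # constant columns: up-genes at a, down-gene at b -> a - b
    a <- 0.8; b <- -0.3
    zc <- zmat(c(a, a, a, a, a, a, b, b, 5, 5),
               c("A", "B", "C", "D", "E"))
    expect_equal(compositeScore(zc, set)$score, rep(a - b, 2))

    # 3-cell, 5-gene toy against hand-computed sums
    z <- zmat(c(1.0, -0.5, 2.0,
                0.0, 1.5, -1.0,
                -1.0, 0.5, 0.0,
                2.0, -2.0, 1.0,
                9.0, 9.0, 9.0),
              c("A", "B", "C", "D", "E"))
    got <- compositeScore(z, set)$score
    expect_equal(got[1], (1.0 + 0.0 - 1.0) / 3 - 2.0 / 1)
    expect_equal(got[2], (-0.5 + 1.5 + 0.5) / 3 - (-2.0))
    expect_equal(got[3], (2.0 - 1.0 + 0.0) / 3 - 1.0)

    md <- S4Vectors::metadata(compositeScore(z, set))
    expect_identical(md$n_up_used, 3L)
    expect_identical(md$n_down_used, 1L)
})

test_that("score ignores genes outside the set and any gene order", {
    set <- SignedGeneSet("toy", c("A", "B"), "D")
    set.seed(1)
    z <- zmat(rnorm(25), c("A", "B", "D", "X", "Y"))
    base <- compositeScore(z, set)$score
    # permute rows
    perm <- z[sample(nrow(z)), , drop = FALSE]
    expect_equal(compositeScore(perm, set)$score, base)
    # change values of out-of-set genes
    z2 <- z
    z2[c("X", "Y"), ] <- 99
    expect_equal(compositeScore(z2, set)$score, base)
    # permuting cells permutes scores identically
    cp <- sample(ncol(z))
    expect_equal(compositeScore(z[, cp], set)$score, base[cp])
    # doubling all set-gene z-values doubles the score
    z3 <- z
    z3[c("A", "B", "D"), ] <- 2 * z3[c("A", "B", "D"), ]
    expect_equal(compositeScore(z3, set)$score, 2 * base)
})

test_that("missing genes shrink the divisor and missing strata warn or fail", {
    set <- SignedGeneSet("toy", c("A", "B", "C"), "D")
    z <- zmat(c(1, 1, 3, 3), c("A", "B"))  # C and D absent
    expect_warning(sc <- compositeScore(z, set), "down")
    expect_equal(sc$score, c(2, 2))  # mean over the 2 present up-genes
    md <- S4Vectors::metadata(suppressWarnings(compositeScore(z, set)))
    expect_identical(md$n_up_used, 2L)
    expect_identical(md$n_down_used, 0L)
    expect_identical(md$missing_up, "C")

    none <- zmat(c(1, 1), c("Q"))
    expect_error(compositeScore(none, set), "no gene")
})

test_that("per-cell-type contrasts behave under null and shifted data", {
    # identical distributions -> large p, ns
    df <- data.frame(score = rep(c(1, 2, 3, 4, 5), 2),
                     condition = rep(c("ctl", "trt"), each = 5),
                     cell_type = "A")
    res <- contrastByCellType(df)
    expect_identical(res$direction, "ns")
    expect_gt(res$p_value, 0.9)

    # {1,2,3} vs {4,5,6}: exact two-sided rank-sum p = 0.1
    df2 <- data.frame(score = c(1, 2, 3, 4, 5, 6),
                      condition = rep(c("ctl", "trt"), each = 3),
                      cell_type = "A")
    expect_equal(contrastByCellType(df2)$p_value, 0.1)

    # insufficient cells are flagged, not tested
    df3 <- rbind(df2, data.frame(score = 1, condition = "ctl", cell_type = "B"))
    res3 <- contrastByCellType(df3)
    expect_identical(res3$direction[res3$cell_type == "B"], "insufficient")
    expect_true(is.na(res3$p_value[res3$cell_type == "B"]))
    # the flagged type is excluded from the Bonferroni family
    expect_equal(res3$p_adjusted[res3$cell_type == "A"], 0.1)

    expect_error(contrastByCellType(df[0, ]), "two condition")
})

test_that("contrasts recover an effect injected into one cell type", {
    cfg <- smallConfig(nGenes = 250L,
                       cellsPerType = c(Fibroblast = 50L, TCell = 50L),
                       effectDelta = 1, downDelta = 1,
                       affectedFraction = c(Fibroblast = 1), seed = 21L)
    sc <- compositeScore(zscoreGenes(logNormalize(simulateCells(cfg))))
    res <- contrastByCellType(sc)
    expect_identical(res$direction[res$cell_type == "Fibroblast"], "up")
    expect_identical(res$direction[res$cell_type == "TCell"], "ns")
})
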