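test_that("skewness matches hand computation and its symmetries", {
    expect_equal(geneSkewness(c(-1, 0, 1)), 0)

    # (0,0,0,10): m2 = 18.75, m3 = 93.75; G1 = g1 * sqrt(n(n-1))/(n-2)
    x <- c(0, 0, 0, 10)
    m2 <- mean((x - mean(x))^2)
    m3 <- mean((x - mean(x))^3)
    g1 <- m3 / m2^1.5
    expect_equal(geneSkewness(x, "g1"), g1)
    expect_equal(geneSkewness(x, "adjusted"), g1 * sqrt(4 * 3) / 2)
    expect_gt(geneSkewness(x), 0)

    # antisymmetry
    set.seed(2)
    y <- rexp(30)
    expect_equal(geneSkewness(-y), -geneSkewness(y))

    expect_warning(expect_equal(geneSkewness(c(1, 1, 1)), 0), "zero variance")
    expect_warning(expect_equal(geneSkewness(c(1, 2)), 0), "length")
})

test_that("gated log transform triggers on any skewed gene in global mode", {
    sym <- matrix(rep(c(1, 2, 3, 4, 5), 3), nrow = 3, byrow = TRUE,
                  dimnames = list(paste0("g", 1:3), NULL))
    out <- gatedLogTransform(sym)
    expect_equal(unclass(out), unclass(sym), ignore_attr = TRUE)
    expect_length(attr(out, "triggered"), 0L)
    expect_false(attr(out, "transformed"))

    skewed <- rbind(sym, g4 = c(0, 0, 0, 0, 50))
    out2 <- gatedLogTransform(skewed)
    expect_identical(attr(out2, "triggered"), "g4")
    expect_equal(unclass(out2), log1p(skewed), ignore_attr = TRUE)  # whole matrix

    pg <- gatedLogTransform(skewed, mode = "per_gene")
    expect_equal(pg["g1", ], sym["g1", ], ignore_attr = TRUE)
    expect_equal(pg["g4", ], log1p(skewed["g4", ]), ignore_attr = TRUE)

    # trigger list matches brute-force per-gene skewness
    set.seed(5)
    m <- matrix(rexp(60)^2, nrow = 10,
                dimnames = list(paste0("g", 1:10), NULL))
    manual <- rownames(m)[apply(m, 1, function(x) {
        mu <- mean(x); n <- length(x)
        g1 <- mean((x - mu)^3) / mean((x - mu)^2)^1.5
        g1 * sqrt(n * (n - 1)) / (n - 2) > 2
    })]
    expect_identical(attr(gatedLogTransform(m), "triggered"), manual)

    expect_error(gatedLogTransform(matrix(-1)), "nonnegative")
})

test_that("inter-gene correlations match brute-force arithmetic", {
    m <- matrix(c(1, 2, 3, 4,
                  -1, -2, -3, -4,
                  2, 1, 4, 3), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
    r <- geneCorrelation(m)
    expect_equal(r["a", "a"], 1)
    expect_equal(r["a", "b"], -1)  # exact negation
    # 4-group toy: covariance / sds by hand
    cov_ac <- mean((m["a", ] - mean(m["a", ])) * (m["c", ] - mean(m["c", ])))
    expect_equal(r["a", "c"],
                 cov_ac / (sd(m["a", ]) * sd(m["c", ]) * 3 / 4))
    expect_equal(r, t(r))

    # zero-variance gene flagged, correlates 0 off-diagonal
    m2 <- rbind(m, d = c(5, 5, 5, 5))
    r2 <- geneCorrelation(m2)
    expect_identical(attr(r2, "flagged"), "d")
    expect_equal(unname(r2["d", c("a", "b", "c")]), c(0, 0, 0))
    expect_equal(r2["d", "d"], 1)

    expect_error(geneCorrelation(m[, 1:2]), "3")
    expect_error(geneCorrelation(m, genes = "zz"), "not found")
})

test_that("complete linkage recovers planted blocks and degenerate cuts", {
    # two blocks: within r = 0.9, across r = 0
    r <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
    blocks <- list(1:3, 4:6)
    for (b in blocks) r[b, b] <- 0.9
    diag(r) <- 1
    cl <- completeLinkage(r, k = 2)
    truth <- rep(1:2, each = 3)
    expect_true(samePartition(clusterAssignments(cl), truth))
    # merge heights match the naive oracle (sorted; ties permute merge order)
    oracle <- oracleCompleteLinkage(1 - r, k = 2)
    expect_equal(sort(cl@hclust$height), sort(oracle$heights))
    expect_true(samePartition(clusterAssignments(cl), oracle$assignment))

    # k = n -> singletons; k = 1 -> one cluster
    expect_length(unique(clusterAssignments(completeLinkage(r, k = 6))), 6L)
    expect_identical(unique(unname(clusterAssignments(completeLinkage(r, k = 1)))), 1L)
    expect_error(completeLinkage(r, k = 0), "between")
    expect_error(completeLinkage(r, k = 7), "between")
})

test_that("merge heights are monotone and labels are order-invariant", {
    r <- randomCorr(12, seed = 31)
    cl <- completeLinkage(r, k = 4)
    expect_true(all(diff(cl@hclust$height) >= -1e-12))
    # clusters contiguous in dendrogram order (validity enforces; spot-check)
    along <- clusterAssignments(cl)[dendrogramOrder(cl)]
    expect_identical(unique(along), 1:4)

    # permuting input genes permutes the partition with them
    perm <- sample(12)
    rp <- r[perm, perm]
    clp <- completeLinkage(rp, k = 4)
    expect_true(samePartition(clusterAssignments(clp),
                              clusterAssignments(cl)[perm]))
})

test_that("agglomeration agrees with the naive oracle on random matrices", {
    for (seed in 1:30) {
        n <- 3L + (seed %% 6L)
        r <- randomCorr(n, seed = 1000 + seed)
        k <- 1L + (seed %% n)
        cl <- completeLinkage(r, k = k)
        oracle <- oracleCompleteLinkage(1 - r, k = k)
        expect_equal(sort(cl@hclust$height), sort(oracle$heights),
                     tolerance = 1e-10)
        expect_true(samePartition(clusterAssignments(cl), oracle$assignment))
    }
})
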