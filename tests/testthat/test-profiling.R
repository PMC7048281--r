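test_that("species distribution percentages are exact and partition to 100", {
    m <- rbind(s1 = c(NO_ADAPTOR = 2L, SHORT = 1L, TRNA = 2L, MAPPED = 4L,
                      UNMAPPED = 1L))
    d <- speciesDistribution(m)
    expect_equal(unname(d$percent["s1", c("NO_ADAPTOR", "SHORT", "TRNA",
                                          "MAPPED", "UNMAPPED")]),
                 c(20, 10, 20, 40, 10))
    expect_equal(sum(d$percent["s1", ]), 100)

    # all reads mapped -> 100% in the miRNA/isomiR class
    d2 <- speciesDistribution(rbind(s = c(MAPPED = 7L)))
    expect_equal(unname(d2$percent[1, "MAPPED"]), 100)

    # empty sample: flagged, all-zero row, excluded from group means
    m3 <- rbind(a = c(MAPPED = 8L, SHORT = 2L),
                b = c(MAPPED = 0L, SHORT = 0L),
                c = c(MAPPED = 2L, SHORT = 2L))
    d3 <- speciesDistribution(m3, groups = c("g1", "g1", "g1"))
    expect_true(d3$empty["b"])
    expect_equal(unname(d3$groupMeans["g1", "MAPPED"]), (80 + 50) / 2)
    expect_equal(unname(rowSums(d3$percent)), c(100, 0, 100))

    expect_error(speciesDistribution(rbind(s = c(WEIRD = 1L))),
                 "unknown read class")
})

test_that("PCA is deterministic, ranked by variance, and separates planted groups", {
    set.seed(41)
    base <- matrix(rnbinom(200 * 8, mu = 50, size = 5), nrow = 200,
                   dimnames = list(sprintf("f%03d", 1:200),
                                   sprintf("s%d", 1:8)))
    # two groups with disjoint high-abundance feature blocks
    base[1:20, 1:4] <- base[1:20, 1:4] + 2000
    base[21:40, 5:8] <- base[21:40, 5:8] + 2000
    pca <- pcaProfile(base, sizeFactors = rep(1, 8), k = 100)
    expect_equal(nrow(pca$coordinates), 8)
    # explained variances non-increasing, sum to 100
    expect_true(all(diff(pca$explainedVariance) <= 1e-9))
    expect_equal(sum(pca$explainedVariance), 100)
    # group separation on PC1: silhouette-like criterion > 0
    pc1 <- pca$coordinates[, 1]
    g <- rep(c(1, 2), each = 4)
    within <- mean(c(dist(pc1[g == 1]), dist(pc1[g == 2])))
    between <- mean(abs(outer(pc1[g == 1], pc1[g == 2], "-")))
    expect_gt(between, within)
    # top-variance selection picks the planted blocks first
    expect_true(all(sprintf("f%03d", 1:40) %in% pca$features[1:60]))

    # duplicated sample -> identical coordinates on all components
    dup <- cbind(base, s9 = base[, 1])
    p2 <- pcaProfile(dup, sizeFactors = rep(1, 9), k = 100)
    expect_equal(unname(p2$coordinates["s1", ]), unname(p2$coordinates["s9", ]),
                 tolerance = 1e-9)

    # k above the feature count uses all features without error
    p3 <- pcaProfile(base[1:30, ], sizeFactors = rep(1, 8), k = 500)
    expect_length(p3$features, 30)
    expect_error(pcaProfile(base[, 1, drop = FALSE], rep(1, 1)), "2 samples")
})

test_that("Ward clustering has closed-form behavior on tiny inputs and recovers planted groups", {
    # 2 samples: one merge at their euclidean distance
    m <- cbind(a = c(0, 0, 0), b = c(16, 0, 0))
    hc <- clusterSamples(m, sizeFactors = c(1, 1))
    tr <- log2(m + 1)
    expect_equal(length(hc$height), 1L)
    expect_equal(hc$height, sqrt(sum((tr[, 1] - tr[, 2])^2)))
    expect_equal(hc$method, "ward.D2")

    # duplicated sample pair merges first at height 0
    set.seed(13)
    mm <- matrix(rnbinom(50 * 4, mu = 100, size = 10), nrow = 50)
    colnames(mm) <- c("x", "y", "z", "x2")
    mm[, "x2"] <- mm[, "x"]
    hc2 <- clusterSamples(mm, sizeFactors = rep(1, 4))
    expect_equal(hc2$height[1], 0)
    first <- sort(colnames(mm)[-hc2$merge[1, ]])
    expect_equal(first, c("x", "x2"))

    # planted two-group design: cutting at 2 recovers the partition
    big <- matrix(rnbinom(300 * 6, mu = 30, size = 5), nrow = 300)
    colnames(big) <- sprintf("s%d", 1:6)
    big[1:50, 1:3] <- big[1:50, 1:3] + 3000
    big[51:100, 4:6] <- big[51:100, 4:6] + 3000
    hc3 <- clusterSamples(big, sizeFactors = rep(1, 6))
    cut <- cutree(hc3, k = 2)
    expect_equal(length(unique(cut[1:3])), 1L)
    expect_equal(length(unique(cut[4:6])), 1L)
    expect_true(cut[1] != cut[4])
})

test_that("abundance overlap counts and percentages follow the contract", {
    m <- rbind(a = c(100, 110), b = c(90, 95), c = c(80, 70),
               d = c(5, 6), e = c(1, 2))
    colnames(m) <- c("r1", "r2")
    ov <- abundanceOverlap(m, list(`1h` = c("b", "c", "d")), nTop = 3,
                           sizeFactors = c(1, 1))
    expect_equal(ov$overlaps$overlap_count, 2L)
    expect_equal(ov$overlaps$overlap_percent, 100 * 2 / 3, tolerance = 1e-9)
    expect_equal(ov$topFeatures, c("a", "b", "c"))

    # empty up-set -> overlap 0, 0%
    ov0 <- abundanceOverlap(m, list(`3h` = character(0)), nTop = 3,
                            sizeFactors = c(1, 1))
    expect_equal(ov0$overlaps$overlap_count, 0L)
    expect_equal(ov0$overlaps$overlap_percent, 0)

    # invariant to sample order and common count scaling
    ov1 <- abundanceOverlap(m[, c(2, 1)], list(`1h` = c("b", "c", "d")),
                            nTop = 3, sizeFactors = c(1, 1))
    ov2 <- abundanceOverlap(m * 10, list(`1h` = c("b", "c", "d")),
                            nTop = 3, sizeFactors = c(1, 1))
    expect_equal(ov1$overlaps$overlap_count, ov$overlaps$overlap_count)
    expect_equal(ov2$overlaps$overlap_count, ov$overlaps$overlap_count)
    expect_equal(ov2$topReadFraction, ov$topReadFraction)

    # nTop above the feature count: capped with a warning
    expect_warning(ovAll <- abundanceOverlap(m, list(x = c("a")), nTop = 10,
                                             sizeFactors = c(1, 1)),
                   "exceeds")
    expect_equal(ovAll$overlaps$n_top, 5L)
    # the cumulative read share of the full set is 100%
    expect_equal(ovAll$topReadFraction, 100)

    # ranking ties break by feature id
    tie <- rbind(z = c(10, 10), y = c(10, 10), x = c(10, 10))
    colnames(tie) <- c("r1", "r2")
    ovT <- abundanceOverlap(tie, list(t = "x"), nTop = 2,
                            sizeFactors = c(1, 1))
    expect_equal(ovT$topFeatures, c("x", "y"))
})
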