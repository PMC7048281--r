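test_that("median-of-ratios size factors match the closed form", {
    m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    sf <- medianOfRatios(m)
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

    # k identical samples -> all factors 1
    mm <- matrix(rep(c(5, 50, 500), 4), ncol = 4)
    expect_equal(unname(medianOfRatios(mm)), rep(1, 4))

    # single sample -> 1 by convention
    expect_equal(unname(medianOfRatios(matrix(c(1, 2, 3), ncol = 1))), 1)

    # equivariance: scaling one sample's counts by c multiplies its factor
    # by c relative to the others (the geometric-mean reference absorbs a
    # common c^(1/n))
    set.seed(5)
    base <- matrix(rnbinom(300, mu = 100, size = 5) + 1, ncol = 3)
    sf1 <- medianOfRatios(base)
    scaled <- base
    scaled[, 2] <- scaled[, 2] * 4
    sf2 <- medianOfRatios(scaled)
    expect_equal((sf2[2] / sf2[1]) / (sf1[2] / sf1[1]), 4, tolerance = 1e-9)
    expect_equal(sf2[3] / sf2[1], sf1[3] / sf1[1], tolerance = 1e-9)

    # no feature expressed everywhere -> error, pseudo-reference fallback works
    sp <- rbind(c(10, 0), c(0, 10))
    expect_error(medianOfRatios(sp), "pseudoReference")
    expect_silent(medianOfRatios(sp, pseudoReference = TRUE))
})

test_that("size factors agree with an independent median-of-ratios implementation", {
    set.seed(19)
    # odd feature count: the median is a single element, so averaging
    # ratios (here) versus log-ratios (reference) cannot differ
    m <- matrix(rnbinom(501 * 6, mu = 200, size = 5) + 1, ncol = 6)
    expect_equal(unname(medianOfRatios(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
})

test_that("the adjusted p-values follow the textbook BH step-up", {
    # hand-computed example: sorted q = (.005, .02, .065, .05125, .042)
    # before monotonization, so the step-up gives (.005, .02, .042, .042,
    # .042) in sorted order
    p <- c(0.042, 0.001, 0.031, 0.039, 0.008)
    expect_equal(oracleBH(p), c(0.042, 0.005, 0.042, 0.042, 0.02))

    # the module's adjustment over tested features (all-zero features are
    # excluded from the family) reproduces the step-up oracle
    set.seed(77)
    m <- simulateNbMatrix(30, mu = 200, dispersion = 0.05)
    m[7, ] <- 0
    res <- nbDifferential(m, rep(c("A", "B"), each = 3),
                          sizeFactors = rep(1, 6))
    tested <- !is.na(res$pvalue)
    expect_equal(sum(!tested), 1L)
    expect_equal(res$padj[tested], oracleBH(res$pvalue[tested]))
    # BH monotonicity after sorting
    expect_true(all(diff(sort(res$padj[tested])) >= -1e-12))
})

test_that("degenerate features behave per contract", {
    same <- matrix(rep(c(100, 120, 90), 2), nrow = 1)
    zero <- matrix(0, nrow = 1, ncol = 6)
    m <- rbind(f1 = same, f0 = zero)
    res <- nbDifferential(m, rep(c("A", "B"), each = 3),
                          sizeFactors = rep(1, 6))
    expect_equal(res$log2FC[1], 0, tolerance = 1e-8)
    expect_equal(res$pvalue[1], 1, tolerance = 1e-6)
    expect_true(is.na(res$pvalue[2]) && is.na(res$padj[2]))
    expect_equal(res$baseMean[2], 0)
    expect_error(nbDifferential(m, c("A", "B", "C", "A", "B", "C")),
                 "two levels")
})

test_that("significance filter applies inclusive thresholds and splits by direction", {
    rec <- data.frame(
        feature_id = c("a", "b", "c", "d", "e"),
        baseMean = c(60, 500, 50, 40, 80),
        log2FC = c(1.2, 0.9, 1.0, 2.0, -1.5),
        pvalue = c(0.01, 0.01, 0.02, 0.001, 0.01),
        padj = c(0.04, 0.04, 0.05, 0.04, 0.03))
    fl <- filterSignificant(rec)
    # (0.04, 1.2, 60) significant up; (0.04, 0.9, 500) fails the lfc bound;
    # (0.05, 1.0, 50) significant: all thresholds inclusive;
    # (0.04, 2.0, 40) fails abundance; (0.03, -1.5, 80) significant down
    expect_equal(fl$up$feature_id, c("a", "c"))
    expect_equal(fl$down$feature_id, "e")
    expect_equal(fl$all$significant, c(TRUE, FALSE, TRUE, FALSE, TRUE))
    # missing padj is never significant
    rec$padj[1] <- NA
    expect_false(filterSignificant(rec)$all$significant[1])
})

test_that("null simulation stays under the false-call budget", {
    set.seed(101)
    n <- 1200
    mu <- exp(runif(n, log(5), log(2000)))
    m <- simulateNbMatrix(n, mu = mu, dispersion = 0.1)
    res <- nbDifferential(m, rep(c("A", "B"), each = 3))
    fl <- filterSignificant(res)
    expect_lte(mean(fl$all$significant), 0.01)
})

test_that("planted effects are recovered with calibrated magnitude", {
    set.seed(202)
    n <- 150
    m <- simulateNbMatrix(n, mu = 500, dispersion = 0.05,
                          lfc = rep(2, n))
    res <- nbDifferential(m, rep(c("A", "B"), each = 3),
                          sizeFactors = rep(1, 6))
    fl <- filterSignificant(res)
    expect_gte(mean(fl$all$significant), 0.8)
    expect_gt(median(res$log2FC, na.rm = TRUE), 1.7)
    expect_lt(median(res$log2FC, na.rm = TRUE), 2.3)
})

test_that("contrast manifest covers group and time comparisons", {
    set.seed(303)
    counts <- matrix(rnbinom(40 * 12, mu = 100, size = 10), nrow = 40,
                     dimnames = list(sprintf("f%02d", 1:40), NULL))
    sheet <- expand.grid(replicate = 1:3, time_point = c("0h", "1h"),
                         group = c("gA", "gB"), stringsAsFactors = FALSE)
    sheet$sample_id <- sprintf("%s_%s_r%d", sheet$group, sheet$time_point,
                               sheet$replicate)
    colnames(counts) <- sheet$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
    de <- runContrasts(se)
    expect_setequal(names(de),
        c("gB_vs_gA", "gA_1h_vs_0h", "gB_1h_vs_0h"))
    expect_equal(de$gA_1h_vs_0h$comparison$reference, "0h")
    expect_equal(de$gB_vs_gA$comparison$n_test, 6)
})
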