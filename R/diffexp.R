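#' Median-of-ratios size factors
#'
#' Per-sample scaling factor = median over features (restricted to features
#' with a positive geometric mean across samples, i.e. expressed in every
#' sample) of the ratio of the sample's count to the feature's geometric
#' mean.  A single sample gets factor 1 by convention.
#'
#' @param counts non-negative count matrix (features x samples) or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay.
#' @param pseudoReference if \code{TRUE}, the geometric mean of each feature
#'   is computed over its positive counts only (fallback for sparse
#'   matrices where no feature is expressed in all samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' medianOfRatios(m)  # 1/sqrt(2), sqrt(2)
#' @export
medianOfRatios <- function(counts, pseudoReference = FALSE) {
    if (methods::is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    if (ncol(counts) == 1L) {
        sf <- 1
        names(sf) <- colnames(counts)
        return(sf)
    }
    if (pseudoReference) {
        logGeo <- apply(counts, 1, function(x) {
            pos <- x > 0
            if (!any(pos)) -Inf else mean(log(x[pos]))
        })
    } else {
        logGeo <- rowMeans(log(counts))
    }
    use <- is.finite(logGeo)
    if (!any(use))
        stop("no feature is expressed in every sample; rerun with ",
             "pseudoReference = TRUE to use a positive-count reference",
             call. = FALSE)
    sf <- apply(counts[use, , drop = FALSE], 2, function(x) {
        r <- x / exp(logGeo[use])
        # with a positive-count reference most features are absent from any
        # given sample; the median is then taken over the sample's expressed
        # features (poscounts-style), keeping the factor positive
        if (pseudoReference) stats::median(r[x > 0]) else stats::median(r)
    })
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor estimated; the count matrix is too ",
             "sparse (try pseudoReference = TRUE)", call. = FALSE)
    sf
}

#' Normalize counts by size factors
#'
#' @param counts count matrix or \code{SummarizedExperiment}.
#' @param sizeFactors optional precomputed factors (default:
#'   \code{\link{medianOfRatios}}).
#' @return matrix of normalized counts (count / size factor).
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
    if (methods::is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
    sweep(counts, 2, sizeFactors, "/")
}

#' Negative-binomial differential expression (two groups)
#'
#' A simplified NB-Wald procedure in the spirit of count-based RNA-seq
#' testing: median-of-ratios normalization, per-feature method-of-moments
#' dispersion on normalized counts (floored), an NB log-linear model with
#' size-factor offsets fitted per feature, a two-sided Wald test on the
#' group coefficient, and Benjamini-Hochberg adjustment over all tested
#' features.  It deliberately does not replicate shrinkage-based tools'
#' internals (no Cox-Reid dispersion, no fold-change shrinkage, no
#' independent filtering); its operating characteristics are validated by
#' simulation instead.
#'
#' \code{log2FC} is the fitted coefficient for the second group level
#' relative to the first, in log2 units.  Features with all-zero counts are
#' excluded from testing and reported with missing p-values.  For display, a
#' descriptive fold change with pseudo-count 0.5 on normalized group means
#' is also reported (\code{log2FC_desc}); the fitted model itself uses no
#' pseudo-count.
#'
#' @param counts count matrix (features x samples) or
#'   \code{SummarizedExperiment}.
#' @param groups two-level factor (or coercible) over the samples; the first
#'   level is the reference.
#' @param sizeFactors optional; default \code{\link{medianOfRatios}} on the
#'   matrix at hand.
#' @param dispersionFloor lower bound for the method-of-moments dispersion
#'   estimate (default 1e-8, effectively Poisson when counts are
#'   underdispersed).
#' @return \code{data.frame}: \code{feature_id}, \code{baseMean} (mean of
#'   normalized counts over the samples in the comparison), \code{log2FC},
#'   \code{lfcSE}, \code{stat}, \code{pvalue}, \code{padj},
#'   \code{log2FC_desc}, \code{dispersion}.
#' @export
nbDifferential <- function(counts, groups, sizeFactors = NULL,
                           dispersionFloor = 1e-8) {
    if (methods::is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("'groups' must have exactly two levels", call. = FALSE)
    if (length(groups) != ncol(counts))
        stop("'groups' length must equal the number of samples", call. = FALSE)
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
    norm <- sweep(counts, 2, sizeFactors, "/")
    gA <- groups == levels(groups)[1]
    gB <- !gA

    baseMean <- rowMeans(norm)
    mA <- rowMeans(norm[, gA, drop = FALSE])
    mB <- rowMeans(norm[, gB, drop = FALSE])
    lfcDesc <- log2((mB + 0.5) / (mA + 0.5))

    # method-of-moments dispersion: pooled within-group variance of
    # normalized counts against the overall normalized mean
    dfA <- max(sum(gA) - 1L, 0L); dfB <- max(sum(gB) - 1L, 0L)
    vA <- if (dfA > 0) apply(norm[, gA, drop = FALSE], 1, stats::var) else 0
    vB <- if (dfB > 0) apply(norm[, gB, drop = FALSE], 1, stats::var) else 0
    pooledVar <- if (dfA + dfB > 0) (dfA * vA + dfB * vB) / (dfA + dfB) else
        rep(NA_real_, nrow(counts))
    disp <- pmax((pooledVar - baseMean) / baseMean^2, dispersionFloor)
    disp[!is.finite(disp)] <- dispersionFloor

    testable <- baseMean > 0 & sum(gA) >= 2L & sum(gB) >= 2L
    n <- nrow(counts)
    log2FC <- lfcSE <- stat <- pvalue <- rep(NA_real_, n)
    off <- log(sizeFactors)
    ln2 <- log(2)
    for (i in which(testable)) {
        fit <- tryCatch(
            suppressWarnings(stats::glm(
                counts[i, ] ~ groups + offset(off),
                family = MASS::negative.binomial(theta = 1 / disp[i]))),
            error = function(e) NULL)
        if (is.null(fit) || !fit$converged && anyNA(stats::coef(fit))) next
        co <- tryCatch(
            suppressWarnings(stats::summary.glm(fit, dispersion = 1)$coefficients),
            error = function(e) NULL)
        if (is.null(co) || nrow(co) < 2L) next
        log2FC[i] <- co[2, 1] / ln2
        lfcSE[i] <- co[2, 2] / ln2
        stat[i] <- co[2, 1] / co[2, 2]
        pvalue[i] <- 2 * stats::pnorm(-abs(stat[i]))
    }
    padj <- rep(NA_real_, n)
    tested <- !is.na(pvalue)
    padj[tested] <- stats::p.adjust(pvalue[tested], method = "BH")
    fid <- rownames(counts)
    if (is.null(fid)) fid <- as.character(seq_len(n))
    data.frame(feature_id = fid, baseMean = baseMean, log2FC = log2FC,
               lfcSE = lfcSE, stat = stat, pvalue = pvalue, padj = padj,
               log2FC_desc = lfcDesc, dispersion = disp,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Significance thresholds
#'
#' All thresholds are inclusive: a feature is significant iff
#' \code{padj <= alpha} and \code{|log2FC| >= minAbsLfc} and
#' \code{baseMean >= minBaseMean}.
#'
#' @param alpha adjusted p-value cutoff (default 0.05).
#' @param minAbsLfc minimum absolute log2 fold change (default 1).
#' @param minBaseMean minimum mean normalized abundance (default 50).
#' @return a validated threshold list.
#' @export
significanceThresholds <- function(alpha = 0.05, minAbsLfc = 1,
                                   minBaseMean = 50) {
    stopifnot(alpha > 0, alpha <= 1, minAbsLfc >= 0, minBaseMean >= 0)
    list(alpha = alpha, minAbsLfc = minAbsLfc, minBaseMean = minBaseMean)
}

#' Filter differential-expression records for significance
#'
#' Applies the conservative filter (adjusted p, absolute log2 fold change,
#' minimal abundance; all inclusive) and splits the survivors by direction.
#' Records with missing \code{padj} are never significant.
#'
#' @param records \code{data.frame} from \code{\link{nbDifferential}}.
#' @param thresholds a \code{\link{significanceThresholds}} list.
#' @return list with \code{all} (the input with added \code{significant} and
#'   \code{direction} columns), \code{up} and \code{down} (significant
#'   subsets with positive / negative log2 fold change).
#' @export
filterSignificant <- function(records, thresholds = significanceThresholds()) {
    sig <- !is.na(records$padj) & !is.na(records$log2FC) &
        records$padj <= thresholds$alpha &
        abs(records$log2FC) >= thresholds$minAbsLfc &
        records$baseMean >= thresholds$minBaseMean
    direction <- ifelse(!sig, NA_character_,
                        ifelse(records$log2FC > 0, "up", "down"))
    out <- records
    out$significant <- sig
    out$direction <- direction
    list(all = out,
         up = out[sig & direction == "up", , drop = FALSE],
         down = out[sig & direction == "down", , drop = FALSE])
}

#' Run the study's standard contrasts
#'
#' Builds the comparison manifest over a sample sheet with \code{group} and
#' \code{time_point} columns: every pair of groups (all samples), and within
#' each group every later time point against the earliest (pre-feeding
#' baseline).  Time points are ordered by their leading number ("0h" before
#' "1h" before "12h").
#'
#' @param se \code{SummarizedExperiment} with \code{group} and
#'   \code{time_point} in \code{colData}.
#' @param thresholds a \code{\link{significanceThresholds}} list.
#' @param minReplicates comparisons where either side has fewer samples are
#'   skipped (default 2).
#' @return named list of results; each element carries the
#'   \code{\link{filterSignificant}} output plus \code{comparison} metadata.
#' @export
runContrasts <- function(se, thresholds = significanceThresholds(),
                         minReplicates = 2L) {
    cd <- SummarizedExperiment::colData(se)
    stopifnot(all(c("group", "time_point") %in% colnames(cd)))
    counts <- SummarizedExperiment::assay(se, "counts")
    group <- as.character(cd$group)
    tp <- as.character(cd$time_point)
    tpLevels <- unique(tp)[order(as.numeric(sub("^([0-9.]+).*$", "\\1",
                                                unique(tp))))]
    out <- list()
    runOne <- function(cols, labels, name, a, b) {
        if (sum(labels == a) < minReplicates || sum(labels == b) < minReplicates)
            return(NULL)
        res <- nbDifferential(counts[, cols, drop = FALSE],
                              factor(labels, levels = c(a, b)))
        flt <- filterSignificant(res, thresholds)
        flt$comparison <- list(name = name, reference = a, test = b,
                               n_reference = sum(labels == a),
                               n_test = sum(labels == b))
        flt
    }
    grps <- sort(unique(group))
    if (length(grps) >= 2) {
        for (i in seq_len(length(grps) - 1L)) for (j in (i + 1L):length(grps)) {
            cols <- which(group %in% c(grps[i], grps[j]))
            nm <- paste0(grps[j], "_vs_", grps[i])
            r <- runOne(cols, group[cols], nm, grps[i], grps[j])
            if (!is.null(r)) out[[nm]] <- r
        }
    }
    base <- tpLevels[1]
    for (g in grps) {
        for (t in tpLevels[-1]) {
            cols <- which(group == g & tp %in% c(base, t))
            nm <- paste0(g, "_", t, "_vs_", base)
            r <- runOne(cols, tp[cols], nm, base, t)
            if (!is.null(r)) out[[nm]] <- r
        }
    }
    out
}
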