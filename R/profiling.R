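#' RNA species distribution per library
#'
#' Converts per-sample read-class counts into the per-library percentage
#' table used for RNA species profiles (No Adaptor / Short / rRNA / tRNA /
#' snRNA / snoRNA / miRNA-isomiR / Unmapped), plus group mean percentages
#' when groups are given.  Percentages of each non-empty sample sum to 100.
#'
#' @param classCountMatrix integer matrix, samples x classes; column names
#'   must be a subset of the read classes (\code{MAPPED} is reported as the
#'   miRNA/isomiR class).  A list of per-read class label vectors is also
#'   accepted.
#' @param groups optional per-sample group labels for group means.
#' @return list with \code{counts}, \code{percent} (per-sample, rows sum to
#'   100), \code{groupMeans} (or \code{NULL}) and \code{empty} (logical per
#'   sample; empty samples are all-zero and excluded from group means).
#' @export
speciesDistribution <- function(classCountMatrix, groups = NULL) {
    if (is.list(classCountMatrix) && !is.data.frame(classCountMatrix)) {
        classCountMatrix <- do.call(rbind, lapply(classCountMatrix, function(x)
            as.integer(classCounts(x))))
        colnames(classCountMatrix) <- READ_CLASSES
    }
    m <- as.matrix(classCountMatrix)
    bad <- setdiff(colnames(m), READ_CLASSES)
    if (length(bad) > 0)
        stop("unknown read class column(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    full <- matrix(0L, nrow = nrow(m), ncol = length(READ_CLASSES),
                   dimnames = list(rownames(m), READ_CLASSES))
    full[, colnames(m)] <- m
    tot <- rowSums(full)
    empty <- tot == 0
    pct <- full / ifelse(tot == 0, 1, tot) * 100
    groupMeans <- NULL
    if (!is.null(groups)) {
        keep <- !empty
        sums <- rowsum(pct[keep, , drop = FALSE], group = groups[keep])
        sizes <- as.vector(table(groups[keep])[rownames(sums)])
        groupMeans <- sweep(sums, 1, sizes, "/")
    }
    list(counts = full, percent = pct, groupMeans = groupMeans, empty = empty)
}

# log2(normalized + 1) transform shared by PCA and clustering; a pragmatic
# stand-in for a regularized log that keeps the variance-ranking and
# distance structure of abundant features
transformCounts <- function(counts, sizeFactors = NULL) {
    log2(normalizeCounts(counts, sizeFactors) + 1)
}

#' PCA of the top-variance features
#'
#' Transforms counts to log2(normalized + 1), selects the \code{k} features
#' with the highest variance across samples (all features when fewer exist),
#' and runs a PCA on the centered (not scaled) sample x feature matrix.
#' Component signs are fixed deterministically: the largest-magnitude
#' loading of each component is made positive.
#'
#' @param counts count matrix or \code{SummarizedExperiment}.
#' @param sizeFactors optional size factors (default
#'   \code{\link{medianOfRatios}}).
#' @param k number of top-variance features (default 500).
#' @return list with \code{coordinates} (samples x PCs),
#'   \code{explainedVariance} (percent per PC, non-increasing),
#'   \code{rotation}, and \code{features} (the features used).
#' @export
pcaProfile <- function(counts, sizeFactors = NULL, k = 500L) {
    tr <- transformCounts(counts, sizeFactors)
    if (ncol(tr) < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
    stopifnot(k >= 2L)
    v <- apply(tr, 1, stats::var)
    ord <- order(-v, rownames(tr))
    use <- ord[seq_len(min(k, nrow(tr)))]
    x <- t(tr[use, , drop = FALSE])
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    for (j in seq_len(ncol(pc$rotation))) {
        i <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[i, j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    ev <- pc$sdev^2
    list(coordinates = pc$x,
         explainedVariance = 100 * ev / sum(ev),
         rotation = pc$rotation,
         features = rownames(tr)[use])
}

#' Ward hierarchical clustering of samples
#'
#' Euclidean distances on the same log2(normalized + 1) matrix as the PCA,
#' Ward linkage in the Ward.D2 variant (merges minimize the increase in
#' total within-cluster variance on squared euclidean distances).
#'
#' @inheritParams pcaProfile
#' @return an \code{hclust} object; \code{$method} is \code{"ward.D2"} and
#'   the distance metric is recorded in \code{$dist.method}.
#' @export
clusterSamples <- function(counts, sizeFactors = NULL) {
    tr <- transformCounts(counts, sizeFactors)
    if (ncol(tr) < 2L)
        stop("clustering requires at least 2 samples", call. = FALSE)
    stats::hclust(stats::dist(t(tr), method = "euclidean"),
                  method = "ward.D2")
}

#' Overlap between most-abundant reference features and up-regulated sets
#'
#' Ranks features by mean normalized count within the reference-group
#' samples (ties broken by feature id), takes the top \code{nTop}, and
#' intersects that set with each supplied set of up-regulated features (one
#' per post-feeding time point).  Also reports the cumulative share of all
#' reference-group reads that the top set represents.
#'
#' @param referenceCounts count matrix of the reference group's samples
#'   (e.g. colostrum-EV libraries), or a \code{SummarizedExperiment}.
#' @param upSets named list of character vectors of up-regulated feature
#'   ids, one per time point.
#' @param nTop size of the abundance set (default 100); capped at the
#'   feature count with a warning.
#' @param sizeFactors optional size factors for the reference samples.
#' @return list with \code{overlaps} (\code{data.frame}: time_point, n_top,
#'   overlap_count, overlap_percent), \code{topFeatures}, and
#'   \code{topReadFraction} (percent of all reads carried by the top set).
#' @export
abundanceOverlap <- function(referenceCounts, upSets, nTop = 100L,
                             sizeFactors = NULL) {
    if (methods::is(referenceCounts, "SummarizedExperiment"))
        referenceCounts <- SummarizedExperiment::assay(referenceCounts,
                                                       "counts")
    referenceCounts <- as.matrix(referenceCounts)
    stopifnot(nTop >= 1L)
    if (nTop > nrow(referenceCounts)) {
        warning("nTop exceeds the feature count; using all ",
                nrow(referenceCounts), " features")
        nTop <- nrow(referenceCounts)
    }
    norm <- normalizeCounts(referenceCounts, sizeFactors)
    abundance <- rowMeans(norm)
    ord <- order(-abundance, rownames(referenceCounts))
    top <- rownames(referenceCounts)[ord[seq_len(nTop)]]
    ov <- data.frame(
        time_point = names(upSets),
        n_top = nTop,
        overlap_count = vapply(upSets, function(u)
            length(intersect(top, u)), integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    ov$overlap_percent <- 100 * ov$overlap_count / ov$n_top
    list(overlaps = ov, topFeatures = top,
         topReadFraction = 100 * sum(abundance[ord[seq_len(nTop)]]) /
             sum(abundance))
}
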