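#' Run the full isomiR analysis pipeline
#'
#' Chains every stage on a set of input files: reference loading, isomiR
#' space enumeration, per-sample preprocessing (adapter trimming, length
#' filter, contaminant removal), exact/one-mismatch quantification,
#' canonical rollup, negative-binomial differential expression over the
#' standard contrasts, and the descriptive profile analytics (species
#' distribution, Ward clustering, top-variance PCA, abundance/up-regulation
#' overlap).  Optionally adds pathway enrichment when a target map and GMT
#' file are supplied.  Pointing the inputs at real FASTQ libraries and a
#' miRBase-style reference runs the same analysis on real data.
#'
#' @param matureFasta,hairpinFasta miRNA reference FASTA paths.
#' @param contaminantFasta contaminant FASTA with class-prefixed headers
#'   (\code{NULL} to skip contaminant filtering).
#' @param sampleSheet \code{data.frame} or TSV path with columns
#'   \code{sample_id}, \code{group}, \code{time_point}, \code{fastq}.
#' @param outDir output directory for all result tables (\code{NULL}: no
#'   files written, results returned only).
#' @param params an \code{\link{isomirParams}} list.
#' @param preprocParams a \code{\link{preprocessParams}} list.
#' @param thresholds a \code{\link{significanceThresholds}} list.
#' @param referenceGroup group whose libraries define the abundance ranking
#'   of the overlap analysis (default: first group on the sheet).
#' @param nTop abundance set size for the overlap analysis (default 100).
#' @param pcaTopK top-variance feature count for the PCA (default 500).
#' @param targetMap,pathwaysGmt optional target-map TSV and GMT paths to
#'   run pathway enrichment on the up-regulated canonical miRNAs.
#' @param linkMap optional mature-to-hairpin link TSV.
#' @return list with components \code{space}, \code{counts} (isomiR-level
#'   \code{SummarizedExperiment}), \code{canonical}, \code{libraryStats},
#'   \code{speciesDistribution}, \code{de} (per-contrast results),
#'   \code{pca}, \code{clustering}, \code{overlap}, \code{enrichment}
#'   (or \code{NULL}), and \code{files} (paths written).
#' @export
runPipeline <- function(matureFasta, hairpinFasta, contaminantFasta,
                        sampleSheet, outDir = NULL,
                        params = isomirParams(),
                        preprocParams = preprocessParams(),
                        thresholds = significanceThresholds(),
                        referenceGroup = NULL, nTop = 100L,
                        pcaTopK = 500L, targetMap = NULL,
                        pathwaysGmt = NULL, linkMap = NULL) {
    if (is.character(sampleSheet) && length(sampleSheet) == 1)
        sampleSheet <- readTsv(sampleSheet)
    stopifnot(all(c("sample_id", "group", "time_point", "fastq") %in%
                  colnames(sampleSheet)))

    ref <- loadMirnaReference(matureFasta, hairpinFasta, linkMap)
    space <- enumerateIsomirSpace(ref, params)
    index <- buildMatchIndex(space@sequences)
    contIdx <- if (is.null(contaminantFasta)) list() else
        buildContaminantIndex(contaminantFasta,
                              minLen = preprocParams$minLen)

    classTab <- matrix(0L, nrow = nrow(sampleSheet),
                       ncol = length(READ_CLASSES),
                       dimnames = list(sampleSheet$sample_id, READ_CLASSES))
    inserts <- list()
    classes <- list()
    for (s in seq_len(nrow(sampleSheet))) {
        sid <- sampleSheet$sample_id[s]
        reads <- readFastqSequences(sampleSheet$fastq[s])
        pp <- classifyReads(reads, contIdx, preprocParams)
        q <- quantifyLibrary(pp$retained, index, space)
        cls <- pp$class
        cls[cls == "RETAINED"] <- ifelse(q$mappedMask, "MAPPED", "UNMAPPED")
        classes[[sid]] <- cls
        classTab[sid, ] <- as.integer(classCounts(cls))
        inserts[[sid]] <- pp$retained
    }

    se <- quantifyExperiment(inserts, index, space, sampleSheet)
    canonical <- rollupCanonical(se)
    dist <- speciesDistribution(classTab, groups = sampleSheet$group)
    de <- runContrasts(se, thresholds)
    deCanonical <- runContrasts(canonical, thresholds)
    sf <- tryCatch(
        medianOfRatios(SummarizedExperiment::assay(se, "counts")),
        error = function(e)
            medianOfRatios(SummarizedExperiment::assay(se, "counts"),
                           pseudoReference = TRUE))
    pca <- pcaProfile(se, sf, k = pcaTopK)
    clust <- clusterSamples(se, sf)

    if (is.null(referenceGroup)) referenceGroup <- sampleSheet$group[1]
    refCols <- sampleSheet$sample_id[sampleSheet$group == referenceGroup]
    otherGroups <- setdiff(unique(sampleSheet$group), referenceGroup)
    upSets <- list()
    for (nm in names(de)) {
        cmp <- de[[nm]]$comparison
        if (grepl("_vs_", nm) && any(startsWith(nm, otherGroups)) &&
            cmp$reference %in% sampleSheet$time_point)
            upSets[[cmp$test]] <- de[[nm]]$up$feature_id
    }
    overlap <- if (length(upSets) > 0)
        abundanceOverlap(
            SummarizedExperiment::assay(se, "counts")[, refCols,
                                                      drop = FALSE],
            upSets, nTop = nTop, sizeFactors = sf[refCols]) else NULL

    enr <- NULL
    if (!is.null(targetMap) && !is.null(pathwaysGmt)) {
        upMirnas <- unique(unlist(lapply(deCanonical, function(d)
            if (d$comparison$reference %in% sampleSheet$time_point)
                d$up$feature_id else character(0)), use.names = FALSE))
        if (length(upMirnas) > 0) {
            tm <- readTargetMap(targetMap)
            enr <- tryCatch(
                pathwayEnrichment(upMirnas, tm, readGmt(pathwaysGmt)),
                error = function(e) NULL)
        }
    }

    files <- character(0)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        out <- function(name) file.path(outDir, name)
        writeIsomirSpace(space, out("isomir_reference.fa"),
                         out("isomir_annotation.tsv"))
        writeCountTable(se, out("isomir_counts.tsv"))
        writeCountTable(canonical, out("canonical_counts.tsv"))
        writeTsv(data.frame(sample_id = rownames(classTab), classTab),
                 out("library_stats.tsv"))
        writeTsv(data.frame(sample_id = rownames(dist$percent),
                            round(dist$percent, 4)),
                 out("species_distribution.tsv"))
        for (nm in names(de))
            writeTsv(de[[nm]]$all, out(paste0("de_isomir_", nm, ".tsv")))
        for (nm in names(deCanonical))
            writeTsv(deCanonical[[nm]]$all,
                     out(paste0("de_canonical_", nm, ".tsv")))
        writeTsv(data.frame(sample_id = rownames(pca$coordinates),
                            pca$coordinates[, seq_len(
                                min(5, ncol(pca$coordinates))),
                                drop = FALSE]),
                 out("pca_coordinates.tsv"))
        writeTsv(data.frame(merge_order = seq_len(nrow(clust$merge)),
                            left = clust$merge[, 1],
                            right = clust$merge[, 2],
                            height = clust$height),
                 out("clustering_linkage.tsv"))
        if (!is.null(overlap))
            writeTsv(overlap$overlaps, out("abundance_overlap.tsv"))
        if (!is.null(enr)) {
            writeTsv(enr, out("enrichment.tsv"))
            writeTsv(topEnrichment(enr), out("enrichment_top20.tsv"))
        }
        files <- list.files(outDir, full.names = TRUE)
    }

    list(space = space, counts = se, canonical = canonical,
         libraryStats = classTab, speciesDistribution = dist,
         de = de, deCanonical = deCanonical, sizeFactors = sf,
         pca = pca, clustering = clust, overlap = overlap,
         enrichment = enr, files = files)
}
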