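#' Simulate a mature/hairpin miRNA reference plus contaminants
#'
#' Generates random hairpins (70-90 nt) each embedding one mature miRNA
#' (20-23 nt) with at least 10 nt of flank on both sides (so every templated
#' extension up to \code{maxAdd} exists), and contaminant sequences
#' (rRNA 80-120 nt, tRNA 60-90 nt, snRNA/snoRNA 60-110 nt) rejection-sampled
#' so that no contaminant contains any substring within Hamming distance 1
#' of any enumerated isomiR variant — contaminant classification can then
#' never steal miRNA-derived reads.  Output is byte-deterministic under a
#' fixed seed.
#'
#' @param nMirnas number of miRNA loci (default 30).
#' @param params \code{\link{isomirParams}} used to enumerate the variant
#'   space that contaminants are screened against.
#' @param contaminantsPerClass sequences per contaminant class (default 4).
#' @param seed RNG seed.
#' @param dir optional directory; when given, \code{mature.fa},
#'   \code{hairpin.fa} and \code{contaminants.fa} are written there.
#' @param maxAttempts rejection-sampling bound per contaminant (default 50).
#' @return list with \code{reference} (an
#'   \code{\link[=IsomirReference-class]{IsomirReference}}),
#'   \code{contaminants} (named list of character vectors), \code{space}
#'   (the enumerated \code{IsomirSpace}) and \code{files} (paths or
#'   \code{NULL}).
#' @export
simulateReference <- function(nMirnas = 30L, params = isomirParams(),
                              contaminantsPerClass = 4L, seed = 1L,
                              dir = NULL, maxAttempts = 50L) {
    stopifnot(nMirnas >= 1L)
    set.seed(seed)
    ids <- sprintf("syn-miR-%03d", seq_len(nMirnas))
    hpIds <- sprintf("syn-mir-%03d", seq_len(nMirnas))
    hpLen <- sample(70:90, nMirnas, replace = TRUE)
    matLen <- sample(20:23, nMirnas, replace = TRUE)
    hairpins <- character(nMirnas)
    matures <- character(nMirnas)
    starts <- integer(nMirnas)
    for (i in seq_len(nMirnas)) {
        h <- randomDna(hpLen[i])
        s <- sample(10:(hpLen[i] - matLen[i] - 10L), 1L) # 0-based start
        hairpins[i] <- h
        matures[i] <- substr(h, s + 1L, s + matLen[i])
        starts[i] <- s
    }
    names(matures) <- ids
    names(hairpins) <- hpIds
    ref <- methods::new("IsomirReference",
        mature = Biostrings::DNAStringSet(matures),
        hairpin = Biostrings::DNAStringSet(hairpins),
        matureAnno = S4Vectors::DataFrame(
            mirna_id = ids, name = ids, hairpin_id = hpIds,
            start = starts, end = starts + matLen))
    space <- enumerateIsomirSpace(ref, params)
    variants <- Biostrings::DNAStringSet(as.character(space@sequences))

    lenRange <- list(RRNA = 80:120, TRNA = 60:90, SNRNA = 60:110,
                     SNORNA = 60:110)
    contaminants <- list()
    for (cls in CONTAMINANT_CLASSES) {
        out <- character(contaminantsPerClass)
        for (j in seq_len(contaminantsPerClass)) {
            ok <- FALSE
            for (attempt in seq_len(maxAttempts)) {
                cand <- randomDna(sample(lenRange[[cls]], 1L))
                subj <- Biostrings::DNAString(cand)
                # reject if any variant occurs in cand within Hamming dist 1
                hits <- vapply(seq_along(variants), function(k)
                    Biostrings::countPattern(variants[[k]], subj,
                        max.mismatch = 1) > 0, logical(1))
                if (!any(hits)) { ok <- TRUE; break }
            }
            if (!ok)
                stop("contaminant rejection sampling failed after ",
                     maxAttempts, " attempts; the variant space is too ",
                     "dense — use a larger alphabet distance or fewer ",
                     "miRNAs", call. = FALSE)
            out[j] <- cand
        }
        contaminants[[cls]] <- out
    }
    files <- NULL
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        matPath <- file.path(dir, "mature.fa")
        hpPath <- file.path(dir, "hairpin.fa")
        contPath <- file.path(dir, "contaminants.fa")
        Biostrings::writeXStringSet(ref@mature, matPath)
        Biostrings::writeXStringSet(ref@hairpin, hpPath)
        contSeqs <- unlist(contaminants, use.names = FALSE)
        contNames <- unlist(lapply(names(contaminants), function(cls)
            sprintf("%s|synthetic_%s_%d", tolower(cls), tolower(cls),
                    seq_along(contaminants[[cls]]))), use.names = FALSE)
        cont <- Biostrings::DNAStringSet(contSeqs)
        names(cont) <- contNames
        Biostrings::writeXStringSet(cont, contPath)
        files <- c(mature = matPath, hairpin = hpPath,
                   contaminants = contPath)
    }
    list(reference = ref, contaminants = contaminants, space = space,
         files = files)
}

#' Simulation design for a synthetic feeding study
#'
#' The default design mirrors a colostrum-feeding transfer study: a
#' colostrum-EV group and a calf-plasma-EV group sampled before the first
#' feeding (0 h) and at post-feeding time points, three animals per cell,
#' 50-nt single-end reads (insert + 3' adapter), with planted
#' time-dependent log2 fold changes in the calf-EV group.
#'
#' @param groups sample groups (default colostrum_EV, calf_EV).
#' @param timePoints time point labels, earliest first (default 0h, 1h, 3h,
#'   6h, 12h).
#' @param replicates animals per group x time point (default 3).
#' @param depth reads per library (default 1e5).
#' @param dispersion NB dispersion of true counts (default 0.1).
#' @param errorRate per-base substitution sequencing error rate applied to
#'   inserts (default 0.001); adapters are appended error-free.
#' @param contaminantFraction,shortFraction,noAdapterFraction expected
#'   fractions of contaminant-derived, too-short-insert and
#'   adapterless reads (defaults 0.1, 0.02, 0.05); their sum must be < 1.
#' @param adapter 3' adapter appended to every insert (default as in
#'   \code{\link{preprocessParams}}).
#' @param readLength sequencing read length (default 50).
#' @param canonicalMass fraction of each miRNA's expression carried by its
#'   canonical (0,0) variant (default 0.7); the rest is spread over a
#'   random subset of its end-variants.
#' @param variantsPerMirna number of non-canonical variants expressed per
#'   miRNA (default 8).
#' @param plantedEffects \code{data.frame} with columns \code{feature_id}
#'   (variant id), \code{group}, \code{time_point}, \code{log2FC}: the
#'   named feature's expected abundance is scaled by \code{2^log2FC} in the
#'   matching samples.
#' @param seed RNG seed (fixed seed implies byte-identical FASTQ output).
#' @return validated design list.
#' @export
simulationDesign <- function(groups = c("colostrum_EV", "calf_EV"),
                             timePoints = c("0h", "1h", "3h", "6h", "12h"),
                             replicates = 3L, depth = 1e5,
                             dispersion = 0.1, errorRate = 0.001,
                             contaminantFraction = 0.1,
                             shortFraction = 0.02,
                             noAdapterFraction = 0.05,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             readLength = 50L, canonicalMass = 0.7,
                             variantsPerMirna = 8L,
                             plantedEffects = NULL, seed = 1L) {
    fr <- c(contaminantFraction, shortFraction, noAdapterFraction)
    stopifnot(all(fr >= 0), all(fr <= 1), sum(fr) < 1, depth >= 1,
              replicates >= 1, dispersion > 0, errorRate >= 0,
              canonicalMass > 0, canonicalMass <= 1, readLength >= 20L)
    list(groups = groups, timePoints = timePoints,
         replicates = as.integer(replicates), depth = depth,
         dispersion = dispersion, errorRate = errorRate,
         contaminantFraction = contaminantFraction,
         shortFraction = shortFraction,
         noAdapterFraction = noAdapterFraction,
         adapter = normalizeDna(adapter, "adapter"),
         readLength = as.integer(readLength),
         canonicalMass = canonicalMass,
         variantsPerMirna = as.integer(variantsPerMirna),
         plantedEffects = plantedEffects, seed = as.integer(seed))
}

#' Default planted postprandial effects
#'
#' Emulates a time-dependent increase: each selected calf-EV feature gets a
#' log2 fold change that grows with the post-feeding time point
#' (\code{log2FC * (index of time point) / (number of post time points)}).
#'
#' @param features variant ids to up-regulate.
#' @param design a \code{\link{simulationDesign}} list.
#' @param group group carrying the effect (default \code{"calf_EV"}).
#' @param log2FC effect size at the last time point (default 2).
#' @return \code{data.frame} suitable as \code{plantedEffects}.
#' @export
postprandialEffects <- function(features, design, group = "calf_EV",
                                log2FC = 2) {
    post <- design$timePoints[-1]
    do.call(rbind, lapply(seq_along(post), function(i)
        data.frame(feature_id = features, group = group,
                   time_point = post[i],
                   log2FC = log2FC * i / length(post),
                   stringsAsFactors = FALSE)))
}

#' Simulate a full small RNA-seq experiment with ground truth
#'
#' Draws per-group isomiR proportions (a fixed share on each canonical
#' variant, Dirichlet weights across miRNAs and across their end-variants),
#' applies planted group/time effects multiplicatively with renormalization,
#' draws per-feature library counts from a negative binomial, and emits
#' 50-nt reads: insert (variant sequence with substitution errors at the
#' design error rate) + error-free adapter, padded with A and truncated to
#' the read length.  Contaminant fragments, too-short inserts and
#' adapterless random reads are injected at the design fractions.  Every
#' read carries a ground-truth provenance label.
#'
#' @param simRef result of \code{\link{simulateReference}} (reference,
#'   contaminants and enumerated space).
#' @param design a \code{\link{simulationDesign}} list.
#' @param dir optional output directory; when given, per-sample
#'   \code{<sample>.fastq.gz}, \code{sample_sheet.tsv}, per-sample
#'   \code{truth_<sample>.tsv}, \code{expected_counts.tsv} and
#'   \code{manifest.txt} are written.
#' @return list with \code{sampleSheet}, \code{reads} (per sample: named
#'   character vector of read sequences), \code{truth} (per sample:
#'   \code{data.frame} read_id/class/source), \code{expectedCounts}
#'   (features x samples matrix of expected miRNA-read counts),
#'   \code{trueProportions}, \code{space}, and \code{files}.
#' @export
simulateExperiment <- function(simRef, design = simulationDesign(),
                               dir = NULL) {
    space <- simRef$space
    v <- space@variants
    set.seed(design$seed)

    canonical <- which(v$e5 == 0L & v$e3 == 0L)
    canonical <- canonical[!duplicated(v$canonical_parent[canonical])]
    mirnas <- v$canonical_parent[canonical]
    nM <- length(mirnas)
    if (nM == 0) stop("variant space has no canonical variants", call. = FALSE)

    pe <- design$plantedEffects
    if (!is.null(pe) && !all(pe$feature_id %in% v$variant_id))
        stop("planted feature(s) absent from the variant space: ",
             paste(setdiff(pe$feature_id, v$variant_id), collapse = ", "),
             call. = FALSE)

    # per-group expression program over the variant space
    groupProps <- list()
    for (g in design$groups) {
        w <- stats::rgamma(nM, shape = 1)   # Dirichlet across miRNAs
        w <- w / sum(w)
        prop <- stats::setNames(numeric(nrow(v)), v$variant_id)
        for (i in seq_len(nM)) {
            own <- which(v$canonical_parent == mirnas[i])
            canIdx <- canonical[i]
            others <- setdiff(own, canIdx)
            nv <- min(design$variantsPerMirna, length(others))
            pick <- if (nv > 0) others[sample.int(length(others), nv)] else
                integer(0)
            prop[canIdx] <- prop[canIdx] + w[i] * design$canonicalMass
            if (nv > 0) {
                sub <- stats::rgamma(nv, shape = 1)
                prop[pick] <- prop[pick] +
                    w[i] * (1 - design$canonicalMass) * sub / sum(sub)
            }
        }
        groupProps[[g]] <- prop / sum(prop)
    }

    sheet <- expand.grid(replicate = seq_len(design$replicates),
                         time_point = design$timePoints,
                         group = design$groups,
                         stringsAsFactors = FALSE)
    sheet$sample_id <- sprintf("%s_%s_r%d", sheet$group, sheet$time_point,
                               sheet$replicate)
    sheet <- sheet[, c("sample_id", "group", "time_point", "replicate")]

    nSpecial <- design$contaminantFraction + design$shortFraction +
        design$noAdapterFraction
    mirnaDepth <- design$depth * (1 - nSpecial)
    contClasses <- names(simRef$contaminants)

    finishRead <- function(insert) {
        r <- paste0(insert, design$adapter)
        pad <- design$readLength - nchar(r)
        r <- ifelse(pad > 0, paste0(r, strrep("A", pmax(pad, 0))), r)
        substr(r, 1L, design$readLength)
    }

    expected <- matrix(0, nrow = nrow(v), ncol = nrow(sheet),
                       dimnames = list(v$variant_id, sheet$sample_id))
    trueProp <- expected
    reads <- list(); truth <- list()
    for (s in seq_len(nrow(sheet))) {
        g <- sheet$group[s]; tpt <- sheet$time_point[s]
        prop <- groupProps[[g]]
        if (!is.null(pe)) {
            hit <- pe$group == g & pe$time_point == tpt
            if (any(hit)) {
                prop[pe$feature_id[hit]] <-
                    prop[pe$feature_id[hit]] * 2^pe$log2FC[hit]
                prop <- prop / sum(prop)
            }
        }
        trueProp[, s] <- prop
        mu <- mirnaDepth * prop
        expected[, s] <- mu
        cnt <- stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
        src <- rep(v$variant_id, cnt)
        inserts <- rep(as.character(v$sequence), cnt)
        inserts <- mutateSequences(inserts, design$errorRate)
        mirnaReads <- finishRead(inserts)
        labels <- data.frame(class = rep("MIRNA", length(mirnaReads)),
                             source = src, stringsAsFactors = FALSE)

        nCont <- stats::rpois(1, design$depth * design$contaminantFraction)
        if (nCont > 0) {
            cls <- sample(contClasses, nCont, replace = TRUE)
            cseq <- vapply(cls, function(cc)
                sample(simRef$contaminants[[cc]], 1L), character(1))
            clen <- sample(16:40, nCont, replace = TRUE)
            clen <- pmin(clen, nchar(cseq))
            cstart <- vapply(seq_len(nCont), function(i)
                sample.int(nchar(cseq[i]) - clen[i] + 1L, 1L), integer(1))
            cins <- substr(cseq, cstart, cstart + clen - 1L)
            cins <- mutateSequences(cins, design$errorRate)
            labels <- rbind(labels, data.frame(class = cls, source = NA,
                                               stringsAsFactors = FALSE))
            mirnaReads <- c(mirnaReads, finishRead(cins))
        }
        nShort <- stats::rpois(1, design$depth * design$shortFraction)
        if (nShort > 0) {
            slen <- sample(5:15, nShort, replace = TRUE)
            pick <- sample.int(nrow(v), nShort, replace = TRUE)
            sseq <- substr(as.character(v$sequence[pick]), 1L,
                           pmin(slen, nchar(as.character(v$sequence[pick]))))
            labels <- rbind(labels, data.frame(
                class = rep("SHORT", nShort), source = NA,
                stringsAsFactors = FALSE))
            mirnaReads <- c(mirnaReads, finishRead(sseq))
        }
        nNoAd <- stats::rpois(1, design$depth * design$noAdapterFraction)
        if (nNoAd > 0) {
            labels <- rbind(labels, data.frame(
                class = rep("NO_ADAPTOR", nNoAd), source = NA,
                stringsAsFactors = FALSE))
            mirnaReads <- c(mirnaReads, randomDna(rep(design$readLength,
                                                      nNoAd)))
        }
        ord <- sample.int(length(mirnaReads))
        mirnaReads <- mirnaReads[ord]
        labels <- labels[ord, , drop = FALSE]
        ids <- sprintf("%s.read%07d", sheet$sample_id[s],
                       seq_along(mirnaReads))
        names(mirnaReads) <- ids
        labels <- cbind(read_id = ids, labels)
        rownames(labels) <- NULL
        reads[[sheet$sample_id[s]]] <- mirnaReads
        truth[[sheet$sample_id[s]]] <- labels
    }

    files <- NULL
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        fq <- character(nrow(sheet))
        for (s in seq_len(nrow(sheet))) {
            sid <- sheet$sample_id[s]
            fq[s] <- file.path(dir, paste0(sid, ".fastq.gz"))
            x <- Biostrings::DNAStringSet(reads[[sid]])
            q <- Biostrings::BStringSet(strrep("I", nchar(reads[[sid]])))
            Biostrings::writeXStringSet(x, fq[s], format = "fastq",
                                        compress = TRUE, qualities = q)
            writeTsv(truth[[sid]], file.path(dir, paste0("truth_", sid,
                                                         ".tsv")))
        }
        sheetOut <- cbind(sheet, fastq = fq)
        writeTsv(sheetOut, file.path(dir, "sample_sheet.tsv"))
        writeTsv(data.frame(variant_id = rownames(expected),
                            round(expected, 4)),
                 file.path(dir, "expected_counts.tsv"))
        cfg <- c(sprintf("groups=%s", paste(design$groups, collapse = ",")),
                 sprintf("timePoints=%s",
                         paste(design$timePoints, collapse = ",")),
                 sprintf("replicates=%d", design$replicates),
                 sprintf("depth=%g", design$depth),
                 sprintf("dispersion=%g", design$dispersion),
                 sprintf("errorRate=%g", design$errorRate),
                 sprintf("contaminantFraction=%g",
                         design$contaminantFraction),
                 sprintf("shortFraction=%g", design$shortFraction),
                 sprintf("noAdapterFraction=%g", design$noAdapterFraction),
                 sprintf("adapter=%s", design$adapter),
                 sprintf("readLength=%d", design$readLength),
                 sprintf("seed=%d", design$seed))
        writeLines(cfg, file.path(dir, "manifest.txt"))
        files <- list(fastq = stats::setNames(fq, sheet$sample_id),
                      sampleSheet = file.path(dir, "sample_sheet.tsv"))
        sheet <- sheetOut
    }
    list(sampleSheet = sheet, reads = reads, truth = truth,
         expectedCounts = expected, trueProportions = trueProp,
         space = space, files = files)
}
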