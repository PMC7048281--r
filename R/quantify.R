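#' Assign inserts to isomiR variants (best-stratum, one mismatch)
#'
#' Ungapped, length-preserving assignment: an insert matches a variant of
#' identical length either exactly (stratum 0) or with exactly one
#' substitution (stratum 1).  If any exact hit exists, stratum 1 is never
#' consulted.  Within a stratum, ties between candidate variants are broken
#' deterministically: (a) smallest \code{|e5|+|e3|} over the candidate's
#' parent annotations, then (b) lexicographically smallest
#' \code{variant_id}.  The single allowed substitution is reported as a
#' mismatch descriptor (0-based position in the read, reference base, read
#' base) — the "polymorphic isomiR" part of the count key.
#'
#' @param inserts character vector of preprocessed insert sequences.
#' @param index \code{\link[=MatchIndex-class]{MatchIndex}} over the variant
#'   sequences of \code{space}.
#' @param space the \code{\link[=IsomirSpace-class]{IsomirSpace}} the index
#'   was built from.
#' @return \code{data.frame} with one row per insert: \code{insert},
#'   \code{variant_id} (\code{NA} if unmapped), \code{stratum} (0, 1 or
#'   \code{NA}), \code{mm_pos} (0-based), \code{mm_ref}, \code{mm_read},
#'   \code{key} (serialized isomiR key, \code{NA} if unmapped).
#' @export
assignReads <- function(inserts, index, space) {
    stopifnot(methods::is(index, "MatchIndex"), methods::is(space, "IsomirSpace"))
    v <- space@variants
    if (length(index@sequences) != nrow(v) ||
        !identical(index@sequences, as.character(v$sequence)))
        stop("index does not match the variant space", call. = FALSE)
    uniq <- unique(inserts)
    ex <- exactLookup(index, uniq)
    res <- data.frame(insert = uniq,
                      variant_id = NA_character_,
                      stratum = NA_integer_,
                      mm_pos = NA_integer_,
                      mm_ref = NA_character_,
                      mm_read = NA_character_,
                      stringsAsFactors = FALSE)
    hit0 <- !is.na(ex)
    res$variant_id[hit0] <- v$variant_id[ex[hit0]]
    res$stratum[hit0] <- 0L
    minOff <- v$min_offset
    vids <- v$variant_id
    for (i in which(!hit0)) {
        cand <- hamming1Lookup(index, uniq[i])
        if (length(cand) == 0) next
        if (length(cand) > 1) {
            o <- order(minOff[cand], vids[cand])
            cand <- cand[o]
        }
        pick <- cand[1L]
        res$variant_id[i] <- vids[pick]
        res$stratum[i] <- 1L
        p <- mismatchPositions(uniq[i], index@sequences[pick])
        res$mm_pos[i] <- p - 1L  # 0-based
        res$mm_ref[i] <- substr(index@sequences[pick], p, p)
        res$mm_read[i] <- substr(uniq[i], p, p)
    }
    res$key <- ifelse(is.na(res$variant_id), NA_character_,
        ifelse(res$stratum == 0L, res$variant_id,
               sprintf("%s|mm:%d:%s>%s", res$variant_id, res$mm_pos,
                       res$mm_ref, res$mm_read)))
    res[match(inserts, uniq), , drop = FALSE]
}

#' Quantify one library of retained inserts
#'
#' Accumulates counts per isomiR key — one key per unique read sequence,
#' combining the matched variant with the mismatch descriptor, so exact and
#' polymorphic (one-substitution) reads of the same variant are counted as
#' distinct features ("the sum of each individual sequence").
#'
#' @inheritParams assignReads
#' @return list with \code{counts} (named integer vector over isomiR keys),
#'   \code{unmapped} (count), \code{keyAnno} (\code{data.frame}: key,
#'   variant_id, e5, e3, mismatch, canonical_parent, ambiguous) and
#'   \code{mappedMask} (logical per input insert).  Conservation holds:
#'   \code{sum(counts) + unmapped == length(inserts)}.
#' @export
quantifyLibrary <- function(inserts, index, space) {
    asg <- assignReads(inserts, index, space)
    mapped <- !is.na(asg$key)
    counts <- integer(0)
    keyAnno <- data.frame(key = character(), variant_id = character(),
                          e5 = integer(), e3 = integer(),
                          mismatch = character(),
                          canonical_parent = character(),
                          ambiguous = logical(), stringsAsFactors = FALSE)
    if (any(mapped)) {
        tab <- table(asg$key[mapped])
        counts <- as.integer(tab)
        names(counts) <- names(tab)
        first <- asg[mapped, , drop = FALSE]
        first <- first[!duplicated(first$key), , drop = FALSE]
        v <- space@variants
        m <- match(first$variant_id, v$variant_id)
        keyAnno <- data.frame(
            key = first$key,
            variant_id = first$variant_id,
            e5 = v$e5[m],
            e3 = v$e3[m],
            mismatch = ifelse(first$stratum == 0L, "",
                sprintf("%d:%s>%s", first$mm_pos, first$mm_ref, first$mm_read)),
            canonical_parent = v$canonical_parent[m],
            ambiguous = v$ambiguous[m],
            stringsAsFactors = FALSE)
        keyAnno <- keyAnno[order(keyAnno$key), , drop = FALSE]
        counts <- counts[keyAnno$key]
    }
    list(counts = counts, unmapped = sum(!mapped), keyAnno = keyAnno,
         mappedMask = mapped)
}

#' Assemble an isomiR-level count matrix over samples
#'
#' Runs \code{\link{quantifyLibrary}} per sample and assembles a
#' \code{SummarizedExperiment} (features = isomiR keys, ordered
#' deterministically; samples in sheet order) with the key annotation as
#' \code{rowData} and the sample sheet as \code{colData}.
#'
#' @param insertsPerSample named list of character vectors of retained
#'   inserts, one per sample.
#' @inheritParams assignReads
#' @param sampleSheet optional \code{data.frame} with one row per sample
#'   (rownames or a \code{sample_id} column matching the list names).
#' @return \code{SummarizedExperiment} with assay \code{"counts"};
#'   per-sample unmapped read counts are in \code{colData()$unmapped} and
#'   \code{metadata()$featureLevel == "isomiR"}.
#' @export
quantifyExperiment <- function(insertsPerSample, index, space,
                               sampleSheet = NULL) {
    stopifnot(is.list(insertsPerSample), !is.null(names(insertsPerSample)))
    qs <- lapply(insertsPerSample, quantifyLibrary, index = index,
                 space = space)
    keys <- sort(unique(unlist(lapply(qs, function(q) q$keyAnno$key),
                               use.names = FALSE)))
    mat <- matrix(0L, nrow = length(keys), ncol = length(qs),
                  dimnames = list(keys, names(qs)))
    for (j in seq_along(qs)) {
        cj <- qs[[j]]$counts
        mat[names(cj), j] <- cj
    }
    anno <- do.call(rbind, lapply(qs, function(q) q$keyAnno))
    anno <- anno[!duplicated(anno$key), , drop = FALSE]
    anno <- anno[match(keys, anno$key), , drop = FALSE]
    rownames(anno) <- keys
    cd <- S4Vectors::DataFrame(
        sample_id = names(qs),
        retained = vapply(insertsPerSample, length, integer(1)),
        mapped = vapply(qs, function(q) sum(q$counts), integer(1)),
        unmapped = vapply(qs, function(q) q$unmapped, integer(1)),
        row.names = names(qs))
    if (!is.null(sampleSheet)) {
        ss <- as.data.frame(sampleSheet)
        if ("sample_id" %in% colnames(ss)) rownames(ss) <- ss$sample_id
        extra <- ss[names(qs), setdiff(colnames(ss), colnames(cd)),
                    drop = FALSE]
        cd <- cbind(cd, S4Vectors::DataFrame(extra))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat),
        rowData = S4Vectors::DataFrame(anno),
        colData = cd)
    S4Vectors::metadata(se)$featureLevel <- "isomiR"
    se
}

#' Roll isomiR-level counts up to canonical miRNAs
#'
#' Sums all isomiR-key counts whose variant resolves to the same canonical
#' parent miRNA (for shared-sequence variants, the lexicographically
#' smallest parent id; such features are flagged \code{ambiguous} in the
#' isomiR-level annotation).  Total counts are conserved.
#'
#' @param se isomiR-level \code{SummarizedExperiment} from
#'   \code{\link{quantifyExperiment}}.
#' @return canonical-level \code{SummarizedExperiment} (features = miRNA
#'   ids) with \code{metadata()$featureLevel == "canonical"}.
#' @export
rollupCanonical <- function(se) {
    rd <- SummarizedExperiment::rowData(se)
    if (is.null(rd$canonical_parent) || anyNA(rd$canonical_parent))
        stop("isomiR matrix contains keys with unknown canonical parent",
             call. = FALSE)
    mat <- SummarizedExperiment::assay(se, "counts")
    rolled <- rowsum(mat, group = as.character(rd$canonical_parent))
    rolled <- rolled[order(rownames(rolled)), , drop = FALSE]
    ambig <- vapply(split(as.logical(rd$ambiguous),
                          as.character(rd$canonical_parent)),
                    any, logical(1))
    out <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = rolled),
        rowData = S4Vectors::DataFrame(
            mirna_id = rownames(rolled),
            has_ambiguous_keys = ambig[rownames(rolled)],
            row.names = rownames(rolled)),
        colData = SummarizedExperiment::colData(se))
    S4Vectors::metadata(out)$featureLevel <- "canonical"
    out
}

#' Write a count matrix (isomiR or canonical) to TSV
#'
#' @param se a \code{SummarizedExperiment} from this package.
#' @param path output TSV; feature annotation columns precede the per-sample
#'   count columns.
#' @return invisibly, \code{path}.
#' @export
writeCountTable <- function(se, path) {
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    mat <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
    writeTsv(cbind(rd, mat), path)
}
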