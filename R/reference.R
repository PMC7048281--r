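#' Load a mature + hairpin miRNA reference
#'
#' Reads miRBase-style mature and hairpin FASTA files, normalizes sequences
#' to the DNA alphabet (U to T), resolves which hairpin each mature derives
#' from, and records the 0-based half-open coordinates of the mature within
#' its hairpin.
#'
#' Mature-to-hairpin linkage is resolved, in order of precedence, by
#' \enumerate{
#'   \item an explicit two-column map (\code{linkMap}: \code{mirna_id},
#'     \code{hairpin_id}),
#'   \item the shared name-prefix convention (a hairpin id that is a
#'     case-insensitive prefix of the mature id; the longest such id wins),
#'   \item substring search over all hairpins, which must locate the mature
#'     in exactly one hairpin.
#' }
#' A mature that occurs in none of the declared/candidate hairpins, or in
#' several hairpins with no declared link, is a hard error naming the
#' record.
#'
#' @param matureFasta path to the mature miRNA FASTA.
#' @param hairpinFasta path to the hairpin (precursor) FASTA.
#' @param linkMap optional \code{data.frame} (or TSV path) with columns
#'   \code{mirna_id}, \code{hairpin_id} declaring the linkage.
#' @return an \code{\link[=IsomirReference-class]{IsomirReference}}, ordered
#'   by \code{mirna_id}.
#' @examples
#' mat <- tempfile(fileext = ".fa"); hp <- tempfile(fileext = ".fa")
#' writeLines(c(">ex-miR-1", "UGAGGUAGUAGGUUGUAUAGUU"), mat)
#' writeLines(c(">ex-mir-1",
#'   "AAGGCTGAGGTAGTAGGTTGTATAGTTTCCGAGGCAAGGCAAGGCTTTTGGGCATGCAATCGATCGGGCAT"), hp)
#' ref <- loadMirnaReference(mat, hp)
#' matureAnnotation(ref)
#' @export
loadMirnaReference <- function(matureFasta, hairpinFasta, linkMap = NULL) {
    mat <- readFastaDna(matureFasta, what = "mature")
    hp <- readFastaDna(hairpinFasta, what = "hairpin")
    if (length(mat) == 0) {
        return(methods::new("IsomirReference",
            mature = Biostrings::DNAStringSet(),
            hairpin = Biostrings::DNAStringSet(hp),
            matureAnno = S4Vectors::DataFrame(
                mirna_id = character(), name = character(),
                hairpin_id = character(), start = integer(), end = integer())))
    }
    if (anyDuplicated(names(mat)))
        stop("duplicated mature ids in ", matureFasta, call. = FALSE)
    if (anyDuplicated(names(hp)))
        stop("duplicated hairpin ids in ", hairpinFasta, call. = FALSE)
    if (is.character(linkMap) && length(linkMap) == 1) linkMap <- readTsv(linkMap)

    hpNames <- names(hp)
    resolveOne <- function(id, seq) {
        declared <- NULL
        if (!is.null(linkMap)) {
            hit <- linkMap$hairpin_id[linkMap$mirna_id == id]
            if (length(hit) > 1)
                stop("mature '", id, "' declared in multiple hairpins in linkMap",
                     call. = FALSE)
            if (length(hit) == 1) declared <- hit
        }
        if (is.null(declared)) {
            # shared name-prefix convention, case-insensitive (miR vs mir)
            pref <- hpNames[startsWith(tolower(id), tolower(hpNames))]
            if (length(pref) > 0) declared <- pref[which.max(nchar(pref))]
        }
        if (!is.null(declared)) {
            if (!declared %in% hpNames)
                stop("mature '", id, "': declared hairpin '", declared,
                     "' not present in hairpin FASTA", call. = FALSE)
            pos <- regexpr(seq, hp[[declared]], fixed = TRUE)
            if (pos < 0)
                stop("mature '", id, "' not found within its hairpin '",
                     declared, "'", call. = FALSE)
            return(c(declared, pos - 1L))
        }
        # no declared link: the mature must occur in exactly one hairpin
        hits <- which(vapply(hp, function(h)
            grepl(seq, h, fixed = TRUE), logical(1)))
        if (length(hits) == 0)
            stop("mature '", id, "' not found in any hairpin", call. = FALSE)
        if (length(hits) > 1)
            stop("mature '", id, "' found in multiple hairpins (",
                 paste(hpNames[hits], collapse = ", "),
                 ") with no declared link", call. = FALSE)
        pos <- regexpr(seq, hp[[hits]], fixed = TRUE)
        c(hpNames[hits], pos - 1L)
    }

    res <- vapply(seq_along(mat),
                  function(i) resolveOne(names(mat)[i], mat[[i]]),
                  character(2))
    ord <- order(names(mat))
    anno <- S4Vectors::DataFrame(
        mirna_id = names(mat)[ord],
        name = names(mat)[ord],
        hairpin_id = res[1, ord],
        start = as.integer(res[2, ord]),
        end = as.integer(res[2, ord]) + nchar(mat)[ord]
    )
    methods::new("IsomirReference",
        mature = Biostrings::DNAStringSet(mat[ord]),
        hairpin = Biostrings::DNAStringSet(hp),
        matureAnno = anno)
}

# Read a FASTA into a named character vector in the DNA alphabet.
readFastaDna <- function(path, what = "sequence") {
    x <- Biostrings::readBStringSet(path)
    seqs <- as.character(x)
    # miRBase headers carry accessions/descriptions after the first word
    names(seqs) <- sub("\\s.*$", "", names(x))
    normalizeDna(seqs, what = what)
}

#' Enumeration parameters for the isomiR space
#'
#' @param maxTrim maximum nucleotides trimmed from either end (default 6).
#' @param maxAdd maximum nucleotides added at either end (default 3).
#' @param minLen minimum variant length retained (default 16); shorter
#'   variants can never be matched because shorter reads are discarded, so
#'   pruning them changes no result.
#' @param additionMode \code{"templated"} (additions take the flanking
#'   hairpin bases; variants that would run off the hairpin are skipped) or
#'   \code{"nontemplated_AU"} (all A/U mono- to tri-nucleotide tails are
#'   appended instead).
#' @return a validated parameter list.
#' @export
isomirParams <- function(maxTrim = 6L, maxAdd = 3L, minLen = 16L,
                         additionMode = c("templated", "nontemplated_AU")) {
    additionMode <- match.arg(additionMode)
    maxTrim <- as.integer(maxTrim); maxAdd <- as.integer(maxAdd)
    minLen <- as.integer(minLen)
    stopifnot(maxTrim >= 0L, maxAdd >= 0L, minLen >= 1L)
    list(maxTrim = maxTrim, maxAdd = maxAdd, minLen = minLen,
         additionMode = additionMode)
}

#' Enumerate the isomiR sequence space
#'
#' For every mature miRNA, generates all end-variant sequences with signed
#' end offsets \code{(e5, e3)} in \code{[-maxTrim, +maxAdd]^2} (negative =
#' trimmed, positive = added), drops variants shorter than \code{minLen},
#' and collapses identical sequences from different (miRNA, e5, e3) origins
#' into one variant carrying all parent annotations.  \code{(0, 0)}
#' reproduces the canonical mature exactly.  Output order is deterministic
#' (by sequence).
#'
#' In \code{templated} mode added bases are read off the hairpin flanks
#' (alternative DROSHA/DICER cleavage); a variant requiring more flank than
#' the hairpin provides is skipped.  In \code{nontemplated_AU} mode every
#' A/U tail of the requested length is generated instead.
#'
#' @param reference an \code{\link[=IsomirReference-class]{IsomirReference}}.
#' @param params an \code{\link{isomirParams}} list.
#' @return an \code{\link[=IsomirSpace-class]{IsomirSpace}}.
#' @export
enumerateIsomirSpace <- function(reference, params = isomirParams()) {
    stopifnot(methods::is(reference, "IsomirReference"))
    anno <- reference@matureAnno
    hp <- as.character(reference@hairpin)

    rows <- vector("list", nrow(anno))
    for (i in seq_len(nrow(anno))) {
        id <- anno$mirna_id[i]
        h <- hp[[anno$hairpin_id[i]]]
        s <- anno$start[i]; e <- anno$end[i]
        g <- expand.grid(e5 = seq(-params$maxTrim, params$maxAdd),
                         e3 = seq(-params$maxTrim, params$maxAdd))
        len <- (e - s) + g$e5 + g$e3
        g <- g[len >= params$minLen, , drop = FALSE]
        if (params$additionMode == "templated") {
            ns <- s - g$e5
            ne <- e + g$e3
            keep <- ns >= 0L & ne <= nchar(h)
            g <- g[keep, , drop = FALSE]
            seqs <- substring(h, ns[keep] + 1L, ne[keep])
            rows[[i]] <- data.frame(variantSeq = seqs, mirna_id = id,
                                    e5 = g$e5, e3 = g$e3,
                                    stringsAsFactors = FALSE)
        } else {
            core5 <- pmax(g$e5, 0L) # nontemplated bases at 5'
            core3 <- pmax(g$e3, 0L)
            # trims come from the mature itself; additions are A/U tails
            base <- substring(h, (s - pmin(g$e5, 0L)) + 1L, e + pmin(g$e3, 0L))
            out <- vector("list", nrow(g))
            tails <- function(n) if (n == 0L) "" else
                apply(expand.grid(rep(list(c("A", "T")), n)), 1, paste, collapse = "")
            for (j in seq_len(nrow(g))) {
                t5 <- tails(core5[j]); t3 <- tails(core3[j])
                combo <- expand.grid(t5 = t5, t3 = t3, stringsAsFactors = FALSE)
                out[[j]] <- data.frame(
                    variantSeq = paste0(combo$t5, base[j], combo$t3),
                    mirna_id = id, e5 = g$e5[j], e3 = g$e3[j],
                    stringsAsFactors = FALSE)
            }
            rows[[i]] <- do.call(rbind, out)
        }
    }
    long <- do.call(rbind, rows)
    if (is.null(long) || nrow(long) == 0) {
        return(methods::new("IsomirSpace",
            sequences = Biostrings::DNAStringSet(),
            variants = S4Vectors::DataFrame(
                variant_id = character(), sequence = character(),
                canonical_parent = character(), e5 = integer(),
                e3 = integer(), n_parents = integer(),
                min_offset = integer(), ambiguous = logical()),
            parents = S4Vectors::DataFrame(
                variant_id = character(), mirna_id = character(),
                e5 = integer(), e3 = integer()),
            params = params))
    }
    # drop duplicate (sequence, mirna, e5, e3) annotations (possible when a
    # repeat within one hairpin yields the same slice twice in AU mode)
    long <- unique(long)
    # collapse identical sequences; deterministic order by sequence
    seqLevels <- sort(unique(long$variantSeq))
    long$seqIdx <- match(long$variantSeq, seqLevels)
    ord <- order(long$seqIdx, long$mirna_id, abs(long$e5) + abs(long$e3),
                 long$e5, long$e3)
    long <- long[ord, , drop = FALSE]

    # canonical parent = lexicographically smallest parent mirna_id; its
    # annotation with the smallest |e5|+|e3| names the variant
    first <- !duplicated(long$seqIdx)
    canon <- long[first, , drop = FALSE]
    nPar <- tabulate(long$seqIdx, nbins = length(seqLevels))
    minOff <- vapply(split(abs(long$e5) + abs(long$e3), long$seqIdx),
                     min, numeric(1))
    nDistinctParents <- vapply(split(long$mirna_id, long$seqIdx),
                               function(x) length(unique(x)), integer(1))

    variantId <- sprintf("%s|e5:%+d|e3:%+d", canon$mirna_id, canon$e5, canon$e3)
    if (anyDuplicated(variantId)) {
        # same canonical annotation can label two different sequences only in
        # nontemplated_AU mode (different tails); disambiguate by tail
        dup <- duplicated(variantId) | duplicated(variantId, fromLast = TRUE)
        variantId[dup] <- paste0(variantId[dup], "|seq:", canon$variantSeq[dup])
    }

    variants <- S4Vectors::DataFrame(
        variant_id = variantId,
        sequence = seqLevels,
        canonical_parent = canon$mirna_id,
        e5 = canon$e5,
        e3 = canon$e3,
        n_parents = nPar,
        min_offset = as.integer(minOff),
        ambiguous = nDistinctParents > 1L
    )
    parents <- S4Vectors::DataFrame(
        variant_id = variantId[long$seqIdx],
        mirna_id = long$mirna_id,
        e5 = long$e5,
        e3 = long$e3
    )
    seqs <- Biostrings::DNAStringSet(seqLevels)
    names(seqs) <- variantId
    methods::new("IsomirSpace", sequences = seqs, variants = variants,
                 parents = parents, params = params)
}

#' Write an isomiR space to FASTA + annotation TSV
#'
#' @param space an \code{IsomirSpace}.
#' @param fastaPath output FASTA (headers are variant ids).
#' @param tsvPath output TSV with one row per (variant, parent) annotation
#'   plus the canonical parent.
#' @return invisibly, the two paths.
#' @export
writeIsomirSpace <- function(space, fastaPath, tsvPath) {
    Biostrings::writeXStringSet(space@sequences, fastaPath)
    p <- as.data.frame(space@parents)
    v <- as.data.frame(space@variants)
    p$sequence <- v$sequence[match(p$variant_id, v$variant_id)]
    p$canonical_parent <- v$canonical_parent[match(p$variant_id, v$variant_id)]
    writeTsv(p[, c("variant_id", "sequence", "mirna_id", "e5", "e3",
                   "canonical_parent")], tsvPath)
    invisible(c(fastaPath, tsvPath))
}
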