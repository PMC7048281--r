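#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet width
NULL

#' Mature/hairpin miRNA reference
#'
#' Holds a set of mature miRNA sequences together with their precursor
#' (hairpin) sequences and the location of each mature within its hairpin.
#' Sequences are stored in the DNA alphabet (U is normalized to T on input)
#' so that FASTQ reads and FASTA references compare directly.  Coordinates
#' are 0-based half-open: \code{hairpin[start:end] == mature}.
#'
#' @slot mature \code{DNAStringSet} of mature sequences, named by miRNA id.
#' @slot hairpin \code{DNAStringSet} of hairpin sequences, named by hairpin id.
#' @slot matureAnno \code{DataFrame} with columns \code{mirna_id},
#'   \code{name}, \code{hairpin_id}, \code{start}, \code{end}.
#'
#' @seealso \code{\link{loadMirnaReference}}, \code{\link{enumerateIsomirSpace}}
#' @export
setClass("IsomirReference",
    slots = c(
        mature = "DNAStringSet",
        hairpin = "DNAStringSet",
        matureAnno = "DataFrame"
    )
)

setValidity("IsomirReference", function(object) {
    msg <- character()
    anno <- object@matureAnno
    need <- c("mirna_id", "name", "hairpin_id", "start", "end")
    if (!all(need %in% colnames(anno)))
        return(paste("matureAnno must have columns:", paste(need, collapse = ", ")))
    if (length(object@mature) != nrow(anno))
        msg <- c(msg, "mature and matureAnno have different lengths")
    if (anyDuplicated(anno$mirna_id))
        msg <- c(msg, "duplicated mirna_id in matureAnno")
    if (nrow(anno) > 0) {
        if (!all(anno$hairpin_id %in% names(object@hairpin)))
            msg <- c(msg, "matureAnno references unknown hairpin_id")
        hlen <- width(object@hairpin)[match(anno$hairpin_id, names(object@hairpin))]
        if (any(anno$end > hlen))
            msg <- c(msg, "mature end coordinate exceeds hairpin length")
        # 0-based half-open: the slice must reproduce the mature exactly
        sl <- substr(as.character(object@hairpin[anno$hairpin_id]),
                     anno$start + 1L, anno$end)
        if (!all(sl == as.character(object@mature)))
            msg <- c(msg, "hairpin[start:end] does not reproduce the mature sequence")
        wl <- width(object@mature)
        if (any(wl < 16L | wl > 30L))
            msg <- c(msg, "mature lengths must be in [16, 30]")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Enumerated isomiR sequence space
#'
#' The mapping reference used for read assignment: every sequence reachable
#' from a canonical mature miRNA by trimming up to \code{maxTrim} nt or
#' adding up to \code{maxAdd} templated nt at the 5' and/or 3' end, pruned
#' at \code{minLen}.  Identical sequences arising from different
#' (miRNA, e5, e3) origins are collapsed into a single variant carrying all
#' parent annotations.
#'
#' @slot sequences \code{DNAStringSet} of unique variant sequences, named by
#'   \code{variant_id}, ordered by sequence.
#' @slot variants \code{DataFrame}: one row per variant
#'   (\code{variant_id}, \code{sequence}, \code{canonical_parent},
#'   \code{e5}, \code{e3} of the canonical annotation, \code{n_parents},
#'   \code{min_offset}, \code{ambiguous}).
#' @slot parents \code{DataFrame} in long form: one row per
#'   (variant, parent) annotation with columns \code{variant_id},
#'   \code{mirna_id}, \code{e5}, \code{e3}.  Negative offsets are trimmed
#'   bases, positive offsets are templated additions.
#' @slot params the \code{\link{isomirParams}} list used for enumeration.
#'
#' @export
setClass("IsomirSpace",
    slots = c(
        sequences = "DNAStringSet",
        variants = "DataFrame",
        parents = "DataFrame",
        params = "list"
    )
)

setValidity("IsomirSpace", function(object) {
    msg <- character()
    v <- object@variants
    if (length(object@sequences) != nrow(v))
        msg <- c(msg, "sequences and variants have different lengths")
    if (anyDuplicated(as.character(object@sequences)))
        msg <- c(msg, "variant sequences are not unique")
    if (anyDuplicated(v$variant_id))
        msg <- c(msg, "variant_id values are not unique")
    p <- object@parents
    if (nrow(p) > 0 && !all(p$variant_id %in% v$variant_id))
        msg <- c(msg, "parents reference unknown variant_id")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Exact / one-mismatch sequence match index
#'
#' Hash index over a set of unique equal-alphabet sequences supporting O(1)
#' expected exact lookup and complete Hamming-distance-1 lookup per query
#' length, via the split-half trick: a single substitution leaves at least
#' one half of the query intact, so candidates are collected from exact
#' half-matches and verified.
#'
#' @slot sequences character vector of indexed sequences.
#' @slot exact environment mapping sequence -> index.
#' @slot halves environment mapping (side, width, half-sequence) -> indices.
#' @slot widths sorted unique sequence widths present in the index.
#'
#' @seealso \code{\link{buildMatchIndex}}
#' @export
setClass("MatchIndex",
    slots = c(
        sequences = "character",
        exact = "environment",
        halves = "environment",
        widths = "integer"
    )
)

setMethod("show", "IsomirReference", function(object) {
    cat("IsomirReference with", length(object@mature), "mature miRNAs and",
        length(object@hairpin), "hairpins\n")
    if (length(object@mature)) {
        w <- width(object@mature)
        cat("  mature length range:", min(w), "-", max(w), "nt\n")
    }
})

setMethod("show", "IsomirSpace", function(object) {
    p <- object@params
    cat("IsomirSpace with", length(object@sequences), "unique variants",
        sprintf("(maxTrim=%d, maxAdd=%d, minLen=%d, %s additions)\n",
                p$maxTrim, p$maxAdd, p$minLen, p$additionMode))
    cat("  parent annotations:", nrow(object@parents), "\n")
})

setMethod("show", "MatchIndex", function(object) {
    cat("MatchIndex over", length(object@sequences), "sequences;",
        "widths:", paste(object@widths, collapse = ", "), "\n")
})

#' @rdname IsomirReference-class
#' @param object,x an \code{IsomirReference}
#' @export
setGeneric("matureSequences", function(x) standardGeneric("matureSequences"))

#' @rdname IsomirReference-class
#' @export
setMethod("matureSequences", "IsomirReference", function(x) x@mature)

#' @rdname IsomirReference-class
#' @export
setGeneric("hairpinSequences", function(x) standardGeneric("hairpinSequences"))

#' @rdname IsomirReference-class
#' @export
setMethod("hairpinSequences", "IsomirReference", function(x) x@hairpin)

#' @rdname IsomirReference-class
#' @export
setGeneric("matureAnnotation", function(x) standardGeneric("matureAnnotation"))

#' @rdname IsomirReference-class
#' @export
setMethod("matureAnnotation", "IsomirReference", function(x) x@matureAnno)

#' @rdname IsomirSpace-class
#' @param x an \code{IsomirSpace}
#' @export
setGeneric("variantSequences", function(x) standardGeneric("variantSequences"))

#' @rdname IsomirSpace-class
#' @export
setMethod("variantSequences", "IsomirSpace", function(x) x@sequences)

#' @rdname IsomirSpace-class
#' @export
setGeneric("variantAnnotation", function(x) standardGeneric("variantAnnotation"))

#' @rdname IsomirSpace-class
#' @export
setMethod("variantAnnotation", "IsomirSpace", function(x) x@variants)

#' @rdname IsomirSpace-class
#' @export
setGeneric("parentAnnotation", function(x) standardGeneric("parentAnnotation"))

#' @rdname IsomirSpace-class
#' @export
setMethod("parentAnnotation", "IsomirSpace", function(x) x@parents)
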