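#' Build an exact / one-mismatch match index
#'
#' Indexes a set of unique sequences for exact lookup and for complete
#' Hamming-distance-1 lookup among indexed sequences of the same length.
#' The distance-1 search uses the split-half trick: a single substitution
#' leaves at least one half of the query intact, so candidates are read off
#' two exact half-lookups and verified, which bounds the candidate set
#' without scanning the whole reference.
#'
#' @param sequences character vector or \code{DNAStringSet} of sequences to
#'   index; must be unique (duplicates are a contract violation upstream and
#'   raise an error).
#' @return a \code{\link[=MatchIndex-class]{MatchIndex}}.
#' @examples
#' idx <- buildMatchIndex(c("ACGTACGT", "ACGTACGA", "TTTTTTTT"))
#' exactLookup(idx, "ACGTACGA")
#' hamming1Lookup(idx, "ACGTACGG")  # both 8-mers at distance 1
#' @export
buildMatchIndex <- function(sequences) {
    seqs <- as.character(sequences)
    names(seqs) <- NULL
    if (anyDuplicated(seqs))
        stop("duplicate sequences passed to buildMatchIndex; ",
             "the variant space must be deduplicated", call. = FALSE)
    exact <- new.env(hash = TRUE, parent = emptyenv(),
                     size = max(1L, length(seqs)))
    halves <- new.env(hash = TRUE, parent = emptyenv(),
                      size = max(1L, 2L * length(seqs)))
    w <- nchar(seqs)
    hw <- w %/% 2L
    keyA <- paste0("A", w, ":", substr(seqs, 1L, hw))
    keyB <- paste0("B", w, ":", substr(seqs, hw + 1L, w))
    for (i in seq_along(seqs)) {
        assign(seqs[i], i, envir = exact)
        halves[[keyA[i]]] <- c(halves[[keyA[i]]], i)
        halves[[keyB[i]]] <- c(halves[[keyB[i]]], i)
    }
    methods::new("MatchIndex", sequences = seqs, exact = exact,
                 halves = halves, widths = sort(unique(as.integer(w))))
}

#' @describeIn buildMatchIndex Exact lookup; returns the index of each query
#'   in the indexed set, or \code{NA} when absent.
#' @param index a \code{MatchIndex}.
#' @param queries character vector of query sequences.
#' @export
exactLookup <- function(index, queries) {
    if (length(queries) == 0) return(integer(0))
    hits <- mget(queries, envir = index@exact, ifnotfound = list(NA_integer_))
    unname(vapply(hits, `[`, integer(1), 1L))
}

#' @describeIn buildMatchIndex All indexed sequences at Hamming distance
#'   exactly 1 from the (single) query, restricted to equal length; returns
#'   an integer vector of indices (possibly empty).
#' @param query a single query sequence.
#' @export
hamming1Lookup <- function(index, query) {
    w <- nchar(query)
    if (!(w %in% index@widths)) return(integer(0))
    hw <- w %/% 2L
    cand <- unique(c(
        index@halves[[paste0("A", w, ":", substr(query, 1L, hw))]],
        index@halves[[paste0("B", w, ":", substr(query, hw + 1L, w))]]
    ))
    if (is.null(cand)) return(integer(0))
    qi <- utf8ToInt(query)
    keep <- vapply(cand, function(i)
        sum(qi != utf8ToInt(index@sequences[i])) == 1L, logical(1))
    as.integer(sort(unname(cand[keep])))
}
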