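# Shared low-level helpers.

# Hamming distance between two equal-length strings.
hammingDist <- function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
}

# Positions (1-based) where two equal-length strings differ.
mismatchPositions <- function(a, b) {
    which(utf8ToInt(a) != utf8ToInt(b))
}

# Normalize a character vector of sequences to the uppercase DNA alphabet
# (U -> T); errors (naming the offending record) on anything outside ACGT.
normalizeDna <- function(x, what = "sequence") {
    x <- chartr("acgtuU", "ACGTTT", x)
    bad <- grepl("[^ACGT]", x)
    if (any(bad)) {
        nm <- names(x)[bad]
        if (is.null(nm)) nm <- which(bad)
        stop("invalid ", what, " alphabet (non-ACGU/T character) in: ",
             paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
    }
    x
}

# Draw random DNA of the given widths (one string per width entry).
randomDna <- function(widths) {
    vapply(widths, function(w) {
        paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
    }, character(1))
}

# Apply per-base substitution errors at rate `rate` to a character vector of
# sequences; substitutions are drawn uniformly from the three other bases.
mutateSequences <- function(seqs, rate) {
    if (rate <= 0 || length(seqs) == 0) return(seqs)
    widths <- nchar(seqs)
    nerr <- stats::rbinom(length(seqs), widths, rate)
    idx <- which(nerr > 0)
    for (i in idx) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(widths[i], nerr[i])
        for (p in pos) {
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
        seqs[i] <- paste(chars, collapse = "")
    }
    seqs
}

# write.table with the conventions used for every TSV the package emits
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      quote = "", comment.char = "", ...)
}
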