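# Read classes, in classification priority order; every raw read receives
# exactly one terminal class.
READ_CLASSES <- c("NO_ADAPTOR", "SHORT", "RRNA", "TRNA", "SNRNA", "SNORNA",
                  "MAPPED", "UNMAPPED")
CONTAMINANT_CLASSES <- c("RRNA", "TRNA", "SNRNA", "SNORNA")

#' Preprocessing parameters
#'
#' @param adapter 3' adapter sequence (DNA alphabet).  The default is the
#'   NEB/Illumina small RNA 3' adapter.
#' @param minOverlap minimum 3'-terminal adapter overlap (default 6 nt).
#' @param maxAdapterMismatch mismatches tolerated in the 3'-terminal overlap
#'   (default 1).
#' @param minLen minimum insert length retained (default 16 nt); shorter
#'   inserts are classified \code{SHORT} and excluded.
#' @param contaminantMaxMismatch mismatches tolerated when matching an
#'   insert inside a contaminant sequence (default 1).
#' @return a validated parameter list.
#' @export
preprocessParams <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                             minOverlap = 6L, maxAdapterMismatch = 1L,
                             minLen = 16L, contaminantMaxMismatch = 1L) {
    adapter <- normalizeDna(adapter, what = "adapter")
    minOverlap <- as.integer(minOverlap)
    minLen <- as.integer(minLen)
    stopifnot(nchar(adapter) >= 1L, minOverlap >= 1L, minLen >= 1L,
              maxAdapterMismatch >= 0L, contaminantMaxMismatch >= 0L)
    list(adapter = adapter, minOverlap = minOverlap,
         maxAdapterMismatch = as.integer(maxAdapterMismatch),
         minLen = minLen,
         contaminantMaxMismatch = as.integer(contaminantMaxMismatch))
}

#' Trim the 3' adapter from reads
#'
#' Two-stage rule: (i) an exact occurrence of the adapter's first 10 nt
#' (or the whole adapter when shorter) anywhere in the read, leftmost
#' occurrence wins; else (ii) a 3'-terminal overlap of at least
#' \code{minOverlap} bases between the read suffix and the adapter prefix
#' with at most \code{maxAdapterMismatch} mismatches, leftmost qualifying
#' position wins.  The insert is everything 5' of the adapter start.  Reads
#' with no qualifying occurrence are flagged no-adaptor (a classification,
#' not an error).
#'
#' @param reads character vector of read sequences.
#' @param params a \code{\link{preprocessParams}} list.
#' @return list with \code{insert} (character; \code{NA} where no adapter
#'   was found) and \code{noAdaptor} (logical).
#' @export
trimAdapter <- function(reads, params = preprocessParams()) {
    n <- length(reads)
    insert <- rep(NA_character_, n)
    if (n == 0) return(list(insert = insert, noAdaptor = logical(0)))
    ad <- params$adapter
    seed <- substr(ad, 1L, min(10L, nchar(ad)))
    pos <- regexpr(seed, reads, fixed = TRUE)
    hit <- pos > 0L
    insert[hit] <- substr(reads[hit], 1L, pos[hit] - 1L)
    # stage (ii): 3'-terminal overlap scan for the remainder
    adInt <- utf8ToInt(ad)
    for (i in which(!hit)) {
        r <- reads[i]
        w <- nchar(r)
        ri <- utf8ToInt(r)
        pmin_ <- max(1L, w - nchar(ad) + 1L) # overlap cannot exceed adapter
        pmax_ <- w - params$minOverlap + 1L
        if (pmax_ < pmin_) next
        for (p in pmin_:pmax_) {
            ov <- w - p + 1L
            if (sum(ri[p:w] != adInt[1:ov]) <= params$maxAdapterMismatch) {
                insert[i] <- substr(r, 1L, p - 1L)
                break
            }
        }
    }
    list(insert = insert, noAdaptor = is.na(insert))
}

#' Build a contaminant match index
#'
#' Expands every contaminant sequence into all windows of the insert-length
#' range and indexes them per class for exact/one-mismatch containment
#' queries: an insert is a contaminant hit iff some window of some sequence
#' of the class is within Hamming distance
#' \code{contaminantMaxMismatch} of it.
#'
#' @param contaminants named list of character vectors (or
#'   \code{DNAStringSet}s), one element per class; names are matched
#'   case-insensitively against rRNA/tRNA/snRNA/snoRNA.  Alternatively a
#'   single FASTA path whose headers carry the class as a prefix
#'   (\code{rRNA|...}, \code{tRNA_...}).
#' @param minLen,maxLen insert-length range to index (defaults 16 and 50).
#' @return named list of \code{MatchIndex} objects in fixed priority order
#'   (rRNA, tRNA, snRNA, snoRNA); classes with no sequences are dropped.
#' @export
buildContaminantIndex <- function(contaminants, minLen = 16L, maxLen = 50L) {
    if (is.character(contaminants) && length(contaminants) == 1)
        contaminants <- loadContaminants(contaminants)
    names(contaminants) <- normalizeClassNames(names(contaminants))
    out <- list()
    for (cls in CONTAMINANT_CLASSES) {
        if (!cls %in% names(contaminants)) next
        seqs <- normalizeDna(as.character(contaminants[[cls]]),
                             what = paste(cls, "contaminant"))
        if (length(seqs) == 0) next
        wins <- character(0)
        for (s in seqs) {
            w <- nchar(s)
            for (l in minLen:min(maxLen, w)) {
                wins <- c(wins, substring(s, 1:(w - l + 1L), l:w))
            }
        }
        out[[cls]] <- buildMatchIndex(unique(wins))
    }
    out
}

#' Load a contaminant FASTA with class-prefixed headers
#'
#' Headers must start with the class name (rRNA/tRNA/snRNA/snoRNA) followed
#' by a separator (\code{|}, \code{_}, \code{:} or \code{-}).
#'
#' @param path FASTA path.
#' @return named list of character vectors, one per class present.
#' @export
loadContaminants <- function(path) {
    seqs <- readFastaDna(path, what = "contaminant")
    cls <- normalizeClassNames(sub("[|_:-].*$", "", names(seqs)))
    bad <- is.na(cls)
    if (any(bad))
        stop("contaminant headers without a recognizable class prefix: ",
             paste(utils::head(names(seqs)[bad], 5), collapse = ", "),
             call. = FALSE)
    split(unname(seqs), cls)
}

normalizeClassNames <- function(x) {
    up <- toupper(x)
    out <- rep(NA_character_, length(x))
    out[up %in% c("RRNA")] <- "RRNA"
    out[up %in% c("TRNA")] <- "TRNA"
    out[up %in% c("SNRNA")] <- "SNRNA"
    out[up %in% c("SNORNA")] <- "SNORNA"
    out
}

# contaminant containment test for a vector of unique inserts against one
# class index; exact window hit or Hamming-1 window hit
isContaminant <- function(inserts, classIndex, maxMismatch = 1L) {
    hit <- !is.na(exactLookup(classIndex, inserts))
    if (maxMismatch >= 1L) {
        todo <- which(!hit)
        for (i in todo) {
            if (length(hamming1Lookup(classIndex, inserts[i])) > 0)
                hit[i] <- TRUE
        }
    }
    hit
}

#' Classify and filter a library of raw reads
#'
#' Runs the full preprocessing contract per read, in fixed priority order:
#' no-adaptor, short (insert < \code{minLen}), contaminant classes (rRNA,
#' tRNA, snRNA, snoRNA; first class containing the insert as a substring
#' with at most one mismatch wins), else retained for miRNA/isomiR mapping.
#' Classification is deterministic; qualities are carried but never used.
#'
#' @param reads character vector (or \code{DNAStringSet}) of raw read
#'   sequences.
#' @param contaminantIndex result of \code{\link{buildContaminantIndex}}
#'   (may be an empty list: no contaminant classes assigned).
#' @param params a \code{\link{preprocessParams}} list.
#' @return list with \code{class} (character, one of the read classes per
#'   read; retained reads are marked \code{"RETAINED"} until mapping
#'   resolves them to MAPPED/UNMAPPED), \code{insert} (trimmed insert or
#'   \code{NA}), and \code{retained} (character vector of retained inserts,
#'   multiplicities preserved).
#' @export
classifyReads <- function(reads, contaminantIndex = list(),
                          params = preprocessParams()) {
    reads <- toupper(as.character(reads))
    n <- length(reads)
    cls <- rep("RETAINED", n)
    tr <- trimAdapter(reads, params)
    cls[tr$noAdaptor] <- "NO_ADAPTOR"
    short <- !tr$noAdaptor & nchar(tr$insert) < params$minLen
    cls[short] <- "SHORT"
    open <- which(cls == "RETAINED")
    if (length(open) > 0 && length(contaminantIndex) > 0) {
        uniq <- unique(tr$insert[open])
        ucls <- rep(NA_character_, length(uniq))
        todo <- rep(TRUE, length(uniq))
        for (cname in intersect(CONTAMINANT_CLASSES, names(contaminantIndex))) {
            if (!any(todo)) break
            hit <- isContaminant(uniq[todo], contaminantIndex[[cname]],
                                 params$contaminantMaxMismatch)
            ucls[todo][hit] <- cname
            todo[todo] <- !hit
        }
        m <- ucls[match(tr$insert[open], uniq)]
        cls[open[!is.na(m)]] <- m[!is.na(m)]
    }
    retained <- tr$insert[cls == "RETAINED"]
    list(class = cls, insert = tr$insert, retained = retained)
}

#' Per-sample class counts from preprocessing + mapping
#'
#' @param class character vector of per-read classes where retained reads
#'   have been resolved to \code{MAPPED}/\code{UNMAPPED} (see
#'   \code{\link{quantifyLibrary}}).
#' @return named integer vector over all eight read classes; sums to the
#'   raw read count (the classes partition the library).
#' @export
classCounts <- function(class) {
    bad <- setdiff(unique(class), READ_CLASSES)
    if (length(bad) > 0)
        stop("unknown read class label(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    table(factor(class, levels = READ_CLASSES))
}

#' Read a FASTQ file into sequences (+ ids)
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet(format = "fastq")};
#' gzipped input is handled transparently.  Qualities are not loaded: the
#' pipeline carries but never interprets them.
#'
#' @param path FASTQ(.gz) path.
#' @return named character vector of read sequences (names are read ids).
#' @export
readFastqSequences <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    out
}
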