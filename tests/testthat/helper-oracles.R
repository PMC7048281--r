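# Independent brute-force oracles and small fixture builders shared across
# the suite.  Oracles are written against the contracts, not against the
# package internals.

# Brute-force isomiR enumeration: walk every (5' offset, 3' offset) pair
# explicitly as substring coordinates on the hairpin and collect the
# resulting sequences.  Returns the sorted unique sequence set.
oracleEnumerate <- function(hairpin, start, end, maxTrim = 6, maxAdd = 3,
                            minLen = 16) {
    out <- character(0)
    for (ns in (start - maxAdd):(start + maxTrim)) {
        for (ne in (end - maxTrim):(end + maxAdd)) {
            if (ns < 0 || ne > nchar(hairpin)) next
            if (ne - ns < minLen) next
            out <- c(out, substr(hairpin, ns + 1, ne))
        }
    }
    sort(unique(out))
}

# Brute-force best-stratum read assignment: scan every variant, compute the
# Hamming distance (equal lengths only), and apply the contract tie-break
# (best stratum; then smallest min |e5|+|e3| over parents; then smallest
# variant id).  Returns the chosen variant_id or NA.
oracleAssign <- function(query, space) {
    v <- as.data.frame(variantAnnotation(space))
    seqs <- as.character(v$sequence)
    same <- nchar(seqs) == nchar(query)
    if (!any(same)) return(NA_character_)
    qi <- utf8ToInt(query)
    d <- vapply(which(same), function(i)
        sum(qi != utf8ToInt(seqs[i])), integer(1))
    idx <- which(same)
    best <- min(d)
    if (best > 1) return(NA_character_)
    cand <- idx[d == best]
    ord <- order(v$min_offset[cand], v$variant_id[cand])
    v$variant_id[cand[ord][1]]
}

# Brute-force upper-tail hypergeometric p-value by direct combinatorics:
# P(overlap >= k) for a query of size n against a pathway of size K in a
# universe of size N.
oracleHyperTail <- function(k, K, n, N) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Textbook Benjamini-Hochberg step-up: sort ascending, q_i = p_i * n / i,
# enforce monotonicity from the largest rank down.
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

# A toy let-7-style reference: one 22-nt mature with 5-nt flanks on both
# sides of its hairpin (start 5, end 27 in 0-based half-open coordinates).
toyReferenceFiles <- function(dir = tempfile("toyref")) {
    dir.create(dir, showWarnings = FALSE)
    mature <- "UGAGGUAGUAGGUUGUAUAGUU"
    hairpin <- paste0("AAGGC", mature, "UCCGA")
    matPath <- file.path(dir, "mature.fa")
    hpPath <- file.path(dir, "hairpin.fa")
    writeLines(c(">toy-miR-1", mature), matPath)
    writeLines(c(">toy-mir-1", hairpin), hpPath)
    list(mature = matPath, hairpin = hpPath, matureSeq = mature,
         hairpinSeq = hairpin, start = 5L, end = 27L)
}

# Random reference fixture with generous flanks, built directly (not via
# simulateReference) so reference-builder tests do not depend on the
# simulator.
randomReferenceFixture <- function(nMirnas = 5, seed = 1) {
    set.seed(seed)
    ids <- sprintf("fix-miR-%02d", seq_len(nMirnas))
    hpIds <- sprintf("fix-mir-%02d", seq_len(nMirnas))
    matLen <- sample(20:23, nMirnas, replace = TRUE)
    hpLen <- matLen + sample(20:30, nMirnas, replace = TRUE)
    starts <- integer(nMirnas)
    matures <- hairpins <- character(nMirnas)
    for (i in seq_len(nMirnas)) {
        hairpins[i] <- paste(sample(c("A", "C", "G", "T"), hpLen[i],
                                    replace = TRUE), collapse = "")
        starts[i] <- sample(8:(hpLen[i] - matLen[i] - 8L), 1L)
        matures[i] <- substr(hairpins[i], starts[i] + 1L,
                             starts[i] + matLen[i])
    }
    dir <- tempfile("fixref")
    dir.create(dir)
    matPath <- file.path(dir, "mature.fa")
    hpPath <- file.path(dir, "hairpin.fa")
    writeLines(as.vector(rbind(paste0(">", ids), matures)), matPath)
    writeLines(as.vector(rbind(paste0(">", hpIds), hairpins)), hpPath)
    list(mature = matPath, hairpin = hpPath, ids = ids, hpIds = hpIds,
         matures = matures, hairpins = hairpins, starts = starts,
         ends = starts + matLen)
}

# NB count matrix simulator for DE tests (matrix level, no reads).
simulateNbMatrix <- function(nFeatures, mu, dispersion, nPerGroup = 3,
                             lfc = rep(0, nFeatures)) {
    gA <- sapply(seq_len(nPerGroup), function(j)
        rnbinom(nFeatures, mu = mu, size = 1 / dispersion))
    gB <- sapply(seq_len(nPerGroup), function(j)
        rnbinom(nFeatures, mu = mu * 2^lfc, size = 1 / dispersion))
    m <- cbind(gA, gB)
    rownames(m) <- sprintf("f%05d", seq_len(nFeatures))
    colnames(m) <- c(paste0("A", seq_len(nPerGroup)),
                     paste0("B", seq_len(nPerGroup)))
    m
}
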