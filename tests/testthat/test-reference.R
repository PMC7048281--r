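test_that("loading a mature/hairpin pair records coordinates and normalizes U to T", {
    toy <- toyReferenceFiles()
    ref <- loadMirnaReference(toy$mature, toy$hairpin)
    anno <- as.data.frame(matureAnnotation(ref))
    expect_equal(anno$start, 5L)
    expect_equal(anno$end, 27L)
    expect_equal(anno$hairpin_id, "toy-mir-1")
    expect_equal(as.character(matureSequences(ref)),
                 c(`toy-miR-1` = chartr("U", "T", toy$matureSeq)))
    # invariant: the hairpin slice reproduces the mature
    hp <- as.character(hairpinSequences(ref))[[anno$hairpin_id]]
    expect_equal(substr(hp, anno$start + 1, anno$end),
                 as.character(matureSequences(ref))[[1]])
})

test_that("reference loading edge cases behave per contract", {
    toy <- toyReferenceFiles()
    # empty mature FASTA -> empty reference, no error
    empty <- tempfile(fileext = ".fa"); file.create(empty)
    ref <- loadMirnaReference(empty, toy$hairpin)
    expect_equal(length(matureSequences(ref)), 0L)

    # 'N' in a mature -> validation error naming the record
    badMat <- tempfile(fileext = ".fa")
    writeLines(c(">bad-miR-1", "UGAGGUAGUAGGUUGUAUAGNU"), badMat)
    expect_error(loadMirnaReference(badMat, toy$hairpin), "bad-miR-1")

    # mature not found in any hairpin -> hard error naming it
    orphan <- tempfile(fileext = ".fa")
    writeLines(c(">lost-miR-9", "ACGTACGTACGTACGTACGT"), orphan)
    expect_error(loadMirnaReference(orphan, toy$hairpin), "lost-miR-9")

    # mature in multiple hairpins with no declared link -> ambiguity error
    hp2 <- tempfile(fileext = ".fa")
    writeLines(c(">hpA", paste0("AAGGC", toy$matureSeq, "UCCGA"),
                 ">hpB", paste0("CCTTG", toy$matureSeq, "AGGCU")), hp2)
    amb <- tempfile(fileext = ".fa")
    writeLines(c(">amb-miR-1", toy$matureSeq), amb)
    expect_error(loadMirnaReference(amb, hp2), "multiple hairpins")
    # ...but a declared link resolves it
    ref2 <- loadMirnaReference(amb, hp2,
        linkMap = data.frame(mirna_id = "amb-miR-1", hairpin_id = "hpB"))
    expect_equal(as.data.frame(matureAnnotation(ref2))$hairpin_id, "hpB")
})

test_that("a full-flank 22-nt mature yields the 79-variant grid", {
    toy <- toyReferenceFiles()
    ref <- loadMirnaReference(toy$mature, toy$hairpin)
    space <- enumerateIsomirSpace(ref, isomirParams())
    # oracle: brute-force coordinate walk (all window sequences are distinct
    # here, so the dedup rule removes nothing)
    hp <- chartr("U", "T", toy$hairpinSeq)
    expected <- oracleEnumerate(hp, 5, 27, maxTrim = 6, maxAdd = 3,
                                minLen = 16)
    expect_equal(as.character(variantAnnotation(space)$sequence), expected)
    expect_equal(length(variantSequences(space)), 79L)
    # flanks are 5 nt, so only additions up to 3 are reachable and the
    # 100-pair grid loses the 21 pairs shorter than 16 nt
    p <- as.data.frame(parentAnnotation(space))
    expect_true(all(p$e5 >= -6 & p$e5 <= 3 & p$e3 >= -6 & p$e3 <= 3))
    expect_true(all(nchar(as.character(variantAnnotation(space)$sequence)) >= 16))
})

test_that("enumeration matches the brute-force oracle on random references", {
    fix <- randomReferenceFixture(nMirnas = 8, seed = 21)
    ref <- loadMirnaReference(fix$mature, fix$hairpin)
    space <- enumerateIsomirSpace(ref)
    anno <- as.data.frame(matureAnnotation(ref))
    expected <- sort(unique(unlist(lapply(seq_len(nrow(anno)), function(i) {
        hp <- as.character(hairpinSequences(ref))[[anno$hairpin_id[i]]]
        oracleEnumerate(hp, anno$start[i], anno$end[i])
    }))))
    expect_equal(as.character(variantAnnotation(space)$sequence), expected)
})

test_that("variants are unique, reconstructible and (0,0) reproduces the mature", {
    fix <- randomReferenceFixture(nMirnas = 5, seed = 33)
    ref <- loadMirnaReference(fix$mature, fix$hairpin)
    space <- enumerateIsomirSpace(ref)
    v <- as.data.frame(variantAnnotation(space))
    p <- as.data.frame(parentAnnotation(space))
    expect_false(anyDuplicated(v$sequence) > 0)
    # round-trip: every (parent, e5, e3) annotation reconstructs the sequence
    anno <- as.data.frame(matureAnnotation(ref))
    hps <- as.character(hairpinSequences(ref))
    for (i in seq_len(nrow(p))) {
        a <- anno[anno$mirna_id == p$mirna_id[i], ]
        hp <- hps[[a$hairpin_id]]
        rec <- substr(hp, a$start - p$e5[i] + 1, a$end + p$e3[i])
        expect_equal(rec, v$sequence[v$variant_id == p$variant_id[i]])
    }
    # the canonical variant of each mature is present and exact
    can <- v$sequence[v$e5 == 0 & v$e3 == 0]
    expect_true(all(as.character(matureSequences(ref)) %in% can))
})

test_that("identity parameters and duplicated-locus collapse follow the dedup rule", {
    fix <- randomReferenceFixture(nMirnas = 4, seed = 7)
    ref <- loadMirnaReference(fix$mature, fix$hairpin)
    sp0 <- enumerateIsomirSpace(ref, isomirParams(maxTrim = 0, maxAdd = 0))
    expect_equal(length(variantSequences(sp0)), 4L)
    v0 <- as.data.frame(variantAnnotation(sp0))
    expect_true(all(v0$e5 == 0 & v0$e3 == 0))

    # duplicated locus: same mature in two hairpins collapses to one variant
    mat <- tempfile(fileext = ".fa"); hp <- tempfile(fileext = ".fa")
    seqA <- "TGAGGTAGTAGGTTGTATAGTT"
    writeLines(c(">dup-miR-2", seqA, ">dup-miR-1", seqA), mat)
    writeLines(c(">dup-mir-2", paste0("AAGGC", seqA, "TCCGA"),
                 ">dup-mir-1", paste0("GGCCA", seqA, "ATTGC")), hp)
    refD <- loadMirnaReference(mat, hp)
    spD <- enumerateIsomirSpace(refD, isomirParams(maxTrim = 0, maxAdd = 0))
    vD <- as.data.frame(variantAnnotation(spD))
    pD <- as.data.frame(parentAnnotation(spD))
    expect_equal(nrow(vD), 1L)
    expect_equal(sort(pD$mirna_id), c("dup-miR-1", "dup-miR-2"))
    expect_equal(vD$canonical_parent, "dup-miR-1") # lexicographically smaller
    expect_true(vD$ambiguous)
})

test_that("enumeration is monotone in maxTrim and maxAdd", {
    fix <- randomReferenceFixture(nMirnas = 3, seed = 11)
    ref <- loadMirnaReference(fix$mature, fix$hairpin)
    base <- as.character(variantAnnotation(
        enumerateIsomirSpace(ref, isomirParams(maxTrim = 3, maxAdd = 1)))$sequence)
    forTrim <- as.character(variantAnnotation(
        enumerateIsomirSpace(ref, isomirParams(maxTrim = 5, maxAdd = 1)))$sequence)
    forAdd <- as.character(variantAnnotation(
        enumerateIsomirSpace(ref, isomirParams(maxTrim = 3, maxAdd = 3)))$sequence)
    expect_true(all(base %in% forTrim))
    expect_true(all(base %in% forAdd))
})

test_that("nontemplated A/U tails are generated on request", {
    toy <- toyReferenceFiles()
    ref <- loadMirnaReference(toy$mature, toy$hairpin)
    sp <- enumerateIsomirSpace(ref, isomirParams(maxTrim = 0, maxAdd = 1,
        additionMode = "nontemplated_AU"))
    v <- as.data.frame(variantAnnotation(sp))
    mature <- chartr("U", "T", toy$matureSeq)
    # canonical + A/T tails on either end (5 distinct sequences at most)
    expect_true(mature %in% v$sequence)
    expect_true(paste0(mature, "A") %in% v$sequence)
    expect_true(paste0(mature, "T") %in% v$sequence)
    expect_true(paste0("A", mature) %in% v$sequence)
    expect_true(paste0("T", mature) %in% v$sequence)
})
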