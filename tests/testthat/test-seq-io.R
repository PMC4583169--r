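test_that("plain dialect loads pre-aligned lines and rejects ragged input", {
    f <- writeTempLines(c("ACGT", "ACGT"))
    ss <- readPlainSeqs(f)
    expect_s4_class(ss, "SequenceSet")
    expect_equal(nSequences(ss), 2L)
    expect_equal(seqWidth(ss), 4L)

    fr <- writeTempLines(c("ACGT", "ACG"))
    expect_error(readPlainSeqs(fr), "line 2")

    expect_error(readPlainSeqs(writeTempLines(character())), "no sequences")
    expect_error(readPlainSeqs(tempfile()), "not found")
})

test_that("plain dialect uppercases, strips gaps and masks non-ACGT as N", {
    f <- writeTempLines(c("ac-gt", "aXgt"))
    ss <- readPlainSeqs(f)
    expect_identical(sequences(ss), c("ACGT", "ANGT"))
})

test_that("fasta dialect center-aligns records about their midpoints", {
    f <- writeTempFasta(c("ACGTACGTAC", "ACGTACGTAC"))
    ss <- readFastaSeqs(f)
    expect_equal(seqWidth(ss), 10L)
    expect_identical(sequences(ss), rep("ACGTACGTAC", 2))

    # lengths 10 and 12: the longer record is trimmed to a 10-span about its
    # center (left-of-middle convention): TTAACCGGTTAA -> TAACCGGTTA
    f2 <- writeTempFasta(c("AACCGGTTAA", "TTAACCGGTTAA"))
    ss2 <- readFastaSeqs(f2)
    expect_identical(sequences(ss2), c("AACCGGTTAA", "TAACCGGTTA"))

    # gaps are stripped before alignment
    f3 <- writeTempFasta(c("AC-GT", "A.CGT"))
    expect_identical(sequences(readFastaSeqs(f3)), c("ACGT", "ACGT"))

    expect_error(readFastaSeqs(writeTempFasta(character())), "no FASTA")
})

test_that("jaspar dialect aligns on the uppercase motif and records its span", {
    f <- writeTempFasta(c("aaCGTGtt", "aCGTGttt"))
    ss <- readJasparSeqs(f)
    expect_identical(sequences(ss), rep("ACGTGTT", 2))
    expect_equal(unname(motifSpan(ss)), c(2L, 5L))
    # extracting the motif span recovers the uppercase substrings
    got <- substr(sequences(ss), motifSpan(ss)[1], motifSpan(ss)[2])
    expect_identical(got, rep("CGTG", 2))

    # identical records come through unchanged with the uppercase span
    f2 <- writeTempFasta(rep("ggttCACGTGaacc", 3))
    ss2 <- readJasparSeqs(f2)
    expect_identical(sequences(ss2), rep("GGTTCACGTGAACC", 3))
    expect_equal(unname(motifSpan(ss2)), c(5L, 10L))

    expect_error(readJasparSeqs(writeTempFasta("acgt")), "uppercase runs")
    expect_error(readJasparSeqs(writeTempFasta("aCGtaCGt")), "uppercase runs")
    expect_warning(readJasparSeqs(writeTempFasta(c("aaCGTGtt", "aaCGTGGtt"))),
                   "common span")
})

test_that("PWM files round-trip at full precision and reject bad columns", {
    ss <- SequenceSet(c("ACGT", "ACGA", "TCGA"))
    m <- baseFrequencies(logoProfile(ss))
    f <- tempfile(fileext = ".tsv")
    writePWM(m, f)
    back <- readPWM(f)
    expect_equal(unname(back), unname(m), tolerance = 1e-12)
    expect_identical(rownames(back), c("A", "C", "G", "T"))

    lsm <- linkageStateMatrix(ss)
    f2 <- tempfile(fileext = ".tsv")
    writePWM(lsm@p, f2)
    expect_equal(nrow(readPWM(f2)), 9L)

    badm <- matrix(c(0.5, 0.2, 0.1, 0.1), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    expect_error(writePWM(badm, f), "sum to 1")
})

test_that("sequence sets round-trip through all three output dialects", {
    ss <- generateTFBS(MotifSpec("CACGTG", conservation = 0.9, n = 8,
                                 flankLength = 5, seed = 3))
    for (fmt in c("plain", "fasta", "jaspar")) {
        f <- tempfile(fileext = if (fmt == "plain") ".txt" else ".fasta")
        writeSequenceSet(ss, f, fmt)
        back <- readSequenceSet(f, fmt)
        expect_identical(sequences(back), sequences(ss))
    }
    f <- tempfile(fileext = ".fasta")
    writeSequenceSet(ss, f, "jaspar")
    expect_equal(unname(motifSpan(readJasparSeqs(f))),
                 unname(motifSpan(ss)))
})

test_that("unknown filetype tags are rejected with the recognized values", {
    expect_error(readSequenceSet(tempfile(), "bam"),
                 "Recognized values.*plain, fasta, jaspar")
})
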