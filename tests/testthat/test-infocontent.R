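test_that("entropy and information content follow the bit-scale definitions", {
    expect_equal(shannonEntropy(c(1, 0, 0, 0)), 0)
    expect_equal(shannonEntropy(rep(0.25, 4)), 2)
    expect_equal(shannonEntropy(c(0.5, 0.5, 0, 0)), 1)
    expect_error(shannonEntropy(c(-0.1, 1.1)), "non-negative")

    expect_equal(informationContent(0, 4), 2)
    expect_equal(informationContent(0, 9), log2(9))
    expect_equal(informationContent(log2(9), 9), 0)
    expect_error(informationContent(2.1, 4), "log2")

    expect_equal(normalizeLinkageIC(log2(9)), 2)
    expect_equal(normalizeLinkageIC(0), 0)
    expect_equal(normalizeLinkageIC(log2(9) / 2), 1)
    expect_error(normalizeLinkageIC(3.5), "log2")
})

test_that("base PWM counts match direct enumeration and mask N", {
    p <- baseFrequencies(logoProfile(SequenceSet(c("AAA", "AAA", "AAA"))))
    expect_equal(unname(p["A", ]), c(1, 1, 1))

    p2 <- basePWM(SequenceSet(c("AT", "TA")))@p
    expect_equal(unname(p2["A", ]), c(0.5, 0.5))
    expect_equal(unname(p2["T", ]), c(0.5, 0.5))

    p3 <- basePWM(SequenceSet(c("ACGT", "ACGA")))@p
    expect_equal(unname(p3[, 4]), c(0.5, 0, 0, 0.5))

    bp <- basePWM(SequenceSet(c("ANGT", "ACGT")))
    expect_equal(bp@nEff[2], 1L)
    expect_equal(unname(bp@p["C", 2]), 1)
})

test_that("linkage states collapse strand-symmetric dimers and mask N dimers", {
    sc <- defaultTRXScale()
    # identical sequences: one state per linkage at frequency 1
    lsm <- linkageStateMatrix(SequenceSet(c("CATG", "CATG")), sc)
    expect_true(all(apply(lsm@p, 2, max) == 1))

    # reverse-complement dimers at a linkage collapse to one symbol:
    # a 10-state implementation would see entropy here
    mix <- SequenceSet(c("ACAT", "ATGT"))   # dimers CA and TG at linkage 2
    pr <- logoProfile(mix, sc)
    expect_equal(icLinkage(pr, normalized = FALSE)[2], log2(9))

    # the shared-score classes CpA/TpG and GpC merge into one symbol too
    shared <- SequenceSet(c("ACAT", "AGCT"))  # CA and GC at linkage 2
    pr2 <- logoProfile(shared, sc)
    expect_equal(icLinkage(pr2, normalized = FALSE)[2], log2(9))

    # N masks the two adjacent linkages but not the rest
    lsm2 <- linkageStateMatrix(SequenceSet(c("ANAT", "ACAT")), sc)
    expect_equal(lsm2@nEff, c(1L, 1L, 2L))
})

test_that("mean TRX profile averages dimer scores at each linkage", {
    sc <- defaultTRXScale()
    expect_equal(meanTRXProfile(SequenceSet(c("CG", "CG")), sc), 43)
    expect_equal(meanTRXProfile(SequenceSet(c("AT", "AT")), sc), 0)
    expect_equal(meanTRXProfile(SequenceSet(c("CG", "AT")), sc), 21.5)
    expect_true(is.na(meanTRXProfile(SequenceSet(c("AN", "NT")), sc)))
})

test_that("fully conserved sets hit the caps; uniform sets decay to zero", {
    pr <- logoProfile(SequenceSet(rep("CATGC", 10)))
    expect_equal(icBase(pr), rep(2, 5))
    expect_equal(icLinkage(pr), rep(2, 4))
    expect_equal(icLinkage(pr, normalized = FALSE), rep(log2(9), 4))

    # minimal two-column input: one linkage
    pr2 <- logoProfile(SequenceSet(c("AC", "AC")))
    expect_length(icBase(pr2), 2L)
    expect_length(icLinkage(pr2), 1L)

    # i.i.d. uniform sequences at large n: base IC within sampling error of 0
    set.seed(42)
    big <- SequenceSet(randomSeqStrings(10000, 6))
    expect_lt(max(icBase(logoProfile(big))), 0.01)
})

test_that("IC + H = log2(k) holds exactly at every position", {
    set.seed(11)
    for (r in 1:10) {
        ss <- SequenceSet(randomSeqStrings(sample(2:6, 1), sample(3:8, 1)))
        pr <- logoProfile(ss)
        expect_equal(icBase(pr) + pr@hBase, rep(2, pr@L), tolerance = 1e-12)
        lsm <- linkageStateMatrix(ss)
        H <- shannonEntropy(lsm@p)
        expect_equal(icLinkage(pr, normalized = FALSE) + H,
                     rep(log2(9), pr@L - 1L), tolerance = 1e-12)
    }
})

test_that("reverse complement mirrors the profile", {
    set.seed(13)
    ss <- SequenceSet(randomSeqStrings(8, 10))
    fwd <- logoProfile(ss)
    rev <- logoProfile(reverseComplement(ss))
    expect_equal(icBase(rev), base::rev(icBase(fwd)), tolerance = 1e-12)
    expect_equal(icLinkage(rev), base::rev(icLinkage(fwd)), tolerance = 1e-12)
    expect_equal(meanTRX(rev), base::rev(meanTRX(fwd)), tolerance = 1e-12)
    # base rows swap A<->T and C<->G under the mirror
    expect_equal(unname(baseFrequencies(rev)["A", ]),
                 base::rev(unname(baseFrequencies(fwd)["T", ])))
    expect_equal(unname(baseFrequencies(rev)["C", ]),
                 base::rev(unname(baseFrequencies(fwd)["G", ])))
})

test_that("base and linkage IC match the brute-force oracle", {
    set.seed(17)
    for (r in 1:25) {
        seqs <- randomSeqStrings(sample(1:5, 1), sample(2:6, 1),
                                 alphabet = c("A", "C", "G", "T", "N"))
        ss <- SequenceSet(seqs)
        pr <- logoProfile(ss)
        expect_equal(icBase(pr), oracleBaseIC(seqs), tolerance = 1e-12)
        expect_equal(icLinkage(pr, normalized = FALSE), oracleLinkIC(seqs),
                     tolerance = 1e-12)
    }
})

test_that("the small-sample correction lowers IC and never goes negative", {
    ss <- SequenceSet(c("ACGT", "ACGT", "TCGA"))
    plain <- logoProfile(ss)
    corr <- logoProfile(ss, correction = TRUE)
    expect_true(all(icBase(corr) <= icBase(plain)))
    expect_true(all(icBase(corr) >= 0))
    expect_true(all(icLinkage(corr) <= icLinkage(plain)))
})

test_that("profiles serialize to TSV with one row per position", {
    ss <- SequenceSet(c("CATG", "CATG"))
    pr <- logoProfile(ss)
    f <- tempfile(fileext = ".tsv")
    writeProfile(pr, f)
    df <- read.delim(f)
    expect_equal(nrow(df), 4L)
    expect_equal(df$ic_base, icBase(pr))
    expect_equal(df$ic_link_norm[1:3], icLinkage(pr))
    expect_true(is.na(df$mean_trx[4]))
})
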