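# build a LogoProfile directly from given IC arrays (frequencies chosen to
# be consistent in range; only the IC arrays matter to the comparison)
profileFromIC <- function(icBase, icLink) {
    L <- length(icBase)
    new("LogoProfile",
        icBase = icBase, hBase = 2 - icBase,
        baseFreq = matrix(0.25, 4, L, dimnames = list(c("A","C","G","T"), NULL)),
        icLinkRaw = icLink * log2(9) / 2, icLinkNorm = icLink,
        meanTRX = rep(21.5, L - 1), nEffBase = rep(10L, L),
        nEffLink = rep(10L, L - 1), L = L, n = 10L, corrected = FALSE)
}

test_that("base-vs-linkage comparison behaves at the null and under shifts", {
    set.seed(31)
    base <- 1 + rnorm(30, sd = 0.05)
    base <- pmin(pmax(base, 0), 2)
    # equal populations: no significance
    pr <- profileFromIC(base, base[-30])
    res <- compareICRegions(pr, c(1, 30))
    expect_gt(res$p, 0.05)
    expect_lt(abs(res$t), 2)

    # linkages shifted +0.5 bits over 25 positions: clearly significant
    pr2 <- profileFromIC(base[1:25], pmin(base[1:25][-25] + 0.5, 2))
    res2 <- compareICRegions(pr2, c(1, 25))
    expect_lt(res2$p, 0.05)
    expect_gt(res2$meanLink, res2$meanBase)

    # paired variant pairs position i with linkage i
    pr3 <- profileFromIC(base[1:25],
                         pmin(base[1:25][-25] + 0.5 + rnorm(24, sd = 0.02), 2))
    res3 <- compareICRegions(pr3, c(1, 25), paired = TRUE)
    expect_lt(res3$p, 0.05)

    expect_error(compareICRegions(pr, c(5, 5)), "at least 2 positions")
    expect_error(compareICRegions(pr, c(0, 10)), "within")
})

test_that("Bonferroni decisions use alpha/m and ignore ordering", {
    d <- bonferroniDecisions(rep(1, 416), 0.05)
    expect_equal(d$threshold, 0.05 / 416, tolerance = 1e-12)
    expect_false(any(d$reject))

    expect_equal(bonferroniDecisions(0.04, 0.05)$threshold, 0.05)
    expect_true(bonferroniDecisions(0.04, 0.05)$reject)

    set.seed(37)
    p <- runif(50)
    perm <- sample(50)
    d1 <- bonferroniDecisions(p, 0.05)
    d2 <- bonferroniDecisions(p[perm], 0.05)
    expect_identical(d1$reject[perm], d2$reject)

    expect_error(bonferroniDecisions(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("codon phase bucketing is period-3 from the start codon", {
    # two genes, anchor 4, 3 codons: check the phase index arithmetic via a
    # set whose linkage IC is computable by hand (all sequences identical ->
    # every linkage IC = log2(9))
    g <- SequenceSet(rep(c("TTTATGGCAGCA"), 3), anchor = 4L)
    cps <- codonPhaseIC(g)
    expect_equal(unname(phaseMeans(cps)), rep(log2(9), 4))
    # x-1 holds the UTR junction + inter-codon steps; 3-z stops at the end
    expect_equal(unname(cps@phaseN), c(3L, 3L, 3L, 2L))

    # i.i.d. uniform bases, no codon structure: all phases equal within
    # Monte-Carlo error
    set.seed(41)
    u <- SequenceSet(randomSeqStrings(400, 90), anchor = 1L)
    cpsU <- suppressWarnings(codonPhaseIC(u))
    pm <- phaseMeans(cpsU)
    expect_lt(max(pm) - min(pm), 0.05)

    # a single gene yields means but no usable ANOVA
    one <- SequenceSet("ATGGCAGCATAA"
                       , anchor = 1L)
    cps1 <- codonPhaseIC(one)
    expect_true(all(is.finite(phaseMeans(cps1))))
    expect_false(is.finite(cps1@fStat))

    expect_error(codonPhaseIC(SequenceSet(c("ATGGCA", "ATGGCA"))),
                 "anchor")
    expect_warning(codonPhaseIC(SequenceSet(rep("TTTGGGCCC", 3),
                                            anchor = 1L)),
                   "ATG")
})

test_that("codon phases mirror under reverse complement of the frame", {
    set.seed(43)
    g <- generateCodingSet(40, 8, utrLength = 0, seed = 43)
    fwd <- suppressWarnings(codonPhaseIC(g))
    rc <- reverseComplement(g)
    # frame of L = 3T with anchor 1 mirrors onto anchor 1 of the reverse
    bwd <- suppressWarnings(codonPhaseIC(rc, anchor = 1L))
    # internal linkages stay internal (1-2 swaps with 2-3), inter-codon
    # linkages stay inter-codon
    expect_equal(sort(c(fwd@perPhase[["1-2"]], fwd@perPhase[["2-3"]])),
                 sort(c(bwd@perPhase[["1-2"]], bwd@perPhase[["2-3"]])),
                 tolerance = 1e-12)
    expect_equal(sort(unique(c(fwd@perPhase[["x-1"]], fwd@perPhase[["3-z"]]))),
                 sort(unique(c(bwd@perPhase[["x-1"]], bwd@perPhase[["3-z"]]))),
                 tolerance = 1e-12)
})

test_that("bootstrap ANOVA is reproducible and validates its inputs", {
    g <- generateCodingSet(30, 12, seed = 47)
    b1 <- bootstrapANOVA(g, nSets = 25, setSize = 5, seed = 7)
    b2 <- bootstrapANOVA(g, nSets = 25, setSize = 5, seed = 7)
    expect_identical(b1$F, b2$F)
    expect_identical(b1$p, b2$p)
    expect_identical(b1$perSet, b2$perSet)
    expect_equal(dim(b1$perSet), c(25L, 4L))

    expect_error(bootstrapANOVA(g[1:3], setSize = 10), "at least")
})

test_that("random DNA honors composition and seed", {
    expect_identical(randomDNA(5, c(A = 1, C = 0, G = 0, T = 0)), "AAAAA")
    s1 <- randomDNA(100, seed = 5)
    s2 <- randomDNA(100, seed = 5)
    expect_identical(s1, s2)

    big <- randomDNA(1e5, seed = 53)
    freq <- table(strsplit(big, "")[[1]]) / 1e5
    expect_true(all(abs(freq - 0.25) < 0.005))

    expect_error(randomDNA(5, c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)),
                 "sum to 1")
})

test_that("codon-context scan separates code structure from random background", {
    # a single codon type: internal linkages fully informative, flanks near
    # the uniform-DNA floor
    r1 <- codonContextScan(rep("CAT", 1500), seed = 59)
    expect_equal(r1$internalMean, log2(9), tolerance = 1e-9)
    expect_gt(r1$internalMean, r1$flankMean + 2)

    # codons uniform over all 64: no code structure, internal ~ flank
    set.seed(61)
    all64 <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                   paste0), c("A","C","G","T"), paste0))
    r2 <- codonContextScan(sample(all64, 20000, TRUE), seed = 62)
    expect_lt(abs(r2$internalMean - r2$flankMean), 0.02)

    # sense codons weighted by a uniform amino-acid distribution: the code
    # organization alone makes internal linkages more informative
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    w <- 1 / table(gc[sense])[gc[sense]]
    set.seed(63)
    r3 <- codonContextScan(sample(sense, 20000, TRUE, prob = w), seed = 64)
    expect_gt(r3$internalMean, r3$flankMean + 0.05)

    expect_warning(
        codonContextScan(rep("GGG", 500),
                         flankComposition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                         seed = 65),
        "composition")
    expect_error(codonContextScan(character()), "non-empty")
    expect_error(codonContextScan("ACGT"), "3-letter")
})
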