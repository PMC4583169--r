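# Downstream statistics: base-vs-linkage information comparison with
# Bonferroni correction, start-codon aligned codon-phase scans, bootstrap
# one-way ANOVA over phase means, and equal-composition random DNA.

#' Compare base and linkage information content over a region
#'
#' Two-sample t-test (Welch by default) of the per-position base IC against
#' the per-linkage IC within a region of the profile.  A region
#' \code{[from, to]} contributes base positions \code{from..to} and the
#' linkages lying wholly inside it (\code{from..to-1}).  With
#' \code{paired = TRUE}, base position \code{i} is paired with linkage
#' \code{i} and a paired t-test is used.
#'
#' @param profile a \linkS4class{LogoProfile}.
#' @param region integer c(from, to), 1-based, within the profile.
#' @param useNormalized compare linkage IC on the 2.0-bit display scale
#'   (default) rather than raw 9-state bits, so both alphabets share a cap.
#' @param paired use a paired t-test instead of Welch.
#' @param label region label carried into the result (e.g. "site", "flank").
#' @return data.frame with one row: label, means, t, df, p.
#' @export
compareICRegions <- function(profile, region = c(1L, profile@L),
                             useNormalized = TRUE, paired = FALSE,
                             label = "region") {
    region <- as.integer(region)
    if (length(region) != 2L || anyNA(region) ||
        region[1] < 1L || region[2] > profile@L || region[1] > region[2])
        validationError("region must be c(from, to) within [1, L]")
    if (region[2] - region[1] < 1L)
        validationError("region too small: at least 2 positions required")
    idxB <- region[1]:region[2]
    idxL <- region[1]:(region[2] - 1L)
    base <- profile@icBase[idxB]
    link <- icLinkage(profile, normalized = useNormalized)[idxL]
    if (paired) {
        base <- profile@icBase[idxL]
        tt <- stats::t.test(link, base, paired = TRUE)
    } else {
        tt <- stats::t.test(link, base)
    }
    data.frame(region = label,
               meanBase = mean(base), meanLink = mean(link),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
}

#' Bonferroni decisions for a family of p-values
#'
#' Each test is rejected iff \code{p < alpha / m} with \code{m} the family
#' size; the decisions do not depend on the order of the p-values.
#'
#' @param p p-values in [0, 1].
#' @param alpha family-wise error level.
#' @return list with \code{threshold} (\code{alpha / m}), \code{reject}
#'   (logical vector) and \code{m}.
#' @examples
#' bonferroniDecisions(rep(1e-5, 416), 0.05)$threshold  # 0.05 / 416
#' @export
bonferroniDecisions <- function(p, alpha = 0.05) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        validationError("p-values must lie in [0, 1]")
    if (!length(p))
        validationError("at least one p-value required")
    thr <- alpha / length(p)
    list(threshold = thr, reject = !is.na(p) & p < thr, m = length(p))
}

# linkage phase index sets for a start-codon anchored window:
# codon t occupies anchor + 3(t-1) .. anchor + 3t - 1, t = 1..T
.phaseIndices <- function(L, anchor) {
    nCodon <- (L - anchor + 1L) %/% 3L
    if (nCodon < 2L)
        validationError("coding side too short: at least 6 bases after the anchor required")
    t <- seq_len(nCodon) - 1L
    keep <- function(j) j[j >= 1L & j <= L - 1L]
    list("x-1" = keep(anchor - 1L + 3L * t),
         "1-2" = keep(anchor + 3L * t),
         "2-3" = keep(anchor + 1L + 3L * t),
         "3-z" = keep(anchor + 2L + 3L * t))
}

# per-linkage raw IC from a state-index matrix (rows = sequences)
.linkICFromStates <- function(m) {
    cnt <- .colCounts(m, 9L)
    H <- .colEntropyFromCounts(cnt)
    log2(9) - H
}

#' Codon-phase periodicity of linkage information content
#'
#' For a sequence set aligned at the start codon (the anchor marks the A of
#' ATG, codon position 1), computes per-linkage IC across the set and
#' buckets the linkages of the coding side, period-3, into the four
#' codon-bridging phases: \code{x-1} (preceding codon's last base to
#' position 1), \code{1-2}, \code{2-3}, and \code{3-z} (position 3 to the
#' next codon's first base).  The start codon is part of the coding region
#' and is included.  In a contiguous reading frame, interior \code{x-1}
#' and \code{3-z} linkages are the same physical inter-codon steps viewed
#' from adjacent codons; they differ at the window boundaries (the
#' UTR-to-ATG junction belongs only to \code{x-1}).  A one-way ANOVA across
#' the four phases on the position-level IC values is attached.
#'
#' @param seqs a \linkS4class{SequenceSet}; all sequences share the anchor.
#' @param scale a \linkS4class{TRXScale}.
#' @param anchor 1-based start-codon position; defaults to the set's anchor.
#' @param normalized report IC on the 2.0-bit display scale instead of raw
#'   9-state bits (default raw).
#' @return A \linkS4class{CodonPhaseSummary}.
#' @export
codonPhaseIC <- function(seqs, scale = defaultTRXScale(),
                         anchor = anchorPosition(seqs), normalized = FALSE) {
    anchor <- as.integer(anchor)
    if (is.na(anchor))
        validationError("an anchor (start codon position) is required")
    L <- seqWidth(seqs)
    if (anchor < 1L || anchor > L - 2L)
        validationError("anchor out of range")
    starts <- substr(sequences(seqs), anchor, anchor + 2L)
    if (mean(starts == "ATG") < 0.5)
        warning("fewer than half of the sequences carry ATG at the anchor; check the alignment")
    idx <- .phaseIndices(L, anchor)
    ic <- .linkICFromStates(.stateIndexMatrix(.seqMatrix(sequences(seqs)),
                                              scale))
    if (normalized) ic <- normalizeLinkageIC(ic)
    perPhase <- lapply(idx, function(j) unname(ic[j][!is.na(ic[j])]))
    means <- vapply(perPhase, function(v)
        if (length(v)) mean(v) else NA_real_, 0)
    fStat <- NA_real_; pVal <- NA_real_
    vals <- unlist(perPhase, use.names = FALSE)
    if (all(lengths(perPhase) >= 2L) && stats::var(vals) > 1e-20) {
        df <- data.frame(
            ic = vals,
            phase = factor(rep(names(perPhase), lengths(perPhase)),
                           levels = names(perPhase)))
        an <- stats::anova(stats::aov(ic ~ phase, data = df))
        fStat <- an[["F value"]][1]
        pVal <- an[["Pr(>F)"]][1]
    }
    new("CodonPhaseSummary", phaseMeans = means,
        phaseN = lengths(perPhase), perPhase = perPhase,
        fStat = fStat, pValue = pVal, anchor = anchor)
}

#' @rdname CodonPhaseSummary-accessors
#' @export
setGeneric("phaseMeans", function(x) standardGeneric("phaseMeans"))

#' Accessors for CodonPhaseSummary
#'
#' @param x a \linkS4class{CodonPhaseSummary}.
#' @name CodonPhaseSummary-accessors
#' @aliases phaseMeans
NULL

#' @rdname CodonPhaseSummary-accessors
#' @export
setMethod("phaseMeans", "CodonPhaseSummary", function(x) x@phaseMeans)

#' @describeIn CodonPhaseSummary summary display.
#' @param object a \code{CodonPhaseSummary}.
#' @export
setMethod("show", "CodonPhaseSummary", function(object) {
    cat("CodonPhaseSummary (anchor =", object@anchor, ")\n")
    print(round(object@phaseMeans, 4))
    cat("positions per phase:", paste(object@phaseN, collapse = " "), "\n")
    if (!is.na(object@fStat))
        cat(sprintf("one-way ANOVA across phases: F = %.2f, p = %.3g\n",
                    object@fStat, object@pValue))
})

#' Bootstrap one-way ANOVA of codon-phase means
#'
#' Draws \code{nSets} random subsets of \code{setSize} genes (with
#' replacement) from a start-codon aligned gene set, computes the four
#' codon-phase mean linkage ICs within each subset, and runs a one-way
#' ANOVA of the phase means across the four phase groups (\code{nSets}
#' replicates per group).
#'
#' Note that the replicates resample one fixed gene pool, so they are not
#' independent draws from the population of genes; with small pools the
#' test is anti-conservative (see the package vignette).
#'
#' @param genes a \linkS4class{SequenceSet} of start-codon aligned genes.
#' @param scale a \linkS4class{TRXScale}.
#' @param nSets number of bootstrap sets.
#' @param setSize genes per set.
#' @param seed RNG seed; recorded in the result.  NULL leaves the RNG
#'   state alone.
#' @param anchor start-codon position; defaults to the set's anchor.
#' @return list with \code{F}, \code{p}, \code{phaseMeans} (mean over sets
#'   per phase), \code{perSet} (nSets x 4 matrix), \code{nSets},
#'   \code{setSize}, \code{seed}.
#' @export
bootstrapANOVA <- function(genes, scale = defaultTRXScale(), nSets = 100L,
                           setSize = 10L, seed = NULL,
                           anchor = anchorPosition(genes)) {
    n <- nSequences(genes)
    if (n < setSize)
        validationError(sprintf(
            "need at least setSize = %d genes, got %d", setSize, n))
    anchor <- as.integer(anchor)
    if (is.na(anchor))
        validationError("an anchor (start codon position) is required")
    if (!is.null(seed)) set.seed(seed)
    idx <- .phaseIndices(seqWidth(genes), anchor)
    states <- .stateIndexMatrix(.seqMatrix(sequences(genes)), scale)
    perSet <- matrix(NA_real_, nSets, 4L,
                     dimnames = list(NULL, names(idx)))
    for (s in seq_len(nSets)) {
        rows <- sample.int(n, setSize, replace = TRUE)
        ic <- .linkICFromStates(states[rows, , drop = FALSE])
        perSet[s, ] <- vapply(idx, function(j) mean(ic[j], na.rm = TRUE), 0)
    }
    df <- data.frame(ic = as.vector(perSet),
                     phase = factor(rep(colnames(perSet), each = nSets),
                                    levels = colnames(perSet)))
    an <- stats::anova(stats::aov(ic ~ phase, data = df))
    list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
         phaseMeans = colMeans(perSet), perSet = perSet,
         nSets = nSets, setSize = setSize, seed = seed)
}

#' Random DNA of given base composition
#'
#' @param length sequence length.
#' @param composition named probabilities for A, C, G, T, summing to 1.
#' @param seed optional RNG seed.
#' @return a single sequence string.
#' @examples
#' randomDNA(10, c(A = 1, C = 0, G = 0, T = 0))  # "AAAAAAAAAA"
#' @export
randomDNA <- function(length, composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                      seed = NULL) {
    if (!setequal(names(composition), .BASES))
        validationError("composition must be named A, C, G, T")
    if (any(composition < 0) || abs(sum(composition) - 1) > 1e-8)
        validationError("composition must be non-negative and sum to 1")
    if (!is.null(seed)) set.seed(seed)
    paste0(sample(.BASES, length, replace = TRUE,
                  prob = composition[.BASES]), collapse = "")
}

#' Codon-context scan against a random-DNA background
#'
#' Pools codons aligned at codon position and flanks each with random
#' triplets of the same base composition as the codon pool, eliminating
#' information due to specific genetic content while retaining what the
#' organization of codon assignments itself imparts.  Each pooled codon
#' becomes a 9-mer (flank triplet + codon + flank triplet); linkage IC is
#' computed across the pool and reported by context: the two linkages
#' internal to the codon (1-2, 2-3), the two junction linkages joining
#' codon to flank (x-1, 3-z), and the four linkages internal to the random
#' flanks (the background).
#'
#' @param codons character vector of 3-letter codons (one entry per codon
#'   occurrence; repeats encode usage).
#' @param scale a \linkS4class{TRXScale}.
#' @param flankComposition optional named base probabilities for the random
#'   flanks; defaults to the codon pool's composition.  A supplied
#'   composition deviating from the pool's by more than 0.05 in any base
#'   triggers a warning.
#' @param seed optional RNG seed for the flanks.
#' @return list with \code{ic} (named per-linkage IC, 8 linkages),
#'   \code{internalMean}, \code{junctionMean}, \code{flankMean},
#'   \code{composition} and the assembled \code{sequences}.
#' @export
codonContextScan <- function(codons, scale = defaultTRXScale(),
                             flankComposition = NULL, seed = NULL) {
    if (!length(codons))
        validationError("codon list must be non-empty")
    codons <- toupper(codons)
    if (any(nchar(codons) != 3L) || any(grepl("[^ACGT]", codons)))
        validationError("codons must be 3-letter ACGT strings")
    pool <- table(factor(unlist(strsplit(codons, "")), levels = .BASES))
    comp <- as.numeric(pool) / sum(pool)
    names(comp) <- .BASES
    if (is.null(flankComposition)) {
        flankComposition <- comp
    } else {
        if (!setequal(names(flankComposition), .BASES) ||
            abs(sum(flankComposition) - 1) > 1e-8)
            validationError("flankComposition must be named A,C,G,T and sum to 1")
        if (any(abs(flankComposition[.BASES] - comp) > 0.05))
            warning("flank composition deviates from the codon pool composition")
    }
    if (!is.null(seed)) set.seed(seed)
    n <- length(codons)
    flanks <- matrix(sample(.BASES, 6L * n, replace = TRUE,
                            prob = flankComposition[.BASES]), nrow = n)
    seqs <- paste0(flanks[, 1], flanks[, 2], flanks[, 3], codons,
                   flanks[, 4], flanks[, 5], flanks[, 6])
    ss <- SequenceSet(seqs, anchor = 4L)
    ic <- .linkICFromStates(.stateIndexMatrix(.seqMatrix(sequences(ss)),
                                              scale))
    names(ic) <- c("f1-f2", "f2-f3", "x-1", "1-2", "2-3", "3-z",
                   "z1-z2", "z2-z3")
    list(ic = ic,
         internalMean = mean(ic[c("1-2", "2-3")]),
         junctionMean = mean(ic[c("x-1", "3-z")]),
         flankMean = mean(ic[c("f1-f2", "f2-f3", "z1-z2", "z2-z3")]),
         composition = comp, sequences = ss)
}
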