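# Shannon information content at nucleobases (k = 4) and at phosphate
# linkages over the 9-state TRX alphabet (k = 9): IC_i = log2(k) - H_i with
# H_i = -sum_s p_{s,i} log2 p_{s,i}.

#' Shannon entropy of symbol frequencies, in bits
#'
#' \code{0 * log(0)} is taken as 0.  For a matrix, entropy is computed per
#' column; columns summing to 0 (unobserved) give NA.
#'
#' @param p numeric vector of frequencies summing to 1, or a matrix of
#'   per-column frequencies.
#' @return entropy in bits (scalar or per-column vector).
#' @examples
#' shannonEntropy(c(0.5, 0.5, 0, 0))   # 1 bit
#' @export
shannonEntropy <- function(p) {
    if (any(p < 0))
        validationError("frequencies must be non-negative")
    if (is.matrix(p)) {
        terms <- p * log2(p)
        terms[p == 0] <- 0
        H <- -colSums(terms)
        H[colSums(p) == 0] <- NA_real_
        return(H)
    }
    if (abs(sum(p) - 1) > 1e-6)
        validationError("frequencies must sum to 1")
    pp <- p[p > 0]
    -sum(pp * log2(pp))
}

#' Information content from entropy
#'
#' \code{IC = log2(k) - H}: 2.0 bits maximum for the 4-letter base alphabet,
#' log2(9) (about 3.17, conventionally printed 3.2) for the 9-state TRX
#' linkage alphabet.
#'
#' @param H entropy in bits (vector allowed; NA passes through).
#' @param k alphabet size.
#' @return information content in bits.
#' @examples
#' informationContent(0, 4)   # 2
#' informationContent(0, 9)   # log2(9)
#' @export
informationContent <- function(H, k) {
    if (any(H > log2(k) + 1e-9, na.rm = TRUE) || any(H < -1e-9, na.rm = TRUE))
        validationError("H must lie in [0, log2(k)]")
    log2(k) - H
}

#' Normalize linkage information content onto the 2.0-bit display axis
#'
#' Linkage IC over 9 states caps at log2(9) bits; for display (and for
#' comparisons against base IC on a common scale) it is rescaled linearly
#' so that log2(9) maps to 2.0 bits, as in standard 4-letter logos.
#'
#' @param ic raw linkage IC in [0, log2(9)] (NA passes through).
#' @return normalized IC in [0, 2].
#' @export
normalizeLinkageIC <- function(ic) {
    if (any(ic < -1e-9 | ic > log2(9) + 1e-9, na.rm = TRUE))
        validationError("raw linkage IC must lie in [0, log2(9)]")
    ic * 2 / log2(9)
}

#' Positional base frequency matrix of a sequence set
#'
#' Relative frequency of each base among the non-N observations at each
#' column.  Columns with no observation are flagged by \code{nEff == 0} and
#' carry zero frequencies (rendered as zero height downstream).
#'
#' @param seqs a \linkS4class{SequenceSet}.
#' @return A \linkS4class{BasePWM}.
#' @export
basePWM <- function(seqs) {
    m <- .seqMatrix(sequences(seqs))
    cnt <- .colCounts(m, 4L)
    ne <- colSums(cnt)
    p <- sweep(cnt, 2L, pmax(ne, 1L), "/")
    dimnames(p) <- list(c("A", "C", "G", "T"), NULL)
    new("BasePWM", p = p, nEff = as.integer(ne))
}

#' Positional TRX-state frequency matrix of a sequence set
#'
#' For every sequence, the dimer at linkage \code{j} (bases \code{j} and
#' \code{j+1}) is mapped to its TRX state symbol; frequencies are tallied
#' over the sequences whose dimer contains no N.  Because two dinucleotide
#' classes share a score, the alphabet has exactly 9 states.
#'
#' @param seqs a \linkS4class{SequenceSet} with \code{seqWidth >= 2}.
#' @param scale a \linkS4class{TRXScale}.
#' @return A \linkS4class{LinkageStateMatrix}.
#' @export
linkageStateMatrix <- function(seqs, scale = defaultTRXScale()) {
    m <- .stateIndexMatrix(.seqMatrix(sequences(seqs)), scale)
    cnt <- .colCounts(m, 9L)
    ne <- colSums(cnt)
    p <- sweep(cnt, 2L, pmax(ne, 1L), "/")
    dimnames(p) <- list(format(scale@symbols, trim = TRUE), NULL)
    new("LinkageStateMatrix", p = p, nEff = as.integer(ne),
        symbols = scale@symbols)
}

#' Mean TRX flexibility at each phosphate linkage
#'
#' Arithmetic mean of the TRX scores of the observed (N-free) dimers at
#' each linkage; NA where no dimer is observed.
#'
#' @inheritParams linkageStateMatrix
#' @return numeric vector of length \code{seqWidth - 1}, values in [0, 43].
#' @export
meanTRXProfile <- function(seqs, scale = defaultTRXScale()) {
    lsm <- linkageStateMatrix(seqs, scale)
    mt <- colSums(lsm@p * lsm@symbols)
    mt[lsm@nEff == 0L] <- NA_real_
    mt
}

#' Full information-content profile of a sequence set
#'
#' Computes the complete data model of the extended logo plot: per-column
#' base entropy and information content (k = 4), per-linkage raw and
#' normalized information content over the 9 TRX states, and the mean TRX
#' flexibility per linkage.  Unobserved columns/linkages get IC 0 and are
#' flagged through the effective counts.
#'
#' An optional small-sample correction subtracts the classical
#' \code{(k-1) / (2 ln(2) n)} bias term from IC (clamped at 0); it is off
#' by default, matching the plain definition \code{IC = log2(k) - H}.
#'
#' @inheritParams linkageStateMatrix
#' @param correction apply the small-sample correction (default FALSE).
#' @return A \linkS4class{LogoProfile}.
#' @examples
#' ss <- SequenceSet(c("CATG", "CATG", "CATG"))
#' pr <- logoProfile(ss)
#' icBase(pr)                 # 2, 2, 2, 2
#' icLinkage(pr)              # 2, 2, 2 (normalized)
#' @export
logoProfile <- function(seqs, scale = defaultTRXScale(), correction = FALSE) {
    bp <- basePWM(seqs)
    lsm <- linkageStateMatrix(seqs, scale)
    hB <- shannonEntropy(bp@p)
    hL <- shannonEntropy(lsm@p)
    icB <- informationContent(hB, 4L)
    icL <- informationContent(hL, 9L)
    if (correction) {
        icB <- pmax(icB - 3 / (2 * log(2) * pmax(bp@nEff, 1L)), 0)
        icL <- pmax(icL - 8 / (2 * log(2) * pmax(lsm@nEff, 1L)), 0)
    }
    icB[is.na(icB)] <- 0
    hB[is.na(hB)] <- 0
    icL[is.na(icL)] <- 0
    mt <- colSums(lsm@p * lsm@symbols)
    mt[lsm@nEff == 0L] <- NA_real_
    new("LogoProfile",
        icBase = icB, hBase = hB, baseFreq = bp@p,
        icLinkRaw = icL, icLinkNorm = normalizeLinkageIC(icL),
        meanTRX = mt,
        nEffBase = bp@nEff, nEffLink = lsm@nEff,
        L = ncol(bp@p), n = nSequences(seqs),
        corrected = isTRUE(correction))
}

#' @rdname LogoProfile-accessors
#' @export
setGeneric("icBase", function(x) standardGeneric("icBase"))

#' @rdname LogoProfile-accessors
#' @export
setGeneric("icLinkage", function(x, normalized = TRUE)
    standardGeneric("icLinkage"))

#' @rdname LogoProfile-accessors
#' @export
setGeneric("meanTRX", function(x) standardGeneric("meanTRX"))

#' @rdname LogoProfile-accessors
#' @export
setGeneric("baseFrequencies", function(x) standardGeneric("baseFrequencies"))

#' Accessors for LogoProfile
#'
#' @param x a \linkS4class{LogoProfile}.
#' @param normalized return linkage IC on the 2.0-bit display scale
#'   (default) or raw bits over 9 states.
#' @name LogoProfile-accessors
#' @aliases icBase icLinkage meanTRX baseFrequencies
NULL

#' @rdname LogoProfile-accessors
#' @export
setMethod("icBase", "LogoProfile", function(x) x@icBase)

#' @rdname LogoProfile-accessors
#' @export
setMethod("icLinkage", "LogoProfile", function(x, normalized = TRUE)
    if (normalized) x@icLinkNorm else x@icLinkRaw)

#' @rdname LogoProfile-accessors
#' @export
setMethod("meanTRX", "LogoProfile", function(x) x@meanTRX)

#' @rdname LogoProfile-accessors
#' @export
setMethod("baseFrequencies", "LogoProfile", function(x) x@baseFreq)

#' Serialize a LogoProfile to TSV
#'
#' One row per base position: position, base IC, per-base frequencies, then
#' the raw/normalized IC and mean TRX of the linkage that follows the
#' position (NA on the last row, which has no following linkage).
#'
#' @param profile a \linkS4class{LogoProfile}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
    L <- profile@L
    df <- data.frame(
        position = seq_len(L),
        ic_base = profile@icBase,
        freq_A = profile@baseFreq["A", ],
        freq_C = profile@baseFreq["C", ],
        freq_G = profile@baseFreq["G", ],
        freq_T = profile@baseFreq["T", ],
        ic_link_raw = c(profile@icLinkRaw, NA),
        ic_link_norm = c(profile@icLinkNorm, NA),
        mean_trx = c(profile@meanTRX, NA))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @describeIn LogoProfile summary display.
#' @param object a \code{LogoProfile}.
#' @export
setMethod("show", "LogoProfile", function(object) {
    cat("LogoProfile: ", object@n, " sequences, L = ", object@L, "\n",
        "  base IC   [bits]: ", paste(round(object@icBase, 3), collapse = " "),
        "\n  link IC (norm) : ",
        paste(round(object@icLinkNorm, 3), collapse = " "),
        "\n  mean TRX       : ",
        paste(round(object@meanTRX, 1), collapse = " "), "\n", sep = "")
})
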