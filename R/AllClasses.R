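#' @import methods
NULL

#' TRX dinucleotide flexibility scale
#'
#' Maps each of the 16 ACGT dinucleotide steps to one of 10 strand-symmetric
#' classes and each class to its TRX score: the percentage of time the
#' phosphate linkage of that step spends in the BII backbone conformation,
#' on a scale from 0 (stiff, ApT) to 43 (flexible, CpG).  Two classes share
#' one score, so the linkage alphabet has exactly 9 distinct symbols.
#'
#' @slot table data.frame with columns \code{class}, \code{dimers}, \code{score}.
#' @slot dimerClass named character(16), dimer -> class label.
#' @slot dimerScore named numeric(16), dimer -> TRX score.
#' @slot symbols sorted numeric vector of the 9 distinct scores.
#' @exportClass TRXScale
setClass("TRXScale",
    representation(
        table      = "data.frame",
        dimerClass = "character",
        dimerScore = "numeric",
        symbols    = "numeric"
    )
)

setValidity("TRXScale", function(object) {
    msg <- character()
    dimers <- .allDimers()
    if (!setequal(names(object@dimerClass), dimers))
        msg <- c(msg, "scale must cover all 16 ACGT dimers")
    cls <- unique(object@dimerClass)
    if (length(cls) != 10L)
        msg <- c(msg, sprintf("expected 10 strand-symmetric classes, got %d",
                              length(cls)))
    rc <- .revcompDimers(names(object@dimerClass))
    if (!all(object@dimerClass == object@dimerClass[rc]))
        msg <- c(msg, "a dimer and its reverse complement must share a class")
    classScore <- object@dimerScore[!duplicated(object@dimerClass)]
    sym <- unique(unname(object@dimerScore))
    if (length(sym) != 9L)
        msg <- c(msg, sprintf("expected 9 distinct TRX scores, got %d",
                              length(sym)))
    if (min(object@dimerScore) != 0)
        msg <- c(msg, "minimum TRX score must be 0")
    if (max(object@dimerScore) != 43)
        msg <- c(msg, "maximum TRX score must be 43")
    if (sum(duplicated(classScore)) != 1L)
        msg <- c(msg, "exactly two classes must share one TRX score")
    gc <- vapply(names(object@dimerClass)[!duplicated(object@dimerClass)],
                 function(d) mean(strsplit(d, "")[[1]] %in% c("G", "C")), 0)
    if (stats::cor(gc, classScore, method = "spearman") <= 0)
        msg <- c(msg, "TRX scores must rank-correlate positively with GC content")
    if (length(msg)) msg else TRUE
})

#' Set of equal-length, center-aligned DNA sequences
#'
#' The container every loader and generator emits: \code{n} uppercase
#' sequences over \{A,C,G,T,N\} of common length \code{L}.  Base positions
#' are 1-based \code{1..L}; phosphate linkage \code{j} sits between bases
#' \code{j} and \code{j+1} (so linkages run \code{1..L-1}).  An optional
#' motif span marks the aligned consensus core (JASPAR dialect) and an
#' optional anchor marks an alignment reference such as the A of a start
#' codon.
#'
#' @slot sequences character vector of equal-length uppercase sequences.
#' @slot labels per-sequence identifiers.
#' @slot motifStart,motifEnd 1-based bounds of the aligned motif core, or NA.
#' @slot anchor 1-based alignment anchor position, or NA.
#' @exportClass SequenceSet
setClass("SequenceSet",
    representation(
        sequences  = "character",
        labels     = "character",
        motifStart = "integer",
        motifEnd   = "integer",
        anchor     = "integer"
    ),
    prototype(motifStart = NA_integer_, motifEnd = NA_integer_,
              anchor = NA_integer_)
)

setValidity("SequenceSet", function(object) {
    msg <- character()
    if (length(object@sequences) < 1L)
        msg <- c(msg, "at least one sequence required")
    w <- unique(nchar(object@sequences))
    if (length(w) != 1L)
        msg <- c(msg, "all sequences must have the same length")
    else if (w < 2L)
        msg <- c(msg, "sequences must have length >= 2")
    if (any(grepl("[^ACGTN]", object@sequences)))
        msg <- c(msg, "sequences must be uppercase over {A,C,G,T,N}")
    if (length(object@labels) &&
        length(object@labels) != length(object@sequences))
        msg <- c(msg, "labels must match the number of sequences")
    L <- if (length(w) == 1L) w else NA_integer_
    span <- c(object@motifStart, object@motifEnd)
    if (xor(is.na(span[1]), is.na(span[2])))
        msg <- c(msg, "motifStart and motifEnd must be set together")
    if (!anyNA(span) && !is.na(L) &&
        (span[1] < 1L || span[2] > L || span[1] > span[2]))
        msg <- c(msg, "motif span out of range")
    if (!is.na(object@anchor) && !is.na(L) &&
        (object@anchor < 1L || object@anchor > L))
        msg <- c(msg, "anchor out of range")
    if (length(msg)) msg else TRUE
})

#' Positional base frequency matrix
#'
#' @slot p 4 x L matrix of relative frequencies (rows A, C, G, T); columns
#'   with no non-N observation are all zero and flagged by \code{nEff == 0}.
#' @slot nEff integer vector, non-N observations per column.
#' @exportClass BasePWM
setClass("BasePWM",
    representation(p = "matrix", nEff = "integer"))

setValidity("BasePWM", function(object) {
    msg <- character()
    if (nrow(object@p) != 4L || !identical(rownames(object@p), c("A","C","G","T")))
        msg <- c(msg, "p must have rows A, C, G, T")
    if (length(object@nEff) != ncol(object@p))
        msg <- c(msg, "nEff length must match columns of p")
    cs <- colSums(object@p)
    bad <- object@nEff > 0L & abs(cs - 1) > 1e-9
    if (any(bad))
        msg <- c(msg, "observed columns must sum to 1")
    if (any(object@p < 0 | object@p > 1))
        msg <- c(msg, "frequencies must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Positional TRX-state frequency matrix
#'
#' Relative frequencies of the 9 TRX linkage states at each phosphate
#' linkage \code{j = 1..L-1}.  A linkage only counts sequences whose dimer
#' at that step contains no N.
#'
#' @slot p 9 x (L-1) matrix, rows labelled by TRX score.
#' @slot nEff integer vector of observed (N-free) dimers per linkage.
#' @slot symbols the 9 distinct TRX scores, sorted.
#' @exportClass LinkageStateMatrix
setClass("LinkageStateMatrix",
    representation(p = "matrix", nEff = "integer", symbols = "numeric"))

setValidity("LinkageStateMatrix", function(object) {
    msg <- character()
    if (nrow(object@p) != 9L)
        msg <- c(msg, "exactly 9 TRX-state rows required")
    if (length(object@nEff) != ncol(object@p))
        msg <- c(msg, "nEff length must match columns of p")
    cs <- colSums(object@p)
    if (any(object@nEff > 0L & abs(cs - 1) > 1e-9))
        msg <- c(msg, "observed columns must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Per-position information content profile of a sequence set
#'
#' The data model behind the extended logo plot: base information content
#' (bits, capped at log2(4) = 2), linkage information content over the
#' 9-state TRX alphabet both raw (capped at log2(9) ~ 3.17 bits) and
#' normalized onto the 2.0-bit display axis, and the mean TRX flexibility
#' at each linkage.
#'
#' @slot icBase,hBase numeric(L): information content and entropy per base column.
#' @slot baseFreq 4 x L base frequency matrix.
#' @slot icLinkRaw,icLinkNorm,meanTRX numeric(L-1) linkage profiles.
#' @slot nEffBase,nEffLink effective (non-N) counts.
#' @slot L,n sequence length and number of sequences.
#' @slot corrected logical, whether the small-sample correction was applied.
#' @exportClass LogoProfile
setClass("LogoProfile",
    representation(
        icBase = "numeric", hBase = "numeric", baseFreq = "matrix",
        icLinkRaw = "numeric", icLinkNorm = "numeric", meanTRX = "numeric",
        nEffBase = "integer", nEffLink = "integer",
        L = "integer", n = "integer", corrected = "logical"
    )
)

setValidity("LogoProfile", function(object) {
    msg <- character()
    L <- object@L
    if (length(object@icBase) != L || length(object@hBase) != L)
        msg <- c(msg, "base arrays must have length L")
    if (length(object@icLinkRaw) != L - 1L ||
        length(object@icLinkNorm) != L - 1L ||
        length(object@meanTRX) != L - 1L)
        msg <- c(msg, "linkage arrays must have length L-1")
    tol <- 1e-9
    if (any(object@icBase < -tol | object@icBase > 2 + tol))
        msg <- c(msg, "base IC must lie in [0, 2] bits")
    if (any(object@icLinkRaw < -tol | object@icLinkRaw > log2(9) + tol))
        msg <- c(msg, "raw linkage IC must lie in [0, log2(9)] bits")
    if (any(object@icLinkNorm < -tol | object@icLinkNorm > 2 + tol))
        msg <- c(msg, "normalized linkage IC must lie in [0, 2] bits")
    mt <- object@meanTRX[!is.na(object@meanTRX)]
    if (any(mt < 0 | mt > 43))
        msg <- c(msg, "mean TRX must lie in [0, 43]")
    if (length(msg)) msg else TRUE
})

#' Graphical parameters of the extended logo plot
#'
#' @slot barStart x-position of the first linkage bar (defaults to 1.5,
#'   midway between the first two letter columns).
#' @slot barIncrement spacing between consecutive bars.
#' @slot barWidth bar width in column units.
#' @slot yMax top of the bits axis (2.0, the 4-letter alphabet cap).
#' @slot colors named fill colors for A, C, G, T.
#' @slot format default output format tag ("svg", "png" or "pdf").
#' @slot width,height output size; width NA means auto from sequence length.
#' @exportClass LogoStyle
setClass("LogoStyle",
    representation(
        barStart = "numeric", barIncrement = "numeric", barWidth = "numeric",
        yMax = "numeric", colors = "character", format = "character",
        width = "numeric", height = "numeric"
    )
)

setValidity("LogoStyle", function(object) {
    msg <- character()
    if (object@barIncrement <= 0)
        msg <- c(msg, "barIncrement must be > 0")
    if (object@barWidth <= 0 || object@barWidth >= 1)
        msg <- c(msg, "barWidth must lie strictly between 0 and 1")
    if (!setequal(names(object@colors), c("A", "C", "G", "T")))
        msg <- c(msg, "colors must be named A, C, G, T")
    if (!object@format %in% c("svg", "png", "pdf"))
        msg <- c(msg, "format must be one of svg, png, pdf")
    if (length(msg)) msg else TRUE
})

#' Codon-phase summary of linkage information content
#'
#' Mean linkage information content at the four codon-bridging phases of a
#' start-codon aligned sequence set: \code{x-1} (linkage joining the last
#' base of the preceding codon to codon position 1), \code{1-2}, \code{2-3}
#' (internal linkages) and \code{3-z} (joining codon position 3 to the next
#' codon), together with a one-way ANOVA across phases on the position-level
#' IC values.
#'
#' @slot phaseMeans named numeric(4), mean linkage IC per phase (bits).
#' @slot phaseN positions contributing to each phase.
#' @slot perPhase list of per-position IC vectors, one per phase.
#' @slot fStat,pValue one-way ANOVA across the four phases (NA if any phase
#'   has fewer than 2 positions).
#' @slot anchor the start-codon anchor used.
#' @exportClass CodonPhaseSummary
setClass("CodonPhaseSummary",
    representation(
        phaseMeans = "numeric", phaseN = "integer", perPhase = "list",
        fStat = "numeric", pValue = "numeric", anchor = "integer"
    )
)

setValidity("CodonPhaseSummary", function(object) {
    msg <- character()
    ph <- c("x-1", "1-2", "2-3", "3-z")
    if (!identical(names(object@phaseMeans), ph))
        msg <- c(msg, "phaseMeans must be named x-1, 1-2, 2-3, 3-z")
    if (!identical(names(object@perPhase), ph))
        msg <- c(msg, "perPhase must be named x-1, 1-2, 2-3, 3-z")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic transcription-factor binding-site set
#'
#' Describes the generator for motif-plus-flank sequence sets: an IUPAC
#' consensus, a per-position conservation level (probability that a motif
#' base is drawn from the consensus-consistent set), flank length and GC
#' fraction, and the number of sequences.
#'
#' @slot consensus IUPAC consensus string.
#' @slot conservation numeric in [0,1], recycled over motif positions.
#' @slot flankLength flanking bases on each side.
#' @slot flankGC GC fraction of the i.i.d. flanks.
#' @slot n number of sequences.
#' @slot seed optional RNG seed (NA = leave RNG state alone).
#' @exportClass MotifSpec
setClass("MotifSpec",
    representation(
        consensus = "character", conservation = "numeric",
        flankLength = "integer", flankGC = "numeric",
        n = "integer", seed = "integer"
    )
)

setValidity("MotifSpec", function(object) {
    msg <- character()
    if (nchar(object@consensus) < 1L)
        msg <- c(msg, "consensus must be non-empty")
    if (any(!strsplit(object@consensus, "")[[1]] %in% names(.iupacMap())))
        msg <- c(msg, "consensus contains invalid IUPAC symbols")
    if (any(object@conservation < 0 | object@conservation > 1))
        msg <- c(msg, "conservation must lie in [0,1]")
    if (object@flankGC < 0 || object@flankGC > 1)
        msg <- c(msg, "flankGC must lie in [0,1]")
    if (object@flankLength < 0L)
        msg <- c(msg, "flankLength must be >= 0")
    if (object@n < 1L)
        msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
})
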