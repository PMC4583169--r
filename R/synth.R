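# Synthetic sequence-set generators: motif-plus-flank binding-site sets
# (JASPAR-writable) and start-codon aligned coding sets, so every analysis
# is testable without external genome downloads.

#' Construct a MotifSpec
#'
#' @param consensus IUPAC consensus string.
#' @param conservation probability that each motif base is drawn from its
#'   consensus-consistent set (off-consensus draws are uniform over the
#'   remaining bases); scalar or per-position, in [0, 1].
#' @param flankLength flank bases on either side (default 7, the usual
#'   span reported around confirmed consensus matches; use 25 for the
#'   wide-flank preset).
#' @param flankGC GC fraction of the i.i.d. flanks.
#' @param n number of sequences to generate.
#' @param seed optional RNG seed.
#' @return A \linkS4class{MotifSpec}.
#' @export
MotifSpec <- function(consensus, conservation = 0.85, flankLength = 7L,
                      flankGC = 0.5, n = 100L, seed = NA) {
    new("MotifSpec", consensus = toupper(consensus),
        conservation = rep_len(conservation, nchar(consensus)),
        flankLength = as.integer(flankLength), flankGC = flankGC,
        n = as.integer(n), seed = as.integer(seed))
}

#' Generate a synthetic transcription-factor binding-site set
#'
#' Each sequence is flank + motif + flank.  Motif base \code{i} is drawn
#' uniformly from the consensus-consistent base set with probability
#' \code{conservation[i]}, otherwise uniformly from the complementary
#' bases; flanks are i.i.d. with the requested GC fraction.  The motif
#' span is recorded, so the set round-trips through the JASPAR dialect
#' (uppercase core, lowercase flanks).
#'
#' @param spec a \linkS4class{MotifSpec}.
#' @return A \linkS4class{SequenceSet} with \code{motifSpan} set.
#' @examples
#' ss <- generateTFBS(MotifSpec("CATG", conservation = 1, n = 5, seed = 1))
#' icBase(logoProfile(ss))[8:11]   # 2 bits at every motif column
#' @export
generateTFBS <- function(spec) {
    if (!is.na(spec@seed)) set.seed(spec@seed)
    n <- spec@n
    w <- nchar(spec@consensus)
    fl <- spec@flankLength
    iupac <- .iupacMap()
    cons <- strsplit(spec@consensus, "")[[1]]
    motif <- matrix("", n, w)
    for (i in seq_len(w)) {
        onSet <- iupac[[cons[i]]]
        offSet <- setdiff(.BASES, onSet)
        if (!length(offSet)) offSet <- .BASES   # N-like column: all uniform
        on <- stats::runif(n) < spec@conservation[i]
        motif[, i] <- ifelse(on,
                             sample(onSet, n, replace = TRUE),
                             sample(offSet, n, replace = TRUE))
    }
    g <- spec@flankGC
    comp <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    flank <- function() {
        if (fl == 0L) return(rep("", n))
        m <- matrix(sample(.BASES, n * fl, replace = TRUE, prob = comp),
                    nrow = n)
        apply(m, 1L, paste0, collapse = "")
    }
    seqs <- paste0(flank(), apply(motif, 1L, paste0, collapse = ""), flank())
    SequenceSet(seqs, labels = paste0("site", seq_len(n)),
                motifStart = fl + 1L, motifEnd = fl + w)
}

# the 61 sense codons of the standard genetic code
.senseCodons <- function() {
    all64 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
    gc <- Biostrings::GENETIC_CODE
    sort(all64[gc[all64] != "*"])
}

#' Generate a start-codon aligned synthetic coding set
#'
#' Each gene is a random untranslated region followed by \code{nCodons}
#' codons, the first forced to ATG; the remaining codons are sampled
#' i.i.d. from a codon-usage table over the 61 sense codons (uniform by
#' default).  The anchor records the position of the A of ATG.
#'
#' @param nGenes number of genes.
#' @param nCodons codons per gene, including the start codon.
#' @param codonWeights named non-negative weights over sense codons
#'   (normalized internally); NULL for uniform usage.  Stop codons are
#'   rejected.
#' @param utrLength length of the upstream non-coding region (default 25).
#' @param utrComposition base probabilities of the UTR (uniform default).
#' @param seed optional RNG seed.
#' @return A \linkS4class{SequenceSet} with the anchor set.
#' @examples
#' g <- generateCodingSet(10, 5, seed = 1)
#' anchorPosition(g)   # 26
#' @export
generateCodingSet <- function(nGenes, nCodons, codonWeights = NULL,
                              utrLength = 25L,
                              utrComposition = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                              seed = NULL) {
    nGenes <- as.integer(nGenes)
    nCodons <- as.integer(nCodons)
    utrLength <- as.integer(utrLength)
    if (nGenes < 1L || nCodons < 1L || utrLength < 0L)
        validationError("nGenes and nCodons must be >= 1, utrLength >= 0")
    sense <- .senseCodons()
    if (is.null(codonWeights)) {
        codonWeights <- stats::setNames(rep(1, length(sense)), sense)
    } else {
        if (is.null(names(codonWeights)) ||
            !all(names(codonWeights) %in% sense))
            validationError("codonWeights must be named by sense codons (no stop codons)")
        if (any(codonWeights < 0) || sum(codonWeights) <= 0)
            validationError("codonWeights must be non-negative with positive sum")
        codonWeights <- codonWeights[names(codonWeights)]
    }
    if (!setequal(names(utrComposition), .BASES) ||
        abs(sum(utrComposition) - 1) > 1e-8 || any(utrComposition < 0))
        validationError("utrComposition must be probabilities over A,C,G,T")
    if (!is.null(seed)) set.seed(seed)
    utr <- if (utrLength > 0L) {
        m <- matrix(sample(.BASES, nGenes * utrLength, replace = TRUE,
                           prob = utrComposition[.BASES]), nrow = nGenes)
        apply(m, 1L, paste0, collapse = "")
    } else rep("", nGenes)
    body <- if (nCodons > 1L) {
        m <- matrix(sample(names(codonWeights), nGenes * (nCodons - 1L),
                           replace = TRUE, prob = codonWeights),
                    nrow = nGenes)
        apply(m, 1L, paste0, collapse = "")
    } else rep("", nGenes)
    SequenceSet(paste0(utr, "ATG", body),
                labels = paste0("gene", seq_len(nGenes)),
                anchor = utrLength + 1L)
}
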