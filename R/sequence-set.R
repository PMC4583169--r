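#' Construct a SequenceSet
#'
#' @param sequences character vector of equal-length sequences; uppercased,
#'   with non-ACGT characters mapped to N.
#' @param labels optional per-sequence identifiers.
#' @param motifStart,motifEnd optional 1-based motif core bounds.
#' @param anchor optional 1-based alignment anchor (e.g. the A of ATG).
#' @return A \linkS4class{SequenceSet}.
#' @examples
#' ss <- SequenceSet(c("ACGT", "ACGA"))
#' seqWidth(ss); nSequences(ss)
#' @export
SequenceSet <- function(sequences, labels = character(),
                        motifStart = NA, motifEnd = NA, anchor = NA) {
    new("SequenceSet",
        sequences = .normalizeSeq(sequences),
        labels = as.character(labels),
        motifStart = as.integer(motifStart),
        motifEnd = as.integer(motifEnd),
        anchor = as.integer(anchor))
}

# uppercase and collapse everything outside {A,C,G,T} to N
.normalizeSeq <- function(x) {
    x <- toupper(unname(x))
    gsub("[^ACGTN]", "N", x)
}

#' @rdname SequenceSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname SequenceSet-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname SequenceSet-accessors
#' @export
setGeneric("seqWidth", function(x) standardGeneric("seqWidth"))

#' @rdname SequenceSet-accessors
#' @export
setGeneric("motifSpan", function(x) standardGeneric("motifSpan"))

#' @rdname SequenceSet-accessors
#' @export
setGeneric("anchorPosition", function(x) standardGeneric("anchorPosition"))

#' @rdname SequenceSet-accessors
#' @export
setGeneric("seqLabels", function(x) standardGeneric("seqLabels"))

#' Accessors for SequenceSet
#'
#' \code{sequences} returns the sequence strings, \code{nSequences} and
#' \code{seqWidth} the dimensions, \code{motifSpan} the (start, end) of the
#' aligned motif core (or NAs), \code{anchorPosition} the alignment anchor,
#' \code{seqLabels} the identifiers.
#'
#' @param x a \linkS4class{SequenceSet}.
#' @name SequenceSet-accessors
#' @aliases sequences nSequences seqWidth motifSpan anchorPosition seqLabels
NULL

#' @rdname SequenceSet-accessors
#' @export
setMethod("sequences", "SequenceSet", function(x) x@sequences)

#' @rdname SequenceSet-accessors
#' @export
setMethod("nSequences", "SequenceSet", function(x) length(x@sequences))

#' @rdname SequenceSet-accessors
#' @export
setMethod("seqWidth", "SequenceSet", function(x) nchar(x@sequences[1L]))

#' @rdname SequenceSet-accessors
#' @export
setMethod("motifSpan", "SequenceSet", function(x)
    c(start = x@motifStart, end = x@motifEnd))

#' @rdname SequenceSet-accessors
#' @export
setMethod("anchorPosition", "SequenceSet", function(x) x@anchor)

#' @rdname SequenceSet-accessors
#' @export
setMethod("seqLabels", "SequenceSet", function(x) x@labels)

#' Subset a SequenceSet by sequence index
#'
#' @param x a \linkS4class{SequenceSet}.
#' @param i sequence indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SequenceSet", function(x, i, j, ..., drop = FALSE) {
    new("SequenceSet", sequences = x@sequences[i],
        labels = if (length(x@labels)) x@labels[i] else character(),
        motifStart = x@motifStart, motifEnd = x@motifEnd, anchor = x@anchor)
})

#' Reverse complement of every sequence in a set
#'
#' Positional metadata (motif span, anchor) is mirrored onto the reversed
#' coordinates.
#'
#' @param x a \linkS4class{SequenceSet}.
#' @return A \linkS4class{SequenceSet} on the opposite strand.
#' @importFrom Biostrings reverseComplement
#' @export
#' @name reverseComplement
#' @aliases reverseComplement,SequenceSet-method
reverseComplement <- Biostrings::reverseComplement

#' @rdname reverseComplement
#' @export
setMethod("reverseComplement", "SequenceSet", function(x, ...) {
    L <- seqWidth(x)
    new("SequenceSet", sequences = .revcompString(x@sequences),
        labels = x@labels,
        motifStart = if (is.na(x@motifEnd)) NA_integer_ else L - x@motifEnd + 1L,
        motifEnd = if (is.na(x@motifStart)) NA_integer_ else L - x@motifStart + 1L,
        anchor = if (is.na(x@anchor)) NA_integer_ else L - x@anchor + 1L)
})

#' @describeIn SequenceSet compact display.
#' @param object a \code{SequenceSet}.
#' @export
setMethod("show", "SequenceSet", function(object) {
    cat("SequenceSet: ", nSequences(object), " sequences of length ",
        seqWidth(object), "\n", sep = "")
    if (!is.na(object@motifStart))
        cat("  motif span: ", object@motifStart, "-", object@motifEnd,
            "\n", sep = "")
    if (!is.na(object@anchor))
        cat("  anchor: ", object@anchor, "\n", sep = "")
    k <- min(3L, nSequences(object))
    cat(paste0("  ", utils::head(object@sequences, k)), sep = "\n")
    if (nSequences(object) > k) cat("  ...\n")
})
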