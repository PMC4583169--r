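#' Load a TRX dinucleotide flexibility scale
#'
#' Reads the scale from a tab-delimited table with three columns
#' (\code{class}, \code{dimers}, \code{score}); \code{dimers} lists the
#' member dinucleotides of a strand-symmetric class, comma-separated, and
#' \code{'#'} starts a comment.  The loaded scale is validated against the
#' structural properties of the TRX scale: 10 strand-symmetric classes, 9
#' distinct scores, minimum 0, maximum 43, exactly one shared-score pair of
#' classes, and a positive rank correlation between score and dimer GC
#' content.  The table shipped with the package transcribes the published
#' BI-BII percent-occupancy values.
#'
#' @param file path to the scale table; defaults to the shipped table.
#' @return A \linkS4class{TRXScale} object.
#' @examples
#' sc <- defaultTRXScale()
#' trxScore(sc, c("CA", "TG", "AT", "CG"))
#' @export
TRXScale <- function(file = system.file("extdata", "trx_scale.tsv",
                                        package = "trxlogo")) {
    .checkFileExists(file)
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    need <- c("class", "dimers", "score")
    if (!all(need %in% names(tab)))
        validationError(sprintf(
            "TRX table must have columns %s", paste(need, collapse = ", ")))
    members <- strsplit(toupper(tab$dimers), ",[[:space:]]*")
    dimerClass <- rep(tab$class, lengths(members))
    dimerScore <- rep(as.numeric(tab$score), lengths(members))
    dimers <- unlist(members)
    if (anyDuplicated(dimers))
        validationError("TRX table assigns some dimer to more than one class")
    names(dimerClass) <- dimers
    names(dimerScore) <- dimers
    new("TRXScale", table = tab,
        dimerClass = dimerClass[.allDimers()],
        dimerScore = dimerScore[.allDimers()],
        symbols = sort(unique(unname(dimerScore))))
}

.scaleCache <- new.env(parent = emptyenv())

#' @rdname TRXScale
#' @export
defaultTRXScale <- function() {
    if (is.null(.scaleCache$default))
        .scaleCache$default <- TRXScale()
    .scaleCache$default
}

.checkDimers <- function(dimers) {
    dimers <- toupper(dimers)
    if (any(nchar(dimers) != 2L))
        validationError("dimers must be exactly 2 characters")
    dimers
}

#' Strand-symmetric class, TRX score and linkage state of a dinucleotide
#'
#' \code{dinucClass} returns the canonical class label of a dinucleotide
#' step (a dimer and its reverse complement always share a class, e.g.
#' CpA/TpG).  \code{trxScore} returns the TRX score of the class, in
#' [0, 43].  \code{stateSymbol} returns the linkage-state symbol used as
#' the 9-letter backbone alphabet: the score value itself, so the two
#' classes that share a score collapse into one symbol.  Dimers containing
#' a non-ACGT character yield \code{NA} (ambiguous; callers mask them).
#'
#' @param scale a \linkS4class{TRXScale}.
#' @param dimers character vector of 2-letter dimers (case-insensitive).
#' @return \code{dinucClass}: class labels; \code{trxScore}: numeric scores;
#'   \code{stateSymbol}: character symbols, one of 9 values.
#' @examples
#' sc <- defaultTRXScale()
#' dinucClass(sc, "CA") == dinucClass(sc, "TG")
#' length(unique(stateSymbol(sc, c(outer(c("A","C","G","T"),
#'                                       c("A","C","G","T"), paste0)))))
#' @export
dinucClass <- function(scale, dimers) {
    dimers <- .checkDimers(dimers)
    unname(scale@dimerClass[dimers])
}

#' @rdname dinucClass
#' @export
trxScore <- function(scale, dimers) {
    dimers <- .checkDimers(dimers)
    unname(scale@dimerScore[dimers])
}

#' @rdname dinucClass
#' @export
stateSymbol <- function(scale, dimers) {
    s <- trxScore(scale, dimers)
    ifelse(is.na(s), NA_character_, format(s, trim = TRUE))
}

#' Gray shade encoding mean TRX flexibility
#'
#' Linear map from mean TRX score to a gray level: 0 (no flexibility)
#' renders black (0.0) and 43 (high flexibility) renders white (1.0).
#'
#' @param meanTRX numeric in [0, 43]; NA passes through.
#' @return gray level(s) in [0, 1].
#' @examples
#' trxShade(c(0, 21.5, 43))
#' @export
trxShade <- function(meanTRX) {
    ok <- is.na(meanTRX) | (meanTRX >= 0 & meanTRX <= 43)
    if (!all(ok))
        validationError("meanTRX must lie in [0, 43]")
    meanTRX / 43
}

#' @describeIn TRXScale display the class/score table.
#' @param object a \code{TRXScale}.
#' @export
setMethod("show", "TRXScale", function(object) {
    cat("TRXScale: 10 dinucleotide classes, ",
        length(object@symbols), " distinct scores in [",
        min(object@symbols), ", ", max(object@symbols), "]\n", sep = "")
    print(object@table, row.names = FALSE)
})
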