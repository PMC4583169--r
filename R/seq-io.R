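# Readers for the three input dialects (plain one-per-line, FASTA with
# whole-record center alignment, JASPAR FASTA with uppercase motif core)
# and the PWM writer.  Gap characters ('-', '.') are stripped before any
# alignment; other non-ACGT characters become N.

.stripGaps <- function(x) gsub("[-.]", "", x)

#' Read pre-aligned sequences, one per line
#'
#' The plain dialect assumes the file is already center aligned: every line
#' must have the same length after gap removal.
#'
#' @param path input file.
#' @return A \linkS4class{SequenceSet}.
#' @export
readPlainSeqs <- function(path) {
    .checkFileExists(path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        validationError(sprintf("no sequences in '%s'", path))
    lines <- .stripGaps(lines)
    w <- nchar(lines)
    if (length(unique(w)) != 1L) {
        bad <- which(w != w[1])[1]
        validationError(sprintf(
            "ragged input: line %d has length %d, expected %d (plain dialect assumes pre-aligned sequences)",
            bad, w[bad], w[1]))
    }
    SequenceSet(lines)
}

# case-preserving FASTA read via Biostrings
.readFastaRecords <- function(path) {
    .checkFileExists(path)
    recs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                     error = function(e)
                         validationError(sprintf(
                             "malformed FASTA in '%s': %s", path,
                             conditionMessage(e))))
    if (!length(recs))
        validationError(sprintf("no FASTA records in '%s'", path))
    x <- as.character(recs)
    names(x) <- names(recs)
    .stripGaps(x)
}

# trim a string to length Lmin about its center; for even spans the center
# is taken left-of-middle (floor((L+1)/2)), consistently everywhere
.centerTrim <- function(x, Lmin) {
    L <- nchar(x)
    c0 <- (L + 1L) %/% 2L
    cmin <- (Lmin + 1L) %/% 2L
    start <- c0 - cmin + 1L
    substr(x, start, start + Lmin - 1L)
}

#' Read FASTA with whole-record center alignment
#'
#' Records may differ in length; each is trimmed to the shortest record's
#' span about its own midpoint (this dialect assumes flanks on either side
#' of any consensus are of equal length, so midpoints line up).
#'
#' @param path input FASTA file.
#' @return A \linkS4class{SequenceSet}.
#' @export
readFastaSeqs <- function(path) {
    x <- .readFastaRecords(path)
    if (any(nchar(x) < 2L))
        validationError("records must have length >= 2 after gap removal")
    Lmin <- min(nchar(x))
    SequenceSet(.centerTrim(x, Lmin), labels = names(x))
}

#' Read JASPAR-style FASTA (uppercase motif core, lowercase flanks)
#'
#' Each record must contain exactly one maximal uppercase run, the
#' consensus motif.  Sequences are aligned on the motif centers and flanks
#' are trimmed to the largest width available in every record (no bases are
#' ever fabricated).  The common motif span is recorded; if motif lengths
#' differ across records the span of the shortest motif is kept, with a
#' warning.
#'
#' @param path input FASTA file.
#' @return A \linkS4class{SequenceSet} with \code{motifSpan} set.
#' @export
readJasparSeqs <- function(path) {
    x <- .readFastaRecords(path)
    runs <- gregexpr("[A-Z]+", x)
    nRuns <- vapply(runs, function(r) sum(r > 0L), 0L)
    if (any(nRuns != 1L)) {
        bad <- which(nRuns != 1L)[1]
        id <- if (!is.null(names(x))) names(x)[bad] else as.character(bad)
        validationError(sprintf(
            "record '%s' has %d uppercase runs; the JASPAR dialect requires exactly one consensus motif in capitals",
            id, nRuns[bad]))
    }
    mStart <- vapply(runs, function(r) r[1], 0L)
    mLen <- vapply(runs, function(r) attr(r, "match.length")[1], 0L)
    mEnd <- mStart + mLen - 1L
    if (length(unique(mLen)) > 1L)
        warning("uppercase motifs differ in length; trimming to the common span")
    L <- nchar(x)
    mc <- mStart + (mLen + 1L) %/% 2L - 1L   # motif center, left-of-middle
    leftFlank <- min(mc - 1L)
    rightFlank <- min(L - mc)
    out <- substr(x, mc - leftFlank, mc + rightFlank)
    mlHalf <- min(mc - mStart)
    mrHalf <- min(mEnd - mc)
    SequenceSet(out, labels = names(x),
                motifStart = leftFlank + 1L - mlHalf,
                motifEnd = leftFlank + 1L + mrHalf)
}

#' Read a sequence set in any of the three dialects
#'
#' @param path input file.
#' @param filetype one of \code{"plain"}, \code{"fasta"}, \code{"jaspar"}.
#' @return A \linkS4class{SequenceSet}.
#' @export
readSequenceSet <- function(path, filetype = c("plain", "fasta", "jaspar")) {
    if (length(filetype) != 1L || !filetype %in% c("plain", "fasta", "jaspar"))
        usageError(sprintf(
            "unrecognized filetype '%s'. Recognized values: plain, fasta, jaspar",
            paste(filetype, collapse = ",")))
    switch(filetype,
           plain = readPlainSeqs(path),
           fasta = readFastaSeqs(path),
           jaspar = readJasparSeqs(path))
}

#' Write a sequence set in any of the three dialects
#'
#' The JASPAR dialect requires a motif span and writes the motif core in
#' uppercase with lowercase flanks.
#'
#' @param x a \linkS4class{SequenceSet}.
#' @param path output file.
#' @param format one of \code{"plain"}, \code{"fasta"}, \code{"jaspar"}.
#' @return \code{path}, invisibly.
#' @export
writeSequenceSet <- function(x, path, format = c("plain", "fasta", "jaspar")) {
    format <- match.arg(format)
    seqs <- sequences(x)
    if (format == "jaspar") {
        span <- motifSpan(x)
        if (anyNA(span))
            validationError("jaspar output requires a motif span")
        L <- seqWidth(x)
        seqs <- paste0(tolower(substr(seqs, 1L, span[1] - 1L)),
                       substr(seqs, span[1], span[2]),
                       tolower(substr(seqs, span[2] + 1L, L)))
    }
    if (format == "plain") {
        writeLines(seqs, path)
    } else {
        labs <- if (length(seqLabels(x))) seqLabels(x) else
            paste0("seq", seq_along(seqs))
        writeLines(paste0(">", labs, "\n", seqs), path)
    }
    invisible(path)
}

#' Write and read a position weight matrix
#'
#' Tab-delimited: one row per symbol, one column per position, a header row
#' of 1-based positions.  Columns must sum to 1 (within 1e-9) wherever any
#' symbol was observed; all-zero columns mark unobserved positions.
#'
#' @param matrix numeric matrix with symbol rownames (4 base rows or 9
#'   TRX-state rows).
#' @param path output/input file.
#' @return \code{writePWM}: \code{path} invisibly; \code{readPWM}: the matrix.
#' @export
writePWM <- function(matrix, path) {
    cs <- colSums(matrix)
    if (any(cs > 0 & abs(cs - 1) > 1e-9))
        validationError("PWM columns must sum to 1 where observed")
    if (is.null(rownames(matrix)))
        validationError("PWM must have symbol rownames")
    df <- as.data.frame(matrix)
    names(df) <- as.character(seq_len(ncol(matrix)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       col.names = NA, row.names = TRUE)
    invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
    .checkFileExists(path)
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    as.matrix(df)
}
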