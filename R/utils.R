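# Internal helpers: alphabet tables, sequence <-> integer matrices, and the
# condition classes used for the CLI exit-code contract.

.BASES <- c("A", "C", "G", "T")

.allDimers <- function() {
    as.vector(outer(.BASES, .BASES, paste0))
}

.revcompDimers <- function(dimers) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vapply(strsplit(dimers, ""), function(b)
        paste0(comp[b[2]], comp[b[1]]), "")
}

.revcompString <- function(x) {
    chartr("ACGTN", "TGCAN", vapply(lapply(strsplit(x, ""), rev),
                                    paste0, "", collapse = ""))
}

.iupacMap <- function() {
    list(A = "A", C = "C", G = "G", T = "T",
         R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
         K = c("G", "T"), M = c("A", "C"),
         B = c("C", "G", "T"), D = c("A", "G", "T"),
         H = c("A", "C", "T"), V = c("A", "C", "G"),
         N = c("A", "C", "G", "T"))
}

# n x L integer matrix: A=1 C=2 G=3 T=4, N -> NA
.seqMatrix <- function(seqs) {
    n <- length(seqs)
    m <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE), .BASES),
                nrow = n, byrow = TRUE)
    m
}

# n x (L-1) matrix of TRX state indices (1..9 into scale@symbols); NA where
# either base of the dimer is N
.stateIndexMatrix <- function(seqMat, scale) {
    lut <- .stateLookup(scale)
    a <- seqMat[, -ncol(seqMat), drop = FALSE]
    b <- seqMat[, -1L, drop = FALSE]
    m <- lut[4L * (a - 1L) + b]
    dim(m) <- dim(a)
    m
}

# length-16 lookup: dimer code 4*(a-1)+b -> index into sorted symbols
.stateLookup <- function(scale) {
    dimers <- .allDimers()  # outer(.BASES,.BASES): "AA","CA","GA","TA","AC",...
    code <- vapply(strsplit(dimers, ""), function(b)
        4L * (match(b[1], .BASES) - 1L) + match(b[2], .BASES), 0L)
    lut <- integer(16L)
    lut[code] <- match(scale@dimerScore[dimers], scale@symbols)
    lut
}

# per-column symbol counts of an integer matrix with values 1..k (NA skipped)
.colCounts <- function(m, k) {
    J <- ncol(m)
    v <- as.integer(m) + k * rep.int(0:(J - 1L), rep.int(nrow(m), J))
    cnt <- tabulate(v[!is.na(v)], nbins = k * J)
    dim(cnt) <- c(k, J)
    cnt
}

# entropy (bits) of each column of a count matrix; NA for empty columns
.colEntropyFromCounts <- function(cnt) {
    ne <- colSums(cnt)
    p <- sweep(cnt, 2L, pmax(ne, 1L), "/")
    terms <- p * log2(p)
    terms[cnt == 0L] <- 0
    H <- -colSums(terms)
    H[ne == 0L] <- NA_real_
    H
}

# condition constructors; classes map onto CLI exit codes 2/3/4
.cond <- function(class, msg, call = sys.call(-1)) {
    structure(class = c(class, "error", "condition"),
              list(message = msg, call = call))
}

usageError <- function(msg) stop(.cond("trxlogo_usage_error", msg))
ioError <- function(msg) stop(.cond("trxlogo_io_error", msg))
validationError <- function(msg) stop(.cond("trxlogo_validation_error", msg))

.checkFileExists <- function(path) {
    if (!file.exists(path))
        ioError(sprintf("file not found: '%s'", path))
    invisible(path)
}
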