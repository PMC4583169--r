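# Independent brute-force oracle for information content: plain loops and
# table() counting, sharing no code with the package internals.  The TRX
# constants are re-read directly from the shipped table.

oracleScoreMap <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        tab <- read.table(system.file("extdata", "trx_scale.tsv",
                                      package = "trxlogo"),
                          header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
        m <- list()
        for (r in seq_len(nrow(tab)))
            for (d in strsplit(tab$dimers[r], ",")[[1]])
                m[[d]] <- tab$score[r]
        cache <<- m
        m
    }
})

oracleEntropy <- function(counts) {
    counts <- counts[counts > 0]
    p <- counts / sum(counts)
    h <- 0
    for (q in p) h <- h - q * log2(q)
    h
}

# per-column base IC by exhaustive counting; NA columns give 0
oracleBaseIC <- function(seqStrings) {
    chars <- lapply(seqStrings, function(s) strsplit(s, "")[[1]])
    L <- length(chars[[1]])
    ic <- numeric(L)
    for (i in seq_len(L)) {
        col <- vapply(chars, `[`, "", i)
        col <- col[col %in% c("A", "C", "G", "T")]
        if (!length(col)) { ic[i] <- 0; next }
        ic[i] <- 2 - oracleEntropy(table(col))
    }
    ic
}

# per-linkage IC over the 9 TRX states by exhaustive counting
oracleLinkIC <- function(seqStrings) {
    smap <- oracleScoreMap()
    L <- nchar(seqStrings[1])
    ic <- numeric(L - 1)
    for (j in seq_len(L - 1)) {
        dimers <- substr(seqStrings, j, j + 1)
        dimers <- dimers[!grepl("N", dimers)]
        if (!length(dimers)) { ic[j] <- 0; next }
        states <- vapply(dimers, function(d) smap[[d]], 0)
        ic[j] <- log2(9) - oracleEntropy(table(states))
    }
    ic
}

randomSeqStrings <- function(n, L, alphabet = c("A", "C", "G", "T")) {
    vapply(seq_len(n), function(i)
        paste0(sample(alphabet, L, replace = TRUE), collapse = ""), "")
}
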