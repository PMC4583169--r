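# Fixture writers: every test input is generated in code at run time.

writeTempLines <- function(lines, ext = ".txt") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

writeTempFasta <- function(seqs, ext = ".fasta", names = NULL) {
    if (!length(seqs)) return(writeTempLines(character(0), ext))
    if (is.null(names)) names <- paste0("rec", seq_along(seqs))
    writeTempLines(paste0(">", names, "\n", seqs), ext)
}

allDimerStrings <- function() {
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    function(a, b) paste0(a, b)))
}

revcompDimer <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    b <- strsplit(d, "")[[1]]
    paste0(comp[b[2]], comp[b[1]])
}
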