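#' RY-recode nucleotide sequences
#'
#' Collapses nucleotides to purines (`R` = A, G) and pyrimidines
#' (`Y` = C, T/U) to damp compositional (GC-content) heterogeneity across
#' lineages before tree inference. Gap characters (`-`, `.`) are preserved.
#' IUPAC ambiguity codes that resolve within one class keep that class
#' (only `R` and `Y` themselves do); all other ambiguity codes span both
#' classes and become missing (`?`), a conservative treatment.
#'
#' @param x character vector of nucleotide sequences (case-insensitive).
#' @return character vector of the same length over the alphabet
#'   `R`, `Y`, `?`, `-`, `.`.
#' @examples
#' ryRecode("ACGT")  # "RYRY"
#' ryRecode("A-G")   # "R-R"
#' ryRecode("ANT")   # "R?Y"
#' @export
ryRecode <- function(x) {
    stopifnot(is.character(x))
    map <- c(A = "R", G = "R", R = "R",
             C = "Y", T = "Y", U = "Y", Y = "Y",
             W = "?", S = "?", K = "?", M = "?",
             B = "?", D = "?", H = "?", V = "?", N = "?",
             "-" = "-", "." = ".", "?" = "?")
    vapply(x, function(seq) {
        chars <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
        bad <- which(!chars %in% names(map))
        if (length(bad))
            stop(sprintf("non-IUPAC character '%s' at position %d",
                         chars[bad[1]], bad[1]), call. = FALSE)
        paste(map[chars], collapse = "")
    }, character(1), USE.NAMES = !is.null(names(x)))
}

#' RY-recode a FASTA file
#'
#' @param infile input FASTA of nucleotide sequences.
#' @param outfile output FASTA of RY-recoded sequences.
#' @return `outfile`, invisibly.
#' @export
ryRecodeFasta <- function(infile, outfile) {
    seqs <- Biostrings::readBStringSet(infile)
    rec <- ryRecode(setNames(as.character(seqs), names(seqs)))
    Biostrings::writeXStringSet(Biostrings::BStringSet(rec), outfile)
    invisible(outfile)
}
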