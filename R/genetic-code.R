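#' @importFrom Biostrings GENETIC_CODE
NULL

# Most-used codon per amino acid in human coding sequence (ties broken
# alphabetically); any synonymous choice gives the same protein-level
# library, this only fixes which codon encodes each programmed change.
.PREFERRED_CODON <- c(
    A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
    H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
    P = "CCC", Q = "CAG", R = "AGA", S = "AGC", T = "ACC", V = "GTG",
    W = "TGG", Y = "TAC", `*` = "TGA")

.AA20 <- sort(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*"))

.checkCodon <- function(codon, what = "codon") {
    if (!is.character(codon) || any(nchar(codon) != 3L) ||
        any(grepl("[^ACGT]", codon)))
        stop(what, " must be 3-mer(s) over {A,C,G,T}: ",
             paste(utils::head(codon), collapse = ", "))
    invisible(codon)
}

.translateOrf <- function(seq) {
    codons <- substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
                        seq(3L, nchar(seq), by = 3L))
    unname(Biostrings::GENETIC_CODE[codons])
}

#' Translate a codon under the standard genetic code
#'
#' Total function over all 64 codons; stop codons translate to `"*"`.
#'
#' @param codon character vector of 3-mers over \{A,C,G,T\}.
#' @return Character vector of one-letter amino-acid codes (`"*"` for stop).
#' @examples
#' translateCodon(c("ATG", "TGA", "TGG"))  # "M" "*" "W"
#' @export
translateCodon <- function(codon) {
    .checkCodon(codon)
    unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a codon substitution
#'
#' Consequence is fully determined by the standard genetic code: `silent`
#' when both codons encode the same amino acid, `nonsense` when the
#' alternate codon is a stop, `missense` otherwise.
#'
#' @param ref_codon,alt_codon 3-mers over \{A,C,G,T\}; `ref_codon` must not
#'   be a stop codon. Both arguments are vectorized.
#' @return Character vector over \{"silent", "missense", "nonsense"\}.
#' @examples
#' classifySubstitution("AAA", "AAG")  # silent (K -> K)
#' classifySubstitution("TGG", "CCG")  # missense (W -> P)
#' classifySubstitution("TGG", "TGA")  # nonsense
#' @export
classifySubstitution <- function(ref_codon, alt_codon) {
    ref_aa <- translateCodon(ref_codon)
    alt_aa <- translateCodon(alt_codon)
    if (any(ref_aa == "*"))
        stop("ref_codon must not be a stop codon")
    ifelse(alt_aa == "*", "nonsense",
           ifelse(ref_aa == alt_aa, "silent", "missense"))
}
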