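# Standard ("universal") genetic code tables used throughout the package.
# Codons are stored in alphabetical order (AAA..TTT); that order is the
# documented column order of every codon-count vector and matrix.

.tcag <- c("T", "C", "A", "G")
.codons_tcag <- paste0(rep(.tcag, each = 16),
                       rep(rep(.tcag, each = 4), 4),
                       rep(.tcag, 16))
.aa_tcag <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]

#' @noRd
.CODONS <- sort(.codons_tcag)

#' @noRd
.CODON_AA <- {
  aa <- stats::setNames(.aa_tcag, .codons_tcag)
  aa[.CODONS]
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- .CODONS[!(.CODONS %in% .STOP_CODONS)]
.SINGLE_CODONS <- c(M = "ATG", W = "TGG")
# the 59 codons with synonymous alternatives (sense minus ATG, TGG)
.VARIABLE_CODONS <- setdiff(.SENSE_CODONS, .SINGLE_CODONS)

# amino acid -> synonymous codon family (six-fold Leu/Ser/Arg kept whole)
.FAMILIES <- split(.SENSE_CODONS, .CODON_AA[.SENSE_CODONS])
.DEGENERACY <- vapply(.FAMILIES, length, integer(1))

# third-position G/C indicator per codon
.THIRD_GC <- stats::setNames(substr(.CODONS, 3, 3) %in% c("G", "C"), .CODONS)

#' The standard genetic code used by codonscope
#'
#' Returns the code tables every statistic in the package is defined on:
#' the standard ("universal") nuclear code, with the three six-fold
#' degenerate amino acids (Leu, Ser, Arg) treated as single families of
#' size six so that RSCU values over a family sum to the family size.
#'
#' @return A list with elements
#'   \item{codons}{all 64 codons, alphabetical; the canonical column order}
#'   \item{amino_acid}{named character, codon -> one-letter amino acid
#'     (`*` for stops)}
#'   \item{stop_codons}{`TAA`, `TAG`, `TGA`}
#'   \item{sense_codons}{the 61 coding codons}
#'   \item{variable_codons}{the 59 sense codons excluding `ATG` and `TGG`}
#'   \item{families}{list, amino acid -> synonymous codon set}
#'   \item{degeneracy}{named integer, amino acid -> family size}
#' @examples
#' code <- genetic_code()
#' code$degeneracy[c("L", "I", "M")]
#' @export
genetic_code <- function() {
  list(codons = .CODONS,
       amino_acid = .CODON_AA,
       stop_codons = .STOP_CODONS,
       sense_codons = .SENSE_CODONS,
       variable_codons = .VARIABLE_CODONS,
       families = .FAMILIES,
       degeneracy = .DEGENERACY)
}

#' Number of G or C bases in each codon
#'
#' The "GC weight" of a codon: how many of its three positions are G or C
#' (0--3).  Used to colour pooled RSCU distributions.
#'
#' @param codons character vector of codons; defaults to all 64.
#' @return named integer vector in 0..3.
#' @export
codon_gc_weight <- function(codons = .CODONS) {
  stats::setNames(
    vapply(strsplit(toupper(codons), ""),
           function(b) sum(b %in% c("G", "C")), integer(1)),
    codons)
}
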