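## Genetic-code plumbing. The single source of truth for the standard code
## is Biostrings::GENETIC_CODE; everything in the package translates
## through codonToAa() below.

BASES <- c("A", "C", "G", "T")

## Canonicalize a DNA string: uppercase, RNA U -> T; error on anything
## outside {A, C, G, T}.
normalizeDna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- setdiff(strsplit(x, "")[[1]], BASES)
  if (length(bad))
    stop("invalid DNA character(s): ", paste(unique(bad), collapse = ", "))
  x
}

checkCodon <- function(codon) {
  codon <- normalizeDna(codon)
  if (nchar(codon) != 3L)
    stop("a codon must be exactly 3 bases, got '", codon, "'")
  codon
}

## Translate codons ("ATG" -> "M"); stop codons give "*".
codonToAa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

## Split a CDS into its codons; errors if length is not a multiple of 3.
splitCodons <- function(cds) {
  cds <- normalizeDna(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("coding sequence length (", n, ") is not a multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding DNA sequence
#'
#' Translates under the standard genetic code, optionally dropping the
#' initiator methionine so residue numbering matches a post-cleavage
#' protein (numbering begins after the removed Met).
#'
#' @param cds a DNA string (character); length must be a multiple of 3.
#'   A terminal stop codon is allowed and dropped; internal stops error.
#' @param removeInitialMet logical; drop the first residue, which must
#'   then be encoded by ATG.
#' @return the protein as a single character string of one-letter codes.
#' @examples
#' translateCds("ATGGCATGG")                      # "MAW"
#' translateCds("ATGGCATGG", removeInitialMet = TRUE)  # "AW"
#' @export
translateCds <- function(cds, removeInitialMet = FALSE) {
  codons <- splitCodons(cds)
  aa <- codonToAa(codons)
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  if (any(aa == "*"))
    stop("internal stop codon at codon position ",
         paste(which(aa == "*"), collapse = ", "))
  if (removeInitialMet) {
    if (!length(aa) || codons[1L] != "ATG")
      stop("removeInitialMet requires the CDS to begin with ATG")
    aa <- aa[-1L]
  }
  paste(aa, collapse = "")
}
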