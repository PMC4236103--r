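#' Single-nucleotide neighbors of a codon
#'
#' Returns the nine codons that differ from the input at exactly one
#' position. The input codon itself is never included.
#'
#' @param codon a 3-base DNA string (U accepted and mapped to T).
#' @return character vector of 9 codons.
#' @examples
#' singleNtNeighbors("ATG")
#' @export
singleNtNeighbors <- function(codon) {
  codon <- checkCodon(codon)
  b <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(BASES, b[pos])) {
      nb <- b
      nb[pos] <- alt
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

#' Amino-acid changes accessible within one DNA change
#'
#' Translates the nine single-nucleotide neighbors of a codon and returns
#' the distinct amino acids they encode, excluding the codon's own amino
#' acid (synonymous changes) and stop codons (nonsense changes are not
#' amino-acid substitutions).
#'
#' @param codon a sense codon (must not encode a stop).
#' @return character vector of one-letter amino acids, sorted.
#' @examples
#' accessibleAaChanges("ATG")  # L V K T R I
#' accessibleAaChanges("TGG")  # TAG/TGA neighbors are stops, excluded
#' @export
accessibleAaChanges <- function(codon) {
  codon <- checkCodon(codon)
  self <- codonToAa(codon)
  if (self == "*")
    stop("codon '", codon, "' is a stop codon")
  aa <- codonToAa(singleNtNeighbors(codon))
  sort(setdiff(unique(aa), c(self, "*")))
}

#' Enumerate substitutions accessible from a coding sequence
#'
#' For every codon of the CDS, collects the amino-acid changes reachable
#' by one nucleotide mutation (excluding synonymous and nonsense changes).
#' Multiple mutational routes to the same amino acid at a site collapse to
#' a single key. With \code{removeInitialMet} the initiator ATG is skipped
#' and numbering starts at 1 on the following residue, matching
#' post-cleavage numbering of mature proteins.
#'
#' @param cds coding DNA string; length a multiple of 3, no internal stop
#'   (a terminal stop codon is allowed and ignored).
#' @param removeInitialMet logical, default TRUE.
#' @return data.frame with columns \code{site}, \code{aa_from},
#'   \code{aa_to}, one row per accessible substitution, ordered by site
#'   then target amino acid.
#' @examples
#' enumerateAccessible("ATGGCATGG")  # 11 keys over 2 sites
#' @export
enumerateAccessible <- function(cds, removeInitialMet = TRUE) {
  codons <- splitCodons(cds)
  aa <- codonToAa(codons)
  if (length(aa) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*"))
    stop("internal stop codon at codon position ",
         paste(which(aa == "*"), collapse = ", "))
  if (removeInitialMet) {
    if (!length(codons) || codons[1L] != "ATG")
      stop("removeInitialMet requires the CDS to begin with ATG")
    codons <- codons[-1L]
    aa <- aa[-1L]
  }
  res <- lapply(seq_along(codons), function(i) {
    to <- accessibleAaChanges(codons[i])
    if (!length(to)) return(NULL)
    data.frame(site = i, aa_from = aa[i], aa_to = to,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(site = integer(0), aa_from = character(0),
                      aa_to = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate all possible single substitutions of a protein
#'
#' Every non-identical target amino acid at every site: exactly 19 * L
#' keys for a protein of length L.
#'
#' @param protein amino-acid string over the 20-letter alphabet.
#' @return data.frame with columns \code{site}, \code{aa_from},
#'   \code{aa_to}.
#' @examples
#' nrow(enumerateAll("AW"))  # 38
#' @export
enumerateAll <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  aa <- strsplit(toupper(protein), "")[[1]]
  checkAaLetters(aa, "residue")
  if (!length(aa))
    return(data.frame(site = integer(0), aa_from = character(0),
                      aa_to = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_along(aa), function(i) {
    data.frame(site = i, aa_from = aa[i],
               aa_to = setdiff(AA_ALPHABET, aa[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a coding sequence from FASTA or GenBank
#'
#' FASTA files are read with Biostrings; the first record is used unless
#' \code{gene} matches a record name. GenBank flat files are parsed for
#' CDS features; when \code{gene} is given, the CDS whose \code{/gene}
#' qualifier matches is extracted from the ORIGIN sequence (simple,
#' complement and join locations are supported), otherwise the full
#' ORIGIN sequence is returned.
#'
#' @param path file path.
#' @param format "fasta" or "genbank"; guessed from the extension when
#'   missing (.gb/.gbk/.genbank vs anything else).
#' @param gene optional gene name selecting a record/CDS feature.
#' @return a DNA string (character).
#' @export
readCds <- function(path, format = c("auto", "fasta", "genbank"),
                    gene = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (!length(set)) stop("no sequences in ", path)
    i <- 1L
    if (!is.null(gene)) {
      hit <- grep(gene, names(set), fixed = TRUE)
      if (!length(hit)) stop("no FASTA record matching gene '", gene, "'")
      i <- hit[1L]
    }
    return(normalizeDna(as.character(set[[i]])))
  }
  readGenBankCds(path, gene)
}

## Minimal GenBank flat-file reader: ORIGIN sequence plus CDS extraction
## by /gene qualifier. Handles "a..b", "complement(a..b)" and
## "join(a..b,c..d)" locations.
readGenBankCds <- function(path, gene = NULL) {
  lines <- readLines(path, warn = FALSE)
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("no ORIGIN block in ", path)
  seqLines <- lines[(oi[1L] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  full <- normalizeDna(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (is.null(gene)) return(full)

  fi <- grep("^FEATURES", lines)
  if (!length(fi)) stop("no FEATURES block in ", path)
  feat <- lines[(fi[1L] + 1L):(oi[1L] - 1L)]
  keyLine <- grepl("^ {5}\\S", feat)
  starts <- which(keyLine)
  loc <- NULL
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- if (k < length(starts)) starts[k + 1L] - 1L else length(feat)
    block <- feat[i0:i1]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1L])
    if (key != "CDS") next
    txt <- paste(gsub("^\\s+", "", block), collapse = " ")
    if (grepl(paste0("/gene=\"", gene, "\""), txt, fixed = TRUE)) {
      loc <- sub("^CDS\\s+(\\S+).*", "\\1", gsub("\\s+", " ", txt))
      break
    }
  }
  if (is.null(loc)) stop("no CDS feature with /gene=\"", gene, "\"")
  extractLocation(full, loc)
}

extractLocation <- function(seqstr, loc) {
  comp <- FALSE
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  pieces <- vapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", p))[[1]]
    if (length(m) != 3L) stop("unsupported location element: ", p)
    substr(seqstr, as.integer(m[2]), as.integer(m[3]))
  }, character(1))
  out <- paste(pieces, collapse = "")
  if (comp)
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  out
}

#' Write substitution keys as TSV
#'
#' Writes the (site, aa.from, aa.to) columns in the supplementary-table
#' header dialect.
#'
#' @param keys data.frame with columns \code{site}, \code{aa_from},
#'   \code{aa_to} (as returned by [enumerateAccessible()]).
#' @param path output file path.
#' @export
writeSubstitutionKeys <- function(keys, path) {
  out <- data.frame(site = keys$site, aa.from = keys$aa_from,
                    aa.to = keys$aa_to, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
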