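## Internal helpers shared across modules.

## The 20 proteinogenic amino acids, one-letter, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards so package functions never clobber user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Format and parse compact substitution keys
#'
#' A substitution key identifies one amino-acid change as
#' \code{<aa_from><site><aa_to>}, e.g. \code{"A15T"} for Ala15 to Thr.
#' Sites are 1-based residue indices (post-cleavage numbering when the
#' initiator methionine has been removed).
#'
#' @param site integer vector of residue positions (>= 1).
#' @param aaFrom,aaTo one-letter amino-acid codes.
#' @param keys character vector of compact keys such as \code{"A15T"}.
#' @return \code{formatSubKey} returns a character vector;
#'   \code{parseSubKey} a data.frame with columns \code{site},
#'   \code{aa_from}, \code{aa_to}.
#' @examples
#' formatSubKey(15, "A", "T")
#' parseSubKey(c("A15T", "K92R"))
#' @export
formatSubKey <- function(site, aaFrom, aaTo) {
  stopifnot(length(site) == length(aaFrom), length(site) == length(aaTo))
  paste0(aaFrom, site, aaTo)
}

#' @rdname formatSubKey
#' @export
parseSubKey <- function(keys) {
  m <- regmatches(keys, regexec("^([A-Y])([0-9]+)([A-Y])$", keys))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed substitution key(s): ",
         paste(keys[bad], collapse = ", "))
  data.frame(
    site = as.integer(vapply(m, `[`, character(1), 3L)),
    aa_from = vapply(m, `[`, character(1), 2L),
    aa_to = vapply(m, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

## Validate a vector of one-letter amino acids; returns invisibly or stops.
checkAaLetters <- function(x, what = "amino acid") {
  bad <- !(x %in% AA_ALPHABET)
  if (any(bad))
    stop("invalid ", what, " letter(s): ",
         paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}
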