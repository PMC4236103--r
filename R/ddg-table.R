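## Canonical column order/names of the on-disk TSV dialect and their
## internal counterparts.
DDG_FILE_COLS <- c("site", "aa.from", "aa.to", "within.1.DNA.change",
                   "wild.phg.sub", "lab.exp.sub", "ddG.fold", "ddG.bind")
DDG_INT_COLS <- c("site", "aa_from", "aa_to", "accessible", "wild_phage",
                  "lab_experiment", "ddg_fold", "ddg_bind")

#' Construct a DdgTable
#'
#' @param subs data.frame with the internal columns \code{site},
#'   \code{aa_from}, \code{aa_to}, \code{accessible}, \code{wild_phage},
#'   \code{lab_experiment}, \code{ddg_fold}, \code{ddg_bind}.
#' @param proteinLength protein length L; defaults to \code{max(site)}.
#' @param referenceId free-text reference-sequence label.
#' @return a validated [DdgTable-class].
#' @export
DdgTable <- function(subs, proteinLength = NULL, referenceId = "") {
  subs <- as.data.frame(subs, stringsAsFactors = FALSE)
  if (is.null(proteinLength))
    proteinLength <- if (nrow(subs)) max(subs$site) else 1L
  subs$site <- as.integer(subs$site)
  for (fl in c("accessible", "wild_phage", "lab_experiment"))
    subs[[fl]] <- as.integer(subs[[fl]])
  rownames(subs) <- NULL
  new("DdgTable", subs = subs[DDG_INT_COLS],
      proteinLength = as.integer(proteinLength),
      referenceId = as.character(referenceId))
}

#' @rdname DdgTable-accessors
setMethod("ddgData", "DdgTable", function(x) x@subs)

#' @rdname DdgTable-accessors
setMethod("proteinLength", "DdgTable", function(x) x@proteinLength)

#' @rdname DdgTable-accessors
setMethod("referenceId", "DdgTable", function(x) x@referenceId)

#' @rdname DdgTable-accessors
setMethod("accessibleSubs", "DdgTable", function(x) {
  d <- x@subs[x@subs$accessible == 1L, , drop = FALSE]
  rownames(d) <- NULL
  d
})

#' @rdname DdgTable-accessors
setMethod("observedSubs", "DdgTable", function(x, source = c("both", "wild",
                                                             "lab")) {
  source <- match.arg(source)
  keep <- switch(source,
    both = x@subs$wild_phage == 1L | x@subs$lab_experiment == 1L,
    wild = x@subs$wild_phage == 1L,
    lab = x@subs$lab_experiment == 1L)
  d <- x@subs[keep, , drop = FALSE]
  rownames(d) <- NULL
  d
})

setMethod("show", "DdgTable", function(object) {
  d <- object@subs
  cat("DdgTable:", nrow(d), "substitutions over", object@proteinLength,
      "residues\n")
  if (nzchar(object@referenceId))
    cat("  reference:", object@referenceId, "\n")
  cat("  accessible:", sum(d$accessible == 1L),
      "| wild phage:", sum(d$wild_phage == 1L),
      "| lab experiment:", sum(d$lab_experiment == 1L), "\n")
  complete <- nrow(d) == 19L * object@proteinLength
  cat("  complete (19*L rows):", complete, "\n")
})

#' Read a ddG substitution table
#'
#' Reads a tab-separated table in the supplementary-table dialect with
#' header columns \code{site}, \code{aa.from}, \code{aa.to},
#' \code{within.1.DNA.change}, \code{wild.phg.sub}, \code{lab.exp.sub},
#' \code{ddG.fold}, \code{ddG.bind}. In strict mode the table must be
#' complete: exactly 19 rows per site, one aa_from per site, 19 * L rows
#' total.
#'
#' @param path path to the TSV file.
#' @param strict logical; enforce completeness.
#' @param referenceId optional reference-sequence label to attach.
#' @return a [DdgTable-class].
#' @export
readDdgTable <- function(path, strict = FALSE, referenceId = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  miss <- setdiff(DDG_FILE_COLS, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  raw <- raw[DDG_FILE_COLS]
  names(raw) <- DDG_INT_COLS

  numify <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data line ",
           bad[1L], ": '", raw[[col]][bad[1L]], "'")
    v
  }
  raw$site <- as.integer(numify("site"))
  for (fl in c("accessible", "wild_phage", "lab_experiment"))
    raw[[fl]] <- as.integer(numify(fl))
  raw$ddg_fold <- numify("ddg_fold")
  raw$ddg_bind <- numify("ddg_bind")

  dup <- duplicated(raw[c("site", "aa_to")])
  if (any(dup))
    stop("duplicate (site, aa_to) pair: site ", raw$site[dup][1L],
         ", aa_to ", raw$aa_to[dup][1L])
  tab <- DdgTable(raw, referenceId = referenceId)
  if (strict) {
    L <- proteinLength(tab)
    if (nrow(raw) != 19L * L)
      stop("strict mode: expected ", 19L * L, " rows for L = ", L,
           ", found ", nrow(raw))
    perSite <- table(factor(raw$site, levels = seq_len(L)))
    if (any(perSite != 19L))
      stop("strict mode: site(s) without exactly 19 rows: ",
           paste(utils::head(which(perSite != 19L)), collapse = ", "))
  }
  tab
}

#' Write a ddG substitution table
#'
#' Writes the supplementary-table TSV dialect with the canonical column
#' order and names. ddG values are written with 6 significant digits;
#' tables round-trip through [readDdgTable()] to within 1e-6 kcal/mol.
#'
#' @param table a [DdgTable-class].
#' @param path output file path.
#' @export
writeDdgTable <- function(table, path) {
  stopifnot(is(table, "DdgTable"))
  d <- ddgData(table)
  out <- data.frame(
    site = d$site, `aa.from` = d$aa_from, `aa.to` = d$aa_to,
    `within.1.DNA.change` = d$accessible, `wild.phg.sub` = d$wild_phage,
    `lab.exp.sub` = d$lab_experiment,
    `ddG.fold` = signif(d$ddg_fold, 6), `ddG.bind` = signif(d$ddg_bind, 6),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cross-check table accessibility flags against a coding sequence
#'
#' Re-enumerates the one-DNA-change neighborhood of \code{cds} and reports
#' every (site, aa_to) where the table's accessibility flag disagrees with
#' the enumeration. The translated CDS (post-Met when
#' \code{removeInitialMet}) must match the table's aa_from at every site.
#'
#' @param table a [DdgTable-class].
#' @param cds coding DNA string for the reference sequence.
#' @param removeInitialMet logical, default TRUE.
#' @return data.frame of discrepancies with columns \code{site},
#'   \code{aa_to}, \code{flagged} (table flag) and \code{enumerated}
#'   (0/1 from the CDS); zero rows when consistent.
#' @export
crossCheckAccessibility <- function(table, cds, removeInitialMet = TRUE) {
  stopifnot(is(table, "DdgTable"))
  prot <- translateCds(cds, removeInitialMet = removeInitialMet)
  aa <- strsplit(prot, "")[[1]]
  d <- ddgData(table)
  sites <- sort(unique(d$site))
  if (max(sites) > length(aa))
    stop("table has sites beyond the translated sequence length (",
         length(aa), ")")
  tabFrom <- vapply(sites, function(s) d$aa_from[d$site == s][1L],
                    character(1))
  bad <- which(aa[sites] != tabFrom)
  if (length(bad))
    stop("aa_from mismatch at site(s): ",
         paste(sites[bad], collapse = ", "))
  acc <- enumerateAccessible(cds, removeInitialMet = removeInitialMet)
  accKey <- paste(acc$site, acc$aa_to)
  enumFlag <- as.integer(paste(d$site, d$aa_to) %in% accKey)
  diff <- which(enumFlag != d$accessible)
  out <- data.frame(site = d$site[diff], aa_to = d$aa_to[diff],
                    flagged = d$accessible[diff],
                    enumerated = enumFlag[diff],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
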