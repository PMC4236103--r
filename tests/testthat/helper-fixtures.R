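## Shared fixtures, built in code.

## A complete 38-row table for the 2-residue protein "AW" translated from
## the toy CDS ATG|GCA|TGG (post-Met numbering), with deterministic ddG
## values and a couple of observed flags.
toyCds <- "ATGGCATGG"

makeToyTable <- function() {
  all <- enumerateAll("AW")
  acc <- enumerateAccessible(toyCds)
  d <- data.frame(
    site = all$site, aa_from = all$aa_from, aa_to = all$aa_to,
    accessible = as.integer(paste(all$site, all$aa_to) %in%
                              paste(acc$site, acc$aa_to)),
    wild_phage = 0L, lab_experiment = 0L,
    ddg_fold = round(sin(seq_len(nrow(all))) * 3, 3),
    ddg_bind = round(cos(seq_len(nrow(all))) * 2, 3),
    stringsAsFactors = FALSE)
  d$wild_phage[c(1L, 5L)] <- 1L
  d$lab_experiment[c(5L, 22L)] <- 1L
  DdgTable(d, proteinLength = 2L, referenceId = "toy")
}

## Independent brute-force oracle for accessibility: mutate every base of
## the CDS to every alternative, translate both sequences with
## Biostrings::translate, and collect the amino-acid differences.
bruteForceAccessible <- function(cds, removeInitialMet = TRUE) {
  ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  refAa <- strsplit(ref, "")[[1]]
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(cds, "")[[1]]
  ## all 3 * len point mutants, translated in one vectorized call
  muts <- character(0)
  for (pos in seq_along(chars)) {
    for (alt in setdiff(bases, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      muts <- c(muts, paste(mut, collapse = ""))
    }
  }
  aaSet <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(muts)))
  found <- character(0)
  for (aaStr in aaSet) {
    aa <- strsplit(aaStr, "")[[1]]
    if (any(aa == "*")) next   # nonsense mutation, not a substitution
    diff <- which(aa != refAa)
    for (s in diff) found <- c(found, paste(s, refAa[s], aa[s]))
  }
  found <- unique(found)
  parts <- strsplit(found, " ")
  out <- data.frame(
    site = as.integer(vapply(parts, `[`, character(1), 1L)),
    aa_from = vapply(parts, `[`, character(1), 2L),
    aa_to = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE)
  if (removeInitialMet) {
    out <- out[out$site > 1L, ]
    out$site <- out$site - 1L
  }
  out <- out[order(out$site, out$aa_to), ]
  rownames(out) <- NULL
  out
}

## Random CDS of n codons beginning with ATG and free of internal stops.
randomCds <- function(nCodons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste0("ATG", paste(sample(sense, nCodons - 1L, replace = TRUE),
                      collapse = ""))
}

## A small study-like fixture: synthetic table with observed flags set
## from draws under known surfaces, plus a matching experiment registry.
makeStudyFixture <- function(L = 60, seed = 42) {
  tab <- synthDdgTable(PoolModel(L = L, seed = seed))
  surf <- SelectionSurfaceParams(0, 0, 1, 1, 0)
  wild <- synthObservedUnderSelection(tab, surf, 15, seed = seed + 1L)
  lab <- synthObservedUnderSelection(tab, surf, 20, seed = seed + 2L)
  d <- ddgData(tab)
  d$wild_phage[paste(d$site, d$aa_to) %in%
                 paste(wild$site, wild$aa_to)] <- 1L
  d$lab_experiment[paste(d$site, d$aa_to) %in%
                     paste(lab$site, lab$aa_to)] <- 1L
  tab2 <- DdgTable(d, proteinLength = proteinLength(tab),
                   referenceId = referenceId(tab))
  attr(tab2, "cds") <- attr(tab, "cds")
  registry <- synthExperiments(6, tab2, nSubs = 3, seed = seed + 3L)
  list(table = tab2, registry = registry)
}

## Naive per-observation loop oracle for the surface score, independent
## of the package's vectorized paths.
naiveScore <- function(params, grid, obs, weighted = TRUE) {
  k <- nrow(grid@proportions)
  ctr <- grid@lo + (seq_len(k) - 0.5) * grid@cell
  ## direct bivariate normal density, un-truncated
  dens <- function(x, y) {
    r <- params@rho
    u <- (x - params@muFold) / params@sigmaFold
    v <- (y - params@muBind) / params@sigmaBind
    exp(-(u^2 - 2 * r * u * v + v^2) / (2 * (1 - r^2))) /
      (2 * pi * params@sigmaFold * params@sigmaBind * sqrt(1 - r^2))
  }
  sel <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    sel[i, j] <- dens(ctr[i], ctr[j])
  sel <- sel / sum(sel)
  C <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    C <- C + grid@proportions[i, j] * sel[i, j]
  total <- 0
  for (r in seq_len(nrow(obs))) {
    w <- if (weighted && !is.null(obs$weight)) obs$weight[r] else 1
    ci <- min(max(floor((obs$ddg_fold[r] - grid@lo) / grid@cell) + 1, 1), k)
    cj <- min(max(floor((obs$ddg_bind[r] - grid@lo) / grid@cell) + 1, 1), k)
    a <- grid@proportions[ci, cj]
    if (a == 0) a <- 1 / (2 * grid@nPool)
    total <- total + w * (log(a) + log(sel[ci, cj]) - log(C))
  }
  total
}
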