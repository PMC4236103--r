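#' PoolModel: generative model for synthetic ddG tables
#'
#' Describes a synthetic pool of substitution stability effects: a
#' protein length, a two-component normal location-scale mixture per
#' stability axis (a narrow near-zero core plus a broader, right-shifted
#' tail, emulating the empirical shape of accessible-substitution
#' distributions), and target destabilizing fractions the generator
#' calibrates to by a rigid shift.
#'
#' @slot L protein length (post-cleavage numbering).
#' @slot foldMixture,bindMixture lists with components \code{mean}
#'   (length 2), \code{sd} (length 2, > 0) and \code{weight} (mixing
#'   weight of the first component, in (0, 1)).
#' @slot targetFracDestabilizingFold,targetFracDestabilizingBind target
#'   proportions of ddG > 0 among accessible substitutions, in (0, 1).
#' @slot seed integer RNG seed.
#' @export
setClass("PoolModel",
  representation(L = "integer", foldMixture = "list", bindMixture = "list",
                 targetFracDestabilizingFold = "numeric",
                 targetFracDestabilizingBind = "numeric", seed = "integer")
)

setValidity("PoolModel", function(object) {
  for (mx in list(object@foldMixture, object@bindMixture)) {
    if (!all(c("mean", "sd", "weight") %in% names(mx)))
      return("mixtures need mean, sd, weight")
    if (length(mx$mean) != 2L || length(mx$sd) != 2L)
      return("mixtures are two-component")
    if (any(mx$sd <= 0)) return("mixture sds must be positive")
    if (mx$weight <= 0 || mx$weight >= 1)
      return("mixing weight must be in (0, 1)")
  }
  tf <- c(object@targetFracDestabilizingFold,
          object@targetFracDestabilizingBind)
  if (any(tf <= 0) || any(tf >= 1))
    return(paste0("target destabilizing fractions must be in (0, 1): a ",
                  "target of 0 or 1 cannot be realized by shifting a ",
                  "full-support mixture"))
  if (object@L < 1L) return("L must be positive")
  TRUE
})

#' Construct a PoolModel
#'
#' Defaults encode the study conditions the generator emulates: a
#' 426-residue coat protein whose accessible substitutions are 72.9%
#' destabilizing for folding and 70.0% for binding, with folding effects
#' more dispersed than binding effects.
#'
#' @param L protein length.
#' @param foldMixture,bindMixture two-component mixtures (see
#'   [PoolModel-class]).
#' @param targetFracDestabilizingFold,targetFracDestabilizingBind target
#'   destabilizing fractions among accessible substitutions.
#' @param seed integer RNG seed.
#' @return a [PoolModel-class].
#' @export
PoolModel <- function(L = 426L,
                      foldMixture = list(mean = c(0, 2.5),
                                         sd = c(0.9, 2.2), weight = 0.75),
                      bindMixture = list(mean = c(0, 1.5),
                                         sd = c(0.55, 1.8), weight = 0.85),
                      targetFracDestabilizingFold = 0.729,
                      targetFracDestabilizingBind = 0.700,
                      seed = 1L) {
  new("PoolModel", L = as.integer(L), foldMixture = foldMixture,
      bindMixture = bindMixture,
      targetFracDestabilizingFold = targetFracDestabilizingFold,
      targetFracDestabilizingBind = targetFracDestabilizingBind,
      seed = as.integer(seed))
}

## Sense codons per amino acid, derived once from the standard code.
senseCodonsByAa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

## Draw n values from a two-component normal mixture.
drawMixture <- function(n, mx) {
  comp <- stats::runif(n) < mx$weight
  ifelse(comp, stats::rnorm(n, mx$mean[1L], mx$sd[1L]),
         stats::rnorm(n, mx$mean[2L], mx$sd[2L]))
}

#' Generate a synthetic ddG substitution table
#'
#' Builds a complete 19 * L table for a random protein. Accessibility is
#' genetically coherent: a random coding sequence consistent with the
#' protein (random synonymous codon per residue, initiator ATG
#' prepended) is simulated and accessibility flags come from
#' [enumerateAccessible()] on it, so per-site accessible-target counts
#' respect the genetic code. ddG values are drawn independently per axis
#' from the model's mixtures and rigidly shifted so the realized
#' destabilizing fraction among accessible substitutions matches the
#' model target (to within 1/n).
#'
#' @param model a [PoolModel-class].
#' @return a [DdgTable-class]; the simulated CDS is attached as
#'   \code{attr(x, "cds")}.
#' @examples
#' tab <- synthDdgTable(PoolModel(L = 30, seed = 7))
#' @export
synthDdgTable <- function(model) {
  stopifnot(is(model, "PoolModel"))
  validObject(model)
  withSeed(model@seed, {
    aa <- sample(AA_ALPHABET, model@L, replace = TRUE)
    byAa <- senseCodonsByAa()
    codons <- vapply(aa, function(a)
      sample(byAa[[a]], 1L), character(1))
    cds <- paste0("ATG", paste(codons, collapse = ""))
    all <- enumerateAll(paste(aa, collapse = ""))
    acc <- enumerateAccessible(cds, removeInitialMet = TRUE)
    accFlag <- as.integer(paste(all$site, all$aa_to) %in%
                            paste(acc$site, acc$aa_to))
    n <- nrow(all)
    fold <- drawMixture(n, model@foldMixture)
    bind <- drawMixture(n, model@bindMixture)
    isAcc <- accFlag == 1L
    ## shift so that among accessible rows the fraction > 0 hits target
    shiftTo <- function(x, target) {
      q <- stats::quantile(x[isAcc], probs = 1 - target, type = 1,
                           names = FALSE)
      x - q
    }
    fold <- shiftTo(fold, model@targetFracDestabilizingFold)
    bind <- shiftTo(bind, model@targetFracDestabilizingBind)
    tab <- DdgTable(
      data.frame(site = all$site, aa_from = all$aa_from,
                 aa_to = all$aa_to, accessible = accFlag,
                 wild_phage = 0L, lab_experiment = 0L,
                 ddg_fold = fold, ddg_bind = bind,
                 stringsAsFactors = FALSE),
      proteinLength = model@L, referenceId = "synthetic")
    attr(tab, "cds") <- cds
    tab
  })
}

#' Sample observed substitutions under a known selection surface
#'
#' Draws \code{n} accessible substitutions without replacement with
#' probability proportional to the truncated bivariate-normal selection
#' density at their (ddG_fold, ddG_bind); substitutions outside the
#' truncation square have zero selection density and cannot be drawn.
#' Optional experiment-multiplicity weights are 1 + Poisson(lambda).
#'
#' @param table a [DdgTable-class].
#' @param params a [SelectionSurfaceParams-class].
#' @param n number of observations to draw.
#' @param seed integer RNG seed.
#' @param weightLambda Poisson rate for the weight distribution; 0
#'   (default) gives all weights 1.
#' @param lo,hi truncation bounds of the selection surface.
#' @return data.frame of weighted observations with columns \code{site},
#'   \code{aa_from}, \code{aa_to}, \code{ddg_fold}, \code{ddg_bind},
#'   \code{weight}.
#' @export
synthObservedUnderSelection <- function(table, params, n, seed = NULL,
                                        weightLambda = 0, lo = -3,
                                        hi = 3) {
  stopifnot(is(table, "DdgTable"), is(params, "SelectionSurfaceParams"))
  acc <- accessibleSubs(table)
  if (!nrow(acc)) stop("no accessible substitutions in table")
  dens <- exp(bvnLogKernel(acc$ddg_fold, acc$ddg_bind, params))
  dens[acc$ddg_fold < lo | acc$ddg_fold > hi |
       acc$ddg_bind < lo | acc$ddg_bind > hi] <- 0
  if (n > sum(dens > 0))
    stop("n exceeds the ", sum(dens > 0),
         " accessible substitutions with positive selection density")
  withSeed(seed, {
    idx <- sample.int(nrow(acc), n, replace = FALSE, prob = dens)
    w <- 1L + if (weightLambda > 0) stats::rpois(n, weightLambda) else 0L
    out <- acc[idx, c("site", "aa_from", "aa_to", "ddg_fold", "ddg_bind")]
    out$weight <- as.integer(w)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic experiment registry
#'
#' Builds \code{nExp} experiments with either linear (a chain of
#' \code{nSubs} segments, one substitution each) or branching (a binary
#' tree with \code{nSplits} splits, so 2^nSplits leaves, one substitution
#' per segment) topologies. Substitutions are drawn from the accessible
#' pool under a selection surface (flat by default), temperature classes
#' are assigned by the mix proportions, and a fraction of experiments
#' start from the unmutated ancestor.
#'
#' @param nExp number of experiments.
#' @param table a [DdgTable-class] supplying the accessible pool.
#' @param nSubs substitutions (= segments) per linear experiment.
#' @param nSplits binary splits; 0 gives linear chains.
#' @param temperatureMix named proportions for classes high/normal/
#'   variable; defaults to the 12:13:4 mix of the compiled adaptation
#'   experiments.
#' @param ancestorFrac fraction of experiments starting from the
#'   ancestor (default 17/29).
#' @param params optional [SelectionSurfaceParams-class] biasing the
#'   substitution draws; NULL draws uniformly from the accessible pool.
#' @param seed integer RNG seed.
#' @return named list of [Experiment-class] objects.
#' @export
synthExperiments <- function(nExp, table, nSubs = 3L, nSplits = 0L,
                             temperatureMix = c(high = 12, normal = 13,
                                                variable = 4),
                             ancestorFrac = 17 / 29, params = NULL,
                             seed = NULL) {
  stopifnot(is(table, "DdgTable"), nExp >= 1L)
  acc <- accessibleSubs(table)
  dens <- if (is.null(params)) rep(1, nrow(acc))
          else exp(bvnLogKernel(acc$ddg_fold, acc$ddg_bind, params))
  mix <- temperatureMix / sum(temperatureMix)
  nSeg <- if (nSplits > 0L) 2L^(nSplits + 1L) - 1L else as.integer(nSubs)
  withSeed(seed, {
    exps <- lapply(seq_len(nExp), function(e) {
      idx <- sample.int(nrow(acc), nSeg, prob = dens)
      keys <- formatSubKey(acc$site[idx], acc$aa_from[idx], acc$aa_to[idx])
      if (nSplits > 0L) {
        ## binary tree, level order: segment i's parent is floor(i/2)
        segs <- data.frame(
          segment = paste0("s", seq_len(nSeg)),
          parent = c(NA_character_,
                     paste0("s", (seq_len(nSeg)[-1L]) %/% 2L)),
          time = NA_real_, stringsAsFactors = FALSE)
      } else {
        segs <- data.frame(
          segment = paste0("s", seq_len(nSeg)),
          parent = c(NA_character_, paste0("s", seq_len(nSeg - 1L))),
          time = as.numeric(seq_len(nSeg)), stringsAsFactors = FALSE)
      }
      segs$substitutions <- as.list(keys)
      Experiment(id = sprintf("synth%02d", e), segments = segs,
                 temperatureClass = sample(names(mix), 1L, prob = mix),
                 ancestorStart = stats::runif(1) < ancestorFrac,
                 sourceLabel = letters[(e - 1L) %% 26L + 1L])
    })
    stats::setNames(exps, vapply(exps, function(e) e@id, character(1)))
  })
}
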