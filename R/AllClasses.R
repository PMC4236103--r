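#' @import methods
NULL

#' DdgTable: per-substitution folding and binding stability changes
#'
#' An S4 container for a table of amino-acid substitutions and their
#' estimated changes in folding stability (\code{ddg_fold}) and pentamer
#' binding stability (\code{ddg_bind}), both in kcal/mol with positive
#' values destabilizing. Each row carries three 0/1 flags: whether the
#' substitution is reachable within one DNA change of the reference coding
#' sequence (\code{accessible}), whether it was inferred among wild phage
#' by consensus comparison (\code{wild_phage}), and whether it was recorded
#' in a laboratory adaptation experiment (\code{lab_experiment}).
#'
#' A \emph{complete} table holds all 19 * L substitutions for a protein of
#' length L. Partial tables (e.g. observed-only lists) are permitted unless
#' strict validation is requested at read time.
#'
#' @slot subs data.frame with columns \code{site}, \code{aa_from},
#'   \code{aa_to}, \code{accessible}, \code{wild_phage},
#'   \code{lab_experiment}, \code{ddg_fold}, \code{ddg_bind}.
#' @slot proteinLength integer, protein length L (post-cleavage numbering).
#' @slot referenceId free-text identifier of the reference sequence.
#'
#' @seealso [readDdgTable()], [writeDdgTable()], [synthDdgTable()]
#' @export
setClass("DdgTable",
  representation(
    subs = "data.frame",
    proteinLength = "integer",
    referenceId = "character"
  )
)

setValidity("DdgTable", function(object) {
  d <- object@subs
  need <- c("site", "aa_from", "aa_to", "accessible", "wild_phage",
            "lab_experiment", "ddg_fold", "ddg_bind")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(object@proteinLength) != 1L || is.na(object@proteinLength) ||
      object@proteinLength < 1L)
    return("proteinLength must be a single positive integer")
  if (nrow(d)) {
    if (any(d$site < 1L | d$site > object@proteinLength))
      return("site out of range [1, proteinLength]")
    if (any(d$aa_from == d$aa_to))
      return("aa_from must differ from aa_to")
    if (!all(d$aa_from %in% AA_ALPHABET) || !all(d$aa_to %in% AA_ALPHABET))
      return("amino-acid letters must be in the 20-letter alphabet")
    for (fl in c("accessible", "wild_phage", "lab_experiment"))
      if (!all(d[[fl]] %in% c(0L, 1L)))
        return(paste0("flag column '", fl, "' must be 0/1"))
    if (!all(is.finite(d$ddg_fold)) || !all(is.finite(d$ddg_bind)))
      return("ddG values must be finite")
    if (anyDuplicated(d[c("site", "aa_to")]))
      return("duplicate (site, aa_to) pair(s)")
    mult <- tapply(d$aa_from, d$site, function(a) length(unique(a)))
    if (any(mult > 1L))
      return("conflicting aa_from within a site")
  }
  TRUE
})

#' StabilityZone: a closed ddG interval around zero
#'
#' Membership is closed on both ends: a value x is in the zone when
#' lo <= x <= hi. The canonical zones are [-2, 2] and [-3.5, 3.5] kcal/mol.
#'
#' @slot lo,hi numeric bounds in kcal/mol, lo < hi.
#' @export
setClass("StabilityZone", representation(lo = "numeric", hi = "numeric"))

setValidity("StabilityZone", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L ||
      !is.finite(object@lo) || !is.finite(object@hi))
    return("lo and hi must be single finite numbers")
  if (object@lo >= object@hi) return("lo must be < hi")
  TRUE
})

#' ZoneCounts: zone membership by three criteria
#'
#' Counts of substitutions whose ddG_fold lies in a stability zone, whose
#' ddG_bind lies in the zone, and whose two values lie in the zone jointly.
#'
#' @slot nTotal,nFoldIn,nBindIn,nJointIn non-negative integer counts.
#' @export
setClass("ZoneCounts",
  representation(nTotal = "integer", nFoldIn = "integer",
                 nBindIn = "integer", nJointIn = "integer")
)

setValidity("ZoneCounts", function(object) {
  n <- c(object@nTotal, object@nFoldIn, object@nBindIn, object@nJointIn)
  if (any(is.na(n)) || any(n < 0L)) return("counts must be non-negative")
  if (object@nJointIn > min(object@nFoldIn, object@nBindIn))
    return("joint count exceeds a marginal count")
  if (max(object@nFoldIn, object@nBindIn) > object@nTotal)
    return("marginal count exceeds total")
  TRUE
})

#' RandomizationResult: Monte-Carlo zone-clustering test result
#'
#' Result of resampling observed-set-sized draws from the accessible pool
#' and comparing zone membership counts with the real observed counts.
#' Two-sided p-values are twice the upper-tail proportion, capped at 1.
#'
#' @slot zone the [StabilityZone-class] tested.
#' @slot nObserved size of the observed set.
#' @slot realCounts [ZoneCounts-class] of the observed set.
#' @slot reps number of Monte-Carlo replicates.
#' @slot seed integer seed used (NA when none supplied).
#' @slot kFold,kBind,kJoint replicate counts with simulated membership >=
#'   the real count (the tie-inclusive upper tail).
#' @slot pFold,pBind,pJoint two-sided p-values in [0, 1].
#' @slot addOne logical; whether the (k+1)/(reps+1) correction was applied.
#' @export
setClass("RandomizationResult",
  representation(
    zone = "StabilityZone", nObserved = "integer",
    realCounts = "ZoneCounts", reps = "integer", seed = "integer",
    kFold = "integer", kBind = "integer", kJoint = "integer",
    pFold = "numeric", pBind = "numeric", pJoint = "numeric",
    addOne = "logical"
  )
)

setValidity("RandomizationResult", function(object) {
  p <- c(object@pFold, object@pBind, object@pJoint)
  if (any(p < 0) || any(p > 1)) return("p-values must lie in [0, 1]")
  if (object@reps < 1L) return("reps must be >= 1")
  TRUE
})

#' SelectionSurfaceParams: a truncated bivariate-normal selection function
#'
#' Parameters (mu_fold, mu_bind, sigma_fold, sigma_bind, rho) of a
#' bivariate normal over (ddG_fold, ddG_bind), truncated to the square
#' [-3, 3] x [-3, 3] kcal/mol when used as a selection surface.
#'
#' @slot muFold,muBind means, kcal/mol.
#' @slot sigmaFold,sigmaBind standard deviations, kcal/mol (> 0).
#' @slot rho correlation, |rho| < 1.
#' @export
setClass("SelectionSurfaceParams",
  representation(muFold = "numeric", muBind = "numeric",
                 sigmaFold = "numeric", sigmaBind = "numeric",
                 rho = "numeric")
)

setValidity("SelectionSurfaceParams", function(object) {
  v <- c(object@muFold, object@muBind, object@sigmaFold,
         object@sigmaBind, object@rho)
  if (length(v) != 5L || any(!is.finite(v)))
    return("all five parameters must be single finite numbers")
  if (object@sigmaFold <= 0 || object@sigmaBind <= 0)
    return("sigmas must be positive")
  if (abs(object@rho) >= 1) return("|rho| must be < 1")
  TRUE
})

#' DensityGrid: gridded accessible-substitution density
#'
#' The square [lo, hi]^2 divided into cells of side \code{cell}; each cell
#' carries the proportion of pool substitutions falling in it. Cells are
#' half-open [x, x + cell) except the last along each axis, which is closed
#' at \code{hi}. Rows index the fold axis, columns the bind axis.
#'
#' @slot lo,hi,cell grid geometry in kcal/mol.
#' @slot proportions numeric matrix of cell masses (sum <= 1).
#' @slot nPool size of the pool the proportions were computed from.
#' @export
setClass("DensityGrid",
  representation(lo = "numeric", hi = "numeric", cell = "numeric",
                 proportions = "matrix", nPool = "integer")
)

setValidity("DensityGrid", function(object) {
  if (object@cell <= 0) return("cell must be positive")
  k <- (object@hi - object@lo) / object@cell
  if (abs(k - round(k)) > 1e-8) return("cell must divide (hi - lo) evenly")
  k <- as.integer(round(k))
  if (!all(dim(object@proportions) == c(k, k)))
    return("proportions matrix does not match grid geometry")
  if (any(object@proportions < 0)) return("proportions must be non-negative")
  if (sum(object@proportions) > 1 + 1e-8)
    return("proportions must sum to at most 1")
  TRUE
})

#' SelectionSurfaceFit: result of the exhaustive lattice scan
#'
#' @slot best [SelectionSurfaceParams-class] maximizing the log-score.
#' @slot logScore the maximized log-score.
#' @slot nClamped number of observations outside the grid bounds that were
#'   clamped to a boundary cell.
#' @slot scanSize number of parameter combinations evaluated.
#' @slot nFloored number of observation cells whose accessible mass was
#'   floored to avoid infinite penalties.
#' @export
setClass("SelectionSurfaceFit",
  representation(best = "SelectionSurfaceParams", logScore = "numeric",
                 nClamped = "integer", scanSize = "integer",
                 nFloored = "integer")
)

setValidity("SelectionSurfaceFit", function(object) {
  if (!is.finite(object@logScore)) return("logScore must be finite")
  TRUE
})

#' Experiment: one (possibly branching) laboratory adaptation
#'
#' Segments form a rooted tree; each segment carries the substitutions
#' fixed along it (compact keys such as \code{"A15T"}) and an optional
#' sampling time point. Temperature classes follow the conventions of the
#' phage-adaptation literature: high (>= 42 C), normal (<= 37 C), or
#' variable.
#'
#' @slot id free-text experiment identifier.
#' @slot sourceLabel short letter code for the data source.
#' @slot temperatureClass one of "high", "normal", "variable".
#' @slot ancestorStart logical; TRUE when the adaptation began from the
#'   unmutated ancestor.
#' @slot segments data.frame with columns \code{segment}, \code{parent}
#'   (NA for the root), \code{time} (numeric, may be NA) and
#'   \code{substitutions} (list column of character key vectors).
#' @export
setClass("Experiment",
  representation(id = "character", sourceLabel = "character",
                 temperatureClass = "character", ancestorStart = "logical",
                 segments = "data.frame")
)

setValidity("Experiment", function(object) {
  if (!object@temperatureClass %in% c("high", "normal", "variable"))
    return("temperatureClass must be high, normal or variable")
  s <- object@segments
  need <- c("segment", "parent", "time", "substitutions")
  if (!all(need %in% names(s)))
    return(paste("segments needs columns:", paste(need, collapse = ", ")))
  if (!nrow(s)) return("at least one (root) segment required")
  if (anyDuplicated(s$segment)) return("duplicate segment ids")
  roots <- is.na(s$parent)
  if (sum(roots) != 1L) return("exactly one root segment required")
  if (!all(s$parent[!roots] %in% s$segment))
    return("parent reference to unknown segment")
  ## rooted tree: every non-root must reach the root without cycles
  parent <- stats::setNames(s$parent, s$segment)
  for (sg in s$segment) {
    seen <- character(0)
    cur <- sg
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) return("cycle in segment graph")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  TRUE
})
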