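#' Randomization test for zone clustering of observed substitutions
#'
#' Tests whether observed substitutions are more concentrated inside a
#' stability zone than random draws from the accessible pool. Each
#' replicate draws |observed| substitutions without replacement from the
#' accessible set and counts zone membership by three criteria: ddG_fold
#' in the zone, ddG_bind in the zone, and both jointly. The two-sided
#' p-value for each criterion is twice the proportion of replicates with
#' a simulated count greater than or equal to the real count (ties
#' included), capped at 1.
#'
#' When a tail count is zero the point estimate is 0; the show method
#' reports such p-values as "< 2/reps". An optional add-one correction
#' (2 * (k + 1) / (reps + 1), capped at 1) is available behind
#' \code{addOne} and is off by default.
#'
#' @param observed data.frame of observed substitutions with
#'   \code{ddg_fold}, \code{ddg_bind} columns (non-empty).
#' @param accessible data.frame of the accessible pool (same columns), or
#'   a [DdgTable-class] whose accessible rows are used.
#' @param zone a [StabilityZone-class].
#' @param reps number of Monte-Carlo replicates (default 10000).
#' @param seed integer seed for exact reproducibility; the caller's RNG
#'   state is untouched.
#' @param addOne logical; apply the add-one estimator.
#' @return a [RandomizationResult-class].
#' @examples
#' pool <- data.frame(ddg_fold = rnorm(200), ddg_bind = rnorm(200))
#' obs <- pool[1:20, ]
#' randomizationTest(obs, pool, StabilityZone(-2, 2), reps = 500, seed = 1)
#' @export
randomizationTest <- function(observed, accessible, zone, reps = 10000L,
                              seed = NULL, addOne = FALSE) {
  if (is(accessible, "DdgTable")) accessible <- accessibleSubs(accessible)
  if (is(observed, "DdgTable")) observed <- observedSubs(observed)
  if (!nrow(observed)) stop("empty observed set")
  if (nrow(observed) > nrow(accessible))
    stop("observed set larger than accessible pool")
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1")

  real <- zoneCounts(observed, zone)
  nObs <- nrow(observed)
  nAcc <- nrow(accessible)
  foldIn <- zoneContains(zone, accessible$ddg_fold)
  bindIn <- zoneContains(zone, accessible$ddg_bind)
  jointIn <- foldIn & bindIn

  k <- c(fold = 0L, bind = 0L, joint = 0L)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(nAcc, nObs)
      if (sum(foldIn[idx]) >= real@nFoldIn) k["fold"] <- k["fold"] + 1L
      if (sum(bindIn[idx]) >= real@nBindIn) k["bind"] <- k["bind"] + 1L
      if (sum(jointIn[idx]) >= real@nJointIn) k["joint"] <- k["joint"] + 1L
    }
  })

  pOf <- function(kk) {
    p <- if (addOne) 2 * (kk + 1) / (reps + 1) else 2 * kk / reps
    min(1, p)
  }
  new("RandomizationResult",
      zone = zone, nObserved = as.integer(nObs), realCounts = real,
      reps = reps, seed = if (is.null(seed)) NA_integer_ else
        as.integer(seed),
      kFold = k[["fold"]], kBind = k[["bind"]], kJoint = k[["joint"]],
      pFold = pOf(k[["fold"]]), pBind = pOf(k[["bind"]]),
      pJoint = pOf(k[["joint"]]), addOne = addOne)
}

setMethod("show", "RandomizationResult", function(object) {
  fmt <- function(k, p) {
    if (k == 0L && !object@addOne)
      sprintf("< %g", 2 / object@reps)
    else sprintf("%.4g", p)
  }
  cat("Randomization test (", object@reps, " replicates, zone [",
      object@zone@lo, ", ", object@zone@hi, "])\n", sep = "")
  cat("  observed n =", object@nObserved, "\n")
  rc <- object@realCounts
  cat("  in-zone counts: fold ", rc@nFoldIn, ", bind ", rc@nBindIn,
      ", joint ", rc@nJointIn, "\n", sep = "")
  cat("  two-sided p: fold ", fmt(object@kFold, object@pFold),
      ", bind ", fmt(object@kBind, object@pBind),
      ", joint ", fmt(object@kJoint, object@pJoint), "\n", sep = "")
})

#' One-sided tail proportion of a randomization result
#'
#' The raw upper-tail proportions k / reps underlying the two-sided
#' p-values, useful for calibration studies.
#'
#' @param result a [RandomizationResult-class].
#' @return named numeric vector (fold, bind, joint).
#' @export
tailProportions <- function(result) {
  stopifnot(is(result, "RandomizationResult"))
  c(fold = result@kFold, bind = result@kBind,
    joint = result@kJoint) / result@reps
}
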