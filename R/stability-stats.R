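#' Construct a StabilityZone
#'
#' @param lo,hi zone bounds in kcal/mol, lo < hi. Membership is closed:
#'   lo <= x <= hi.
#' @return a [StabilityZone-class].
#' @examples
#' StabilityZone(-2, 2)
#' @export
StabilityZone <- function(lo, hi) new("StabilityZone", lo = lo, hi = hi)

setMethod("show", "StabilityZone", function(object) {
  cat("StabilityZone [", object@lo, ", ", object@hi, "] kcal/mol\n",
      sep = "")
})

## Closed-interval membership.
zoneContains <- function(zone, x) x >= zone@lo & x <= zone@hi

#' Fraction of destabilizing substitutions
#'
#' The proportion of ddG values strictly greater than zero (positive =
#' destabilizing; values exactly 0 count as non-destabilizing).
#'
#' @param values numeric vector of ddG values (kcal/mol), non-empty.
#' @return proportion in [0, 1].
#' @examples
#' fractionDestabilizing(c(1, -1))  # 0.5
#' @export
fractionDestabilizing <- function(values) {
  if (!length(values)) stop("empty ddG collection")
  mean(values > 0)
}

#' @rdname zoneCounts
setMethod("zoneCounts", signature(subs = "data.frame", zone = "StabilityZone"),
  function(subs, zone) {
    fin <- zoneContains(zone, subs$ddg_fold)
    bin <- zoneContains(zone, subs$ddg_bind)
    new("ZoneCounts", nTotal = nrow(subs), nFoldIn = sum(fin),
        nBindIn = sum(bin), nJointIn = sum(fin & bin))
  })

#' @rdname zoneCounts
setMethod("zoneCounts", signature(subs = "DdgTable", zone = "StabilityZone"),
  function(subs, zone) zoneCounts(ddgData(subs), zone))

setMethod("show", "ZoneCounts", function(object) {
  n <- object@nTotal
  pr <- function(k) sprintf("%.3f (%d)", if (n) k / n else NA_real_, k)
  cat("ZoneCounts over n =", n, "substitutions\n")
  cat("  fold in zone: ", pr(object@nFoldIn),
      " | bind in zone: ", pr(object@nBindIn),
      " | jointly: ", pr(object@nJointIn), "\n", sep = "")
})

#' Correlation between folding and binding effects
#'
#' Pearson correlation of ddg_fold vs ddg_bind across substitutions,
#' with its square and a p-value from the standard t approximation.
#'
#' @param subs a [DdgTable-class] or data.frame with \code{ddg_fold} and
#'   \code{ddg_bind} columns; at least 3 rows, non-zero variance in both.
#' @return list with elements \code{r}, \code{r_squared}, \code{p_value}.
#' @export
correlationFoldBind <- function(subs) {
  if (is(subs, "DdgTable")) subs <- ddgData(subs)
  if (nrow(subs) < 3L) stop("need at least 3 substitutions")
  if (stats::sd(subs$ddg_fold) == 0 || stats::sd(subs$ddg_bind) == 0)
    stop("zero variance in ddg_fold or ddg_bind")
  ct <- stats::cor.test(subs$ddg_fold, subs$ddg_bind, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value)
}

#' Per-residue median absolute stability effects
#'
#' Median of |ddG| at each site, over the accessible pool or all
#' substitutions. The median of an even-sized set is the mean of the two
#' middle values. Sites with no substitution in the chosen pool get NA.
#'
#' @param table a [DdgTable-class].
#' @param which "fold" or "bind".
#' @param pool "accessible" or "all".
#' @return data.frame with columns \code{site} (1..L) and
#'   \code{median_abs_ddg}.
#' @export
residueMedianEffects <- function(table, which = c("fold", "bind"),
                                 pool = c("accessible", "all")) {
  stopifnot(is(table, "DdgTable"))
  which <- match.arg(which)
  pool <- match.arg(pool)
  d <- if (pool == "accessible") accessibleSubs(table) else ddgData(table)
  v <- abs(d[[paste0("ddg_", which)]])
  L <- proteinLength(table)
  med <- rep(NA_real_, L)
  agg <- tapply(v, factor(d$site, levels = seq_len(L)), stats::median)
  med[as.integer(names(agg))] <- as.numeric(agg)
  data.frame(site = seq_len(L), median_abs_ddg = med)
}

#' Export per-residue median effects as TSV
#'
#' One row per site with the median |ddG_fold| and |ddG_bind| over the
#' chosen pool, suitable for downstream structure coloring.
#'
#' @inheritParams residueMedianEffects
#' @param path output file path.
#' @export
writeResidueMedianEffects <- function(table, path, pool = "accessible") {
  f <- residueMedianEffects(table, "fold", pool)
  b <- residueMedianEffects(table, "bind", pool)
  out <- data.frame(site = f$site, median_abs_ddg_fold = f$median_abs_ddg,
                    median_abs_ddg_bind = b$median_abs_ddg)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Folding and binding ddG from the thermodynamic cycle
#'
#' For an n-copy complex (n = 5 for the coat-protein pentamer), binding
#' stability is \code{dG_bind = dG_interaction - n * dG_fold}: the free
#' energy of the assembled complex relative to n folded monomers. The
#' substitution effects are then differences between the substituted and
#' reference proteins:
#' \code{ddG_fold = dG_fold_sub - dG_fold_ref} and
#' \code{ddG_bind = dG_bind_sub - dG_bind_ref}.
#'
#' @param dG_interaction_ref,dG_interaction_sub complex free energies,
#'   kcal/mol.
#' @param dG_fold_ref,dG_fold_sub per-monomer folding free energies,
#'   kcal/mol.
#' @param n_copies number of monomers in the complex (default 5).
#' @return list with elements \code{ddg_fold}, \code{ddg_bind}.
#' @examples
#' ddgBindFromCycle(-100, -98, -10, -11)  # ddg_fold -1, ddg_bind +7
#' @export
ddgBindFromCycle <- function(dG_interaction_ref, dG_interaction_sub,
                             dG_fold_ref, dG_fold_sub, n_copies = 5L) {
  stopifnot(n_copies >= 1L)
  bindRef <- dG_interaction_ref - n_copies * dG_fold_ref
  bindSub <- dG_interaction_sub - n_copies * dG_fold_sub
  list(ddg_fold = dG_fold_sub - dG_fold_ref,
       ddg_bind = bindSub - bindRef)
}
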