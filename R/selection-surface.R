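#' Construct SelectionSurfaceParams
#'
#' @param muFold,muBind means of the selection surface, kcal/mol.
#' @param sigmaFold,sigmaBind standard deviations, kcal/mol (> 0).
#' @param rho correlation, |rho| < 1.
#' @return a [SelectionSurfaceParams-class].
#' @export
SelectionSurfaceParams <- function(muFold, muBind, sigmaFold, sigmaBind,
                                   rho) {
  new("SelectionSurfaceParams", muFold = muFold, muBind = muBind,
      sigmaFold = sigmaFold, sigmaBind = sigmaBind, rho = rho)
}

setMethod("show", "SelectionSurfaceParams", function(object) {
  cat(sprintf(
    "SelectionSurfaceParams: mu = (%.4g, %.4g), sigma = (%.4g, %.4g), rho = %.4g\n",
    object@muFold, object@muBind, object@sigmaFold, object@sigmaBind,
    object@rho))
})

setMethod("show", "SelectionSurfaceFit", function(object) {
  cat("SelectionSurfaceFit over", object@scanSize, "lattice points\n")
  cat("  log-score:", format(object@logScore), "\n")
  if (object@nClamped)
    cat("  observations clamped to boundary cells:", object@nClamped, "\n")
  if (object@nFloored)
    cat("  zero-mass observation cells floored:", object@nFloored, "\n")
  show(object@best)
})

## Cell index along one axis; values outside [lo, hi] give NA, v == hi
## falls in the last (closed) cell.
cellIndex <- function(v, lo, hi, cell) {
  k <- as.integer(round((hi - lo) / cell))
  idx <- floor((v - lo) / cell) + 1L
  idx[v == hi] <- k
  idx[v < lo | v > hi] <- NA_integer_
  as.integer(idx)
}

cellCenters <- function(lo, hi, cell) {
  k <- as.integer(round((hi - lo) / cell))
  lo + (seq_len(k) - 0.5) * cell
}

#' Grid the accessible-substitution density
#'
#' Divides the square [lo, hi]^2 into cells of side \code{cell} and
#' records the proportion of pool substitutions in each (half-open cells,
#' last cell closed at \code{hi}). Points outside the bounds carry no
#' mass, so the matrix sums to the in-bounds fraction of the pool.
#'
#' @param pool data.frame with \code{ddg_fold}, \code{ddg_bind} columns,
#'   or a [DdgTable-class] (its accessible rows are used); non-empty.
#' @param lo,hi,cell grid geometry, defaults -3, 3, 0.25 (a 24 x 24 grid).
#' @return a [DensityGrid-class].
#' @export
gridAccessibleDensity <- function(pool, lo = -3, hi = 3, cell = 0.25) {
  if (is(pool, "DdgTable")) pool <- accessibleSubs(pool)
  if (!nrow(pool)) stop("empty pool")
  k <- (hi - lo) / cell
  if (abs(k - round(k)) > 1e-8) stop("cell must divide (hi - lo) evenly")
  k <- as.integer(round(k))
  i <- cellIndex(pool$ddg_fold, lo, hi, cell)
  j <- cellIndex(pool$ddg_bind, lo, hi, cell)
  keep <- !is.na(i) & !is.na(j)
  m <- matrix(0, k, k)
  if (any(keep)) {
    tt <- table(factor(i[keep], levels = seq_len(k)),
                factor(j[keep], levels = seq_len(k)))
    m <- matrix(as.numeric(tt), k, k) / nrow(pool)
  }
  new("DensityGrid", lo = lo, hi = hi, cell = cell, proportions = m,
      nPool = nrow(pool))
}

## Unnormalized bivariate-normal log density (constant terms dropped) at
## points (x, y).
bvnLogKernel <- function(x, y, params) {
  u <- (x - params@muFold) / params@sigmaFold
  v <- (y - params@muBind) / params@sigmaBind
  -(u^2 - 2 * params@rho * u * v + v^2) / (2 * (1 - params@rho^2))
}

#' Truncated bivariate-normal cell probabilities
#'
#' Evaluates the bivariate normal density at the cell centers of the
#' truncation square and renormalizes so the cell probabilities sum to 1.
#' Rows index the fold axis, columns the bind axis.
#'
#' @param params a [SelectionSurfaceParams-class].
#' @param lo,hi,cell grid geometry (defaults -3, 3, 0.25).
#' @return matrix of cell probabilities summing to 1.
#' @export
truncatedBvnCellDensities <- function(params, lo = -3, hi = 3,
                                      cell = 0.25) {
  stopifnot(is(params, "SelectionSurfaceParams"))
  ctr <- cellCenters(lo, hi, cell)
  g <- expand.grid(x = ctr, y = ctr)
  d <- exp(bvnLogKernel(g$x, g$y, params))
  m <- matrix(d, length(ctr), length(ctr))
  m / sum(m)
}

## Resolve observation weights; default 1.
obsWeights <- function(obs, weighted = TRUE) {
  w <- if (weighted && !is.null(obs$weight)) as.numeric(obs$weight)
       else rep(1, nrow(obs))
  if (any(w < 1)) stop("weights must be >= 1")
  w
}

## Map observations to (possibly clamped) cell indices; returns list with
## i, j and nClamped.
obsCells <- function(obs, lo, hi, cell) {
  k <- as.integer(round((hi - lo) / cell))
  clampIdx <- function(v) pmin(pmax(floor((v - lo) / cell) + 1, 1L), k)
  i <- clampIdx(obs$ddg_fold)
  j <- clampIdx(obs$ddg_bind)
  out <- obs$ddg_fold < lo | obs$ddg_fold > hi |
         obs$ddg_bind < lo | obs$ddg_bind > hi
  list(i = as.integer(i), j = as.integer(j), nClamped = sum(out))
}

## Accessible mass per observation cell with the zero-mass floor applied.
## Returns list(mass, nFloored).
flooredMass <- function(grid, ci, cj) {
  mass <- grid@proportions[cbind(ci, cj)]
  zero <- mass == 0
  if (any(zero)) {
    mass[zero] <- 1 / (2 * grid@nPool)
    warning(sum(zero), " observation(s) in zero-mass accessible cell(s); ",
            "mass floored at 1/(2*", grid@nPool, ")", call. = FALSE)
  }
  list(mass = mass, nFloored = sum(zero))
}

#' Log-score of a candidate selection surface
#'
#' The probability of observing a substitution at a given (ddG_fold,
#' ddG_bind) is modeled as proportional to the accessible-substitution
#' density in that grid cell times the (truncated, renormalized)
#' selection-function probability of the cell. Because that product is a
#' probability model over cells, it is normalized by its total mass
#' C(params) = sum over cells of accessible_mass * selection_prob, so the
#' score is the weighted log-likelihood
#' sum_i w_i * log(A_i * s_i / C(params)). Without this normalizer the
#' accessible-density terms would be constant in the parameters and the
#' fit would ignore the shape of the accessible pool entirely.
#' Observations outside the grid bounds are clamped to the nearest
#' boundary cell; accessible cells with zero mass that contain an
#' observation are floored at 1/(2 * pool size) with a warning (the
#' floored mass enters only the observation terms, not C).
#'
#' @param params a [SelectionSurfaceParams-class].
#' @param accessibleDensity a [DensityGrid-class] from
#'   [gridAccessibleDensity()].
#' @param obs data.frame of observations with \code{ddg_fold},
#'   \code{ddg_bind} and optional \code{weight} columns; non-empty.
#' @param weighted logical; use the \code{weight} column when present.
#' @return the log-score (a single number).
#' @export
scoreParams <- function(params, accessibleDensity, obs, weighted = TRUE) {
  stopifnot(is(accessibleDensity, "DensityGrid"))
  if (!nrow(obs)) stop("empty observation set")
  g <- accessibleDensity
  w <- obsWeights(obs, weighted)
  oc <- obsCells(obs, g@lo, g@hi, g@cell)
  am <- flooredMass(g, oc$i, oc$j)
  sel <- truncatedBvnCellDensities(params, g@lo, g@hi, g@cell)
  C <- sum(g@proportions * sel)
  sum(w * (log(am$mass) + log(sel[cbind(oc$i, oc$j)]) - log(C)))
}

#' Parameter lattices for the selection-surface scan
#'
#' \code{surfaceLattice()} is the full scan: means from -1 to 1 in steps
#' of 0.1, standard deviations from 0.25 to 1.5 in steps of 0.0625, and
#' correlations from -0.9 to 0.9 in steps of 0.1 (the +/-1 endpoints are
#' excluded because the covariance is singular there). This lattice has
#' about 3.7 million combinations. \code{coarseSurfaceLattice()} is a
#' documented reduced lattice for fast fits and tests: mu step 0.25,
#' sigma in {0.5, 0.75, 1, 1.25}, rho in {-0.5, 0, 0.5}.
#'
#' @return list with components \code{muFold}, \code{muBind},
#'   \code{sigmaFold}, \code{sigmaBind}, \code{rho}.
#' @export
surfaceLattice <- function() {
  list(muFold = seq(-1, 1, by = 0.1), muBind = seq(-1, 1, by = 0.1),
       sigmaFold = seq(0.25, 1.5, by = 0.0625),
       sigmaBind = seq(0.25, 1.5, by = 0.0625),
       rho = seq(-0.9, 0.9, by = 0.1))
}

#' @rdname surfaceLattice
#' @export
coarseSurfaceLattice <- function() {
  list(muFold = seq(-1, 1, by = 0.25), muBind = seq(-1, 1, by = 0.25),
       sigmaFold = c(0.5, 0.75, 1, 1.25), sigmaBind = c(0.5, 0.75, 1, 1.25),
       rho = c(-0.5, 0, 0.5))
}

#' Fit the selection surface by exhaustive lattice scan
#'
#' Scores every parameter combination on the lattice with [scoreParams()]
#' semantics and returns the argmax. Ties are broken by the first maximum
#' in lexicographic (muFold, muBind, sigmaFold, sigmaBind, rho) order.
#' The scan is vectorized: for each (sigmaFold, sigmaBind, rho)
#' combination the truncation normalizer and the observation terms for
#' all mean pairs are obtained from a handful of matrix operations, so
#' the full default lattice completes in minutes on one core.
#'
#' @param pool accessible pool (data.frame or [DdgTable-class]).
#' @param obs data.frame of observations with \code{ddg_fold},
#'   \code{ddg_bind} and optional \code{weight}.
#' @param lattice lattice spec from [surfaceLattice()] or
#'   [coarseSurfaceLattice()].
#' @param weighted logical; use observation weights.
#' @param lo,hi,cell grid geometry (defaults -3, 3, 0.25).
#' @return a [SelectionSurfaceFit-class].
#' @export
fitSelectionSurface <- function(pool, obs, lattice = surfaceLattice(),
                                weighted = TRUE, lo = -3, hi = 3,
                                cell = 0.25) {
  grid <- gridAccessibleDensity(pool, lo, hi, cell)
  if (!nrow(obs)) stop("empty observation set")
  if (!all(lengths(lattice[c("muFold", "muBind", "sigmaFold", "sigmaBind",
                             "rho")]) >= 1L))
    stop("empty lattice")
  w <- obsWeights(obs, weighted)
  W <- sum(w)
  oc <- obsCells(obs, lo, hi, cell)
  am <- flooredMass(grid, oc$i, oc$j)
  constA <- sum(w * log(am$mass))

  ctr <- cellCenters(lo, hi, cell)
  k <- length(ctr)
  muF <- lattice$muFold
  muB <- lattice$muBind
  nF <- length(muF)
  nB <- length(muB)
  cx <- ctr[oc$i]
  cy <- ctr[oc$j]

  ## centered-coordinate matrices: rows = mu values, cols = cells / obs
  XF <- outer(muF, ctr, function(m, x) x - m)     # nF x k
  XB <- outer(muB, ctr, function(m, y) y - m)     # nB x k
  OF <- outer(muF, cx, function(m, x) x - m)      # nF x nObs
  OB <- outer(muB, cy, function(m, y) y - m)      # nB x nObs

  best <- NULL
  bestScore <- -Inf
  grpF <- rep(seq_len(nF), each = k)
  grpB <- rep(seq_len(nB), each = k)
  ## accessible-mass matrix tiled to the (mean, cell) layout of M below,
  ## for the product normalizer C = sum_cells A * kernel / Z
  Atile <- grid@proportions[rep(seq_len(k), nF), rep(seq_len(k), nB)]

  for (sf in lattice$sigmaFold) {
    Uc <- as.vector(t(XF)) / sf   # length nF*k, cell index fastest
    Uo <- OF / sf
    for (sb in lattice$sigmaBind) {
      Vc <- as.vector(t(XB)) / sb
      Vo <- OB / sb
      for (rho in lattice$rho) {
        c2 <- 2 * (1 - rho^2)
        ## normalizer ZA(muF, muB) = sum over the k x k cells of
        ## accessible mass times the bvn kernel, for every mean pair at
        ## once; the truncation normalizer Z cancels between the cell
        ## probabilities and C, leaving score = constA + N - W*log(ZA)
        E <- tcrossprod(Uc, Vc) * (2 * rho / c2)
        E <- E - Uc^2 / c2                    # column-major recycling
        E <- sweep(E, 2L, Vc^2 / c2, "-")
        MA <- exp(E) * Atile
        ZAf <- rowsum(MA, grpF, reorder = FALSE)         # nF x (nB*k)
        ZA <- t(rowsum(t(ZAf), grpB, reorder = FALSE))   # nF x nB
        ## observation kernel term summed with weights
        af <- as.vector(Uo^2 %*% w)                      # nF
        bb <- as.vector(Vo^2 %*% w)                      # nB
        cross <- (Uo * rep(w, each = nF)) %*% t(Vo)      # nF x nB
        N <- -(outer(af, rep(1, nB)) + outer(rep(1, nF), bb) -
               2 * rho * cross) / c2
        S <- constA + N - W * log(ZA)
        mx <- max(S)
        if (mx >= bestScore) {
          hit <- which(S == mx, arr.ind = TRUE)
          hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
          cand <- c(muF[hit[1L, 1L]], muB[hit[1L, 2L]], sf, sb, rho)
          replace <- mx > bestScore ||
            (mx == bestScore && !is.null(best) && lexLess(cand, best))
          if (replace) {
            bestScore <- mx
            best <- cand
          }
        }
      }
    }
  }
  scanSize <- nF * nB * length(lattice$sigmaFold) *
    length(lattice$sigmaBind) * length(lattice$rho)
  new("SelectionSurfaceFit",
      best = SelectionSurfaceParams(best[1L], best[2L], best[3L],
                                    best[4L], best[5L]),
      logScore = bestScore, nClamped = as.integer(oc$nClamped),
      scanSize = as.integer(scanSize), nFloored = as.integer(am$nFloored))
}

## TRUE when parameter vector a precedes b lexicographically.
lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Export a fitted surface as a contour-ready grid
#'
#' Writes a TSV of (x, y, density) over the truncation square, where
#' density is the renormalized truncated bivariate-normal cell
#' probability, for plotting contour maps of the fitted selection
#' function.
#'
#' @param params a [SelectionSurfaceParams-class].
#' @param path output file path.
#' @param lo,hi,cell grid geometry (defaults -3, 3, 0.25).
#' @export
writeSurfaceGrid <- function(params, path, lo = -3, hi = 3, cell = 0.25) {
  ctr <- cellCenters(lo, hi, cell)
  m <- truncatedBvnCellDensities(params, lo, hi, cell)
  g <- expand.grid(x = ctr, y = ctr)
  out <- data.frame(x = g$x, y = g$y, density = as.vector(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
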