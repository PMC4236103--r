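test_that("accessible density gridding has the documented geometry", {
  p4 <- data.frame(ddg_fold = rep(0.1, 4), ddg_bind = rep(0.1, 4))
  g <- gridAccessibleDensity(p4)
  expect_identical(dim(g@proportions), c(24L, 24L))
  expect_equal(sum(g@proportions), 1)
  expect_equal(max(g@proportions), 1)  # all mass in one cell
  ## a point outside the bounds carries no mass
  p5 <- rbind(p4, data.frame(ddg_fold = 3.26, ddg_bind = 0))
  g5 <- gridAccessibleDensity(p5)
  expect_equal(sum(g5@proportions), 4 / 5)
  ## the upper boundary belongs to the last (closed) cell
  pb <- data.frame(ddg_fold = 3, ddg_bind = 3)
  gb <- gridAccessibleDensity(pb)
  expect_equal(gb@proportions[24, 24], 1)
  expect_error(gridAccessibleDensity(p4[0, ]), "empty pool")
})

test_that("truncated bivariate-normal cell probabilities match a direct
           evaluation oracle", {
  ctr <- -3 + (1:24 - 0.5) * 0.25
  for (par in list(SelectionSurfaceParams(0, 0, 1, 1, 0),
                   SelectionSurfaceParams(-0.4, 0.6, 0.5, 1.2, 0.5),
                   SelectionSurfaceParams(0.3, -0.2, 0.8, 0.6, -0.7))) {
    m <- truncatedBvnCellDensities(par)
    expect_equal(sum(m), 1, tolerance = 1e-9)
    ## independent closed-form evaluation at cell centers
    o <- outer(ctr, ctr, function(x, y) {
      u <- (x - par@muFold) / par@sigmaFold
      v <- (y - par@muBind) / par@sigmaBind
      exp(-(u^2 - 2 * par@rho * u * v + v^2) / (2 * (1 - par@rho^2)))
    })
    expect_equal(m, o / sum(o), tolerance = 1e-12)
  }
  ## symmetric params: symmetric matrix, mode at the origin cells
  m0 <- truncatedBvnCellDensities(SelectionSurfaceParams(0, 0, 1, 1, 0))
  expect_equal(m0, t(m0))
  expect_true(which.max(m0) %in% c(12 + 11 * 24, 12 + 12 * 24,
                                   13 + 11 * 24, 13 + 12 * 24))
  ## rho sign flip mirrors the matrix across one axis
  mp <- truncatedBvnCellDensities(SelectionSurfaceParams(0, 0, 1, 1, 0.5))
  mn <- truncatedBvnCellDensities(SelectionSurfaceParams(0, 0, 1, 1, -0.5))
  expect_equal(mp, mn[, 24:1], tolerance = 1e-12)
  expect_error(SelectionSurfaceParams(0, 0, 1, 1, 1), "rho")
})

test_that("surface score equals the naive loop oracle", {
  set.seed(13)
  pool <- data.frame(ddg_fold = rnorm(1000, 0.6, 1.3),
                     ddg_bind = rnorm(1000, 0.3, 1.0))
  g <- gridAccessibleDensity(pool)
  obs <- data.frame(ddg_fold = rnorm(40, 0, 1), ddg_bind = rnorm(40, 0, 1),
                    weight = sample(1:3, 40, replace = TRUE))
  for (par in list(SelectionSurfaceParams(0, 0, 1, 1, 0),
                   SelectionSurfaceParams(-0.5, 0.5, 0.75, 0.75, 0),
                   SelectionSurfaceParams(0.2, -0.1, 0.5, 1.4, -0.4))) {
    expect_equal(suppressWarnings(scoreParams(par, g, obs)),
                 naiveScore(par, g, obs), tolerance = 1e-9)
  }
  ## linearity in weights
  obs2 <- obs
  obs2$weight <- obs$weight * 2
  par <- SelectionSurfaceParams(0.1, 0.1, 1, 1, 0)
  expect_equal(suppressWarnings(scoreParams(par, g, obs2)),
               2 * suppressWarnings(scoreParams(par, g, obs)),
               tolerance = 1e-9)
  ## score difference: selection log-ratios plus the normalizer term
  p1 <- SelectionSurfaceParams(0, 0, 1, 1, 0)
  p2 <- SelectionSurfaceParams(0.5, -0.5, 0.8, 1.2, 0.3)
  s1 <- truncatedBvnCellDensities(p1)
  s2 <- truncatedBvnCellDensities(p2)
  ci <- pmin(pmax(floor((obs$ddg_fold + 3) / 0.25) + 1, 1), 24)
  cj <- pmin(pmax(floor((obs$ddg_bind + 3) / 0.25) + 1, 1), 24)
  w <- obs$weight
  want <- sum(w * (log(s1[cbind(ci, cj)]) - log(s2[cbind(ci, cj)]))) -
    sum(w) * (log(sum(g@proportions * s1)) - log(sum(g@proportions * s2)))
  expect_equal(suppressWarnings(scoreParams(p1, g, obs)) -
                 suppressWarnings(scoreParams(p2, g, obs)), want,
               tolerance = 1e-9)
})

test_that("a single observation in the only occupied accessible cell
           scores zero for any surface", {
  pool <- data.frame(ddg_fold = rep(0.1, 20), ddg_bind = rep(0.1, 20))
  g <- gridAccessibleDensity(pool)
  obs <- data.frame(ddg_fold = 0.1, ddg_bind = 0.1)
  for (par in list(SelectionSurfaceParams(0, 0, 1, 1, 0),
                   SelectionSurfaceParams(-1, 1, 0.25, 1.5, 0.9)))
    expect_equal(scoreParams(par, g, obs), 0, tolerance = 1e-12)
})

test_that("the lattice scan is deterministic and matches scoreParams at
           its optimum", {
  tab <- synthDdgTable(PoolModel(L = 60, seed = 19))
  acc <- accessibleSubs(tab)
  obs <- synthObservedUnderSelection(
    tab, SelectionSurfaceParams(0, 0, 1, 1, 0), 60, seed = 20)
  lat <- coarseSurfaceLattice()
  f1 <- fitSelectionSurface(acc, obs, lattice = lat)
  f2 <- fitSelectionSurface(acc, obs, lattice = lat)
  expect_identical(f1@best, f2@best)
  expect_identical(f1@logScore, f2@logScore)
  g <- gridAccessibleDensity(acc)
  expect_equal(f1@logScore, scoreParams(f1@best, g, obs),
               tolerance = 1e-8)
  expect_identical(f1@scanSize, as.integer(9 * 9 * 4 * 4 * 3))
  ## unit weights and unweighted fits coincide
  obsW <- obs
  obsW$weight <- 1
  f3 <- fitSelectionSurface(acc, obsW, lattice = lat, weighted = TRUE)
  f4 <- fitSelectionSurface(acc, obsW, lattice = lat, weighted = FALSE)
  expect_identical(f3@best, f4@best)
})

test_that("point-mass observations drive the surface to the nearest
           lattice mean with minimal spread", {
  set.seed(21)
  pool <- data.frame(ddg_fold = rnorm(2000, 0.5, 1.2),
                     ddg_bind = rnorm(2000, 0.3, 1.0))
  obs <- data.frame(ddg_fold = rep(-0.625, 5), ddg_bind = rep(0.875, 5))
  f <- fitSelectionSurface(pool, obs, lattice = coarseSurfaceLattice())
  expect_lte(abs(f@best@muFold - (-0.625)), 0.25)
  expect_lte(abs(f@best@muBind - 0.875), 0.25)
  expect_equal(f@best@sigmaFold, min(coarseSurfaceLattice()$sigmaFold))
  expect_equal(f@best@sigmaBind, min(coarseSurfaceLattice()$sigmaBind))
})

test_that("out-of-bounds observations are clamped and zero-mass cells
           floored, with counts reported", {
  pool <- data.frame(ddg_fold = rnorm(500, 0, 0.5),
                     ddg_bind = rnorm(500, 0, 0.5))
  obs <- data.frame(ddg_fold = c(3.26, 0), ddg_bind = c(0, 2.9))
  expect_warning(
    f <- fitSelectionSurface(pool, obs, lattice = coarseSurfaceLattice()),
    "floored")
  expect_identical(f@nClamped, 1L)
  expect_gte(f@nFloored, 1L)
})
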