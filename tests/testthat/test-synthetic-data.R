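test_that("synthetic tables are complete, calibrated and reproducible", {
  m <- PoolModel(L = 50, seed = 3)
  tab <- synthDdgTable(m)
  expect_identical(nrow(ddgData(tab)), 950L)
  acc <- accessibleSubs(tab)
  ## realized destabilizing fractions hit the targets among accessible
  expect_lte(abs(fractionDestabilizing(acc$ddg_fold) - 0.729), 0.02)
  expect_lte(abs(fractionDestabilizing(acc$ddg_bind) - 0.700), 0.02)
  ## determinism
  tab2 <- synthDdgTable(PoolModel(L = 50, seed = 3))
  expect_identical(ddgData(tab), ddgData(tab2))
  expect_identical(attr(tab, "cds"), attr(tab2, "cds"))
  ## different seed, different values
  tab3 <- synthDdgTable(PoolModel(L = 50, seed = 4))
  expect_false(identical(ddgData(tab)$ddg_fold, ddgData(tab3)$ddg_fold))
  ## infeasible calibration targets are rejected
  expect_error(PoolModel(L = 10, targetFracDestabilizingFold = 0),
               "target destabilizing")
})

test_that("synthetic accessibility is genetically coherent with the
           simulated CDS", {
  tab <- synthDdgTable(PoolModel(L = 40, seed = 9))
  cds <- attr(tab, "cds")
  expect_identical(translateCds(cds, removeInitialMet = TRUE),
                   paste(ddgData(tab)$aa_from[!duplicated(
                     ddgData(tab)$site)], collapse = ""))
  expect_identical(nrow(crossCheckAccessibility(tab, cds)), 0L)
  ## no site offers more than 9 accessible targets
  expect_true(all(table(accessibleSubs(tab)$site) <= 9))
})

test_that("fold and bind axes are generated independently", {
  tab <- synthDdgTable(PoolModel(L = 426, seed = 17))
  expect_identical(nrow(ddgData(tab)), 8094L)
  r <- correlationFoldBind(ddgData(tab))$r
  expect_lt(abs(r), 0.1)
})

test_that("selection-biased sampling reduces to uniform under a flat
           surface", {
  tab <- synthDdgTable(PoolModel(L = 120, seed = 21))
  acc <- accessibleSubs(tab)
  flat <- SelectionSurfaceParams(0, 0, 50, 50, 0)
  inb <- acc[abs(acc$ddg_fold) <= 3 & abs(acc$ddg_bind) <= 3, ]
  obs <- synthObservedUnderSelection(tab, flat, 500, seed = 3)
  ## chi-square goodness of fit of draw counts across 10 equal bins of
  ## the in-bounds pool
  key <- paste(inb$site, inb$aa_to)
  grp <- cut(seq_len(nrow(inb)), 10, labels = FALSE)
  cnt <- tabulate(grp[match(paste(obs$site, obs$aa_to), key)], 10)
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
  ## drawing every in-bounds substitution returns the whole set
  whole <- synthObservedUnderSelection(tab, flat, nrow(inb), seed = 4)
  expect_setequal(paste(whole$site, whole$aa_to), key)
  expect_error(
    synthObservedUnderSelection(tab, flat, nrow(inb) + 1, seed = 5),
    "positive selection density")
  ## reproducibility and weights
  o1 <- synthObservedUnderSelection(tab, flat, 30, seed = 6,
                                    weightLambda = 0.7)
  o2 <- synthObservedUnderSelection(tab, flat, 30, seed = 6,
                                    weightLambda = 0.7)
  expect_identical(o1, o2)
  expect_true(all(o1$weight >= 1))
})

test_that("a tight origin-centered surface selects smaller effects than
           the pool average", {
  tab <- synthDdgTable(PoolModel(L = 80, seed = 23))
  acc <- accessibleSubs(tab)
  tight <- SelectionSurfaceParams(0, 0, 0.5, 0.5, 0)
  wins <- 0
  for (s in 1:20) {
    o <- synthObservedUnderSelection(tab, tight, 50, seed = 200 + s)
    wins <- wins + (mean(abs(o$ddg_fold)) < mean(abs(acc$ddg_fold)) &&
                      mean(abs(o$ddg_bind)) < mean(abs(acc$ddg_bind)))
  }
  expect_gte(wins, 19)
})

test_that("synthetic experiments honor topology specs and seeds", {
  tab <- synthDdgTable(PoolModel(L = 50, seed = 25))
  ## one linear experiment with 3 substitutions: a chain of 3 segments
  reg <- synthExperiments(1, tab, nSubs = 3, seed = 1)
  s <- reg[[1]]@segments
  expect_identical(nrow(s), 3L)
  expect_identical(s$parent, c(NA, "s1", "s2"))
  expect_true(all(lengths(s$substitutions) == 1L))
  ## two binary splits: 4 leaves
  regB <- synthExperiments(1, tab, nSplits = 2, seed = 2)
  sb <- regB[[1]]@segments
  leaves <- setdiff(sb$segment, sb$parent)
  expect_length(leaves, 4L)
  expect_identical(nrow(sb), 7L)
  ## identical seeds give identical registries
  r1 <- synthExperiments(5, tab, seed = 7)
  r2 <- synthExperiments(5, tab, seed = 7)
  expect_identical(lapply(r1, function(e) e@segments$substitutions),
                   lapply(r2, function(e) e@segments$substitutions))
  expect_identical(vapply(r1, function(e) e@temperatureClass, ""),
                   vapply(r2, function(e) e@temperatureClass, ""))
  classes <- vapply(r1, function(e) e@temperatureClass, "")
  expect_true(all(classes %in% c("high", "normal", "variable")))
})
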