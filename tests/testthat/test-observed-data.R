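test_that("consensus comparison yields unique ancestral-to-variant keys", {
  seqs <- c("AAW", "AAW", "ATW")
  cs <- consensusSubstitutions(seqs)
  expect_identical(cs, data.frame(site = 2L, aa_from = "A", aa_to = "T",
                                  stringsAsFactors = FALSE))
  ## identical sequences imply no substitutions
  expect_identical(nrow(consensusSubstitutions(c("ACDE", "ACDE"))), 0L)
  ## duplicates across sequences collapse
  cs2 <- consensusSubstitutions(c("AA", "AT", "AT", "AA", "AA"))
  expect_identical(nrow(cs2), 1L)
  ## order invariance
  set.seed(31)
  seqs3 <- c("ACDEF", "ACDEY", "ACREF", "ACDEF")
  for (i in 1:5) {
    perm <- sample(seqs3)
    expect_identical(consensusSubstitutions(perm),
                     consensusSubstitutions(seqs3))
  }
  ## ties error unless a policy is chosen
  expect_error(consensusSubstitutions(c("A", "T")), "tie")
  tb <- consensusSubstitutions(c("A", "T"), tieBreak = "first-in-alphabet")
  expect_identical(tb$aa_from, "A")
  expect_identical(tb$aa_to, "T")
  expect_error(consensusSubstitutions(c("AA", "A")), "equal length")
})

test_that("cumulative trajectories sum ddG along the segment tree", {
  fix <- makeStudyFixture(L = 40, seed = 60)
  tab <- fix$table
  d <- accessibleSubs(tab)
  key <- function(i) formatSubKey(d$site[i], d$aa_from[i], d$aa_to[i])

  ## no substitutions: a single origin point
  e0 <- Experiment("none", character(0))
  t0 <- cumulativeTrajectory(e0, tab)
  expect_equal(c(t0$cum_ddg_fold, t0$cum_ddg_bind), c(0, 0))

  ## linear chain accumulates the segment sums
  segs <- data.frame(segment = c("s1", "s2"),
                     parent = c(NA, "s1"), time = c(1, 2),
                     stringsAsFactors = FALSE)
  segs$substitutions <- list(key(1), key(2))
  e1 <- Experiment("lin", segs)
  t1 <- cumulativeTrajectory(e1, tab)
  expect_equal(t1$cum_ddg_fold[t1$segment == "s2"],
               d$ddg_fold[1] + d$ddg_fold[2])
  expect_equal(t1$cum_ddg_bind[t1$segment == "s2"],
               d$ddg_bind[1] + d$ddg_bind[2])

  ## branches accumulate independently from their shared parent
  segs2 <- data.frame(segment = c("root", "a", "b"),
                      parent = c(NA, "root", "root"), time = NA,
                      stringsAsFactors = FALSE)
  segs2$substitutions <- list(key(1), key(2), key(3))
  e2 <- Experiment("branch", segs2)
  t2 <- cumulativeTrajectory(e2, tab)
  expect_equal(t2$cum_ddg_fold[t2$segment == "a"],
               d$ddg_fold[1] + d$ddg_fold[2])
  expect_equal(t2$cum_ddg_fold[t2$segment == "b"],
               d$ddg_fold[1] + d$ddg_fold[3])

  ## unknown keys are reported by name
  bad <- Experiment("bad", "A999C")
  expect_error(cumulativeTrajectory(bad, tab), "A999C")
})

test_that("individual effect radius is the largest Euclidean norm", {
  expect_equal(individualEffectRadius(
    data.frame(ddg_fold = 3, ddg_bind = 4)), 5)
  expect_equal(individualEffectRadius(
    data.frame(ddg_fold = c(1, 0), ddg_bind = c(0, 2))), 2)
  expect_equal(individualEffectRadius(
    data.frame(ddg_fold = c(0, 0), ddg_bind = c(0, 0))), 0)
  expect_error(individualEffectRadius(
    data.frame(ddg_fold = numeric(0), ddg_bind = numeric(0))), "empty")
})

test_that("experiment weights count distinct experiments, with filters", {
  mk <- function(id, keys, temp = "normal", anc = TRUE)
    Experiment(id, keys, temperatureClass = temp, ancestorStart = anc)
  exps <- list(mk("e1", "A1C", "high"), mk("e2", "A1C", "high", anc = FALSE),
               mk("e3", "A1C"), mk("e4", "C2G"), mk("e5", character(0)))
  w <- experimentWeights(exps)
  expect_identical(w$weight[w$key == "A1C"], 3L)
  expect_identical(w$weight[w$key == "C2G"], 1L)
  ## a key repeated across segments of one experiment counts once
  segs <- data.frame(segment = c("s1", "s2"), parent = c(NA, "s1"),
                     time = NA, stringsAsFactors = FALSE)
  segs$substitutions <- list("A1C", "A1C")
  wdup <- experimentWeights(list(Experiment("dup", segs)))
  expect_identical(wdup$weight, 1L)
  ## temperature and ancestor filters
  wh <- experimentWeights(exps, temperatureClass = "high",
                          ancestorOnly = TRUE)
  expect_identical(wh$weight[wh$key == "A1C"], 1L)
  expect_false("C2G" %in% wh$key)
})

test_that("experiment registries round-trip through YAML", {
  fix <- makeStudyFixture(L = 30, seed = 61)
  reg <- fix$registry
  f <- tempfile(fileext = ".yaml")
  writeExperimentRegistry(reg, f)
  back <- readExperimentRegistry(f)
  expect_identical(names(back), names(reg))
  for (id in names(reg)) {
    expect_identical(back[[id]]@temperatureClass, reg[[id]]@temperatureClass)
    expect_identical(back[[id]]@ancestorStart, reg[[id]]@ancestorStart)
    expect_identical(back[[id]]@segments$segment, reg[[id]]@segments$segment)
    expect_identical(back[[id]]@segments$substitutions,
                     reg[[id]]@segments$substitutions)
  }
})

test_that("trajectory endpoints are invariant to substitution order
           within segments", {
  fix <- makeStudyFixture(L = 40, seed = 62)
  tab <- fix$table
  d <- accessibleSubs(tab)
  set.seed(63)
  for (i in 1:50) {
    idx <- sample(nrow(d), 5)
    keys <- formatSubKey(d$site[idx], d$aa_from[idx], d$aa_to[idx])
    e1 <- Experiment("p1", keys)
    e2 <- Experiment("p2", sample(keys))
    t1 <- cumulativeTrajectory(e1, tab)
    t2 <- cumulativeTrajectory(e2, tab)
    expect_equal(t1$cum_ddg_fold, t2$cum_ddg_fold)
    expect_equal(t1$cum_ddg_bind, t2$cum_ddg_bind)
  }
})
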