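test_that("doses follow each strategy's schedule", {
  cyc <- strategySchedule("CYCLING", period = 50)
  expect_equal(unname(dosesAt(cyc, 49.9)[1, ]), c(240, 0))
  expect_equal(unname(dosesAt(cyc, 50.1)[1, ]), c(0, 240))
  expect_equal(unname(dosesAt(cyc, 100)[1, ]), c(240, 0))

  mix <- strategySchedule("MIXING", period = 50)
  expect_equal(unname(dosesAt(mix, 0)), rbind(c(240, 0), c(0, 240)))
  expect_equal(unname(dosesAt(mix, 62)), rbind(c(0, 240), c(240, 0)))

  expect_equal(unname(dosesAt(strategySchedule("COCKTAIL_CMB"), 17)[1, ]),
               c(120, 120))
  expect_equal(unname(dosesAt(strategySchedule("SINGLE"), 3)[1, ]), c(240, 0))
  expect_equal(unname(dosesAt(strategySchedule("NONE"), 3)[1, ]), c(0, 0))
})

test_that("every drug-using strategy spends the full dose budget at all times", {
  times <- c(0, 0.1, 25, 49.95, 50, 75.5, 1000.3)
  for (st in c("CONTROL", "SINGLE", "CYCLING", "MIXING", "COCKTAIL_CMB",
               "COCKTAIL_SEP")) {
    sched <- strategySchedule(st, period = 50)
    for (tt in times)
      expect_equal(unname(rowSums(dosesAt(sched, tt))),
                   rep(240, sched@nArms))
  }
})

test_that("strategy growth uses the right pharmacodynamic composition", {
  sp0 <- strainPanel(0)
  # full resistance to the sole drug: dose sits exactly at the MIC
  gSingle <- growthForStrategy(strategySchedule("SINGLE"), sp0, 0)
  expect_equal(gSingle["R1", 1], 0, tolerance = 1e-12)
  # no drugs: drug-free growth for every strain
  gNone <- growthForStrategy(strategySchedule("NONE"), sp0, 0)
  expect_equal(unname(gNone[, 1]), rep(0.25, 4))
  # separate cocktail, super-resistant double mutant: two 1/6 damage terms
  gSep <- growthForStrategy(strategySchedule("COCKTAIL_SEP"), sp0, 0)
  expect_equal(gSep["R3", 1], 0.25 - 2 / 6, tolerance = 1e-12)
  # combined cocktail differs from separate for the same strains
  gCmb <- growthForStrategy(strategySchedule("COCKTAIL_CMB"), sp0, 0)
  expect_equal(gCmb["R3", 1], 0, tolerance = 1e-12)
})

test_that("a mixing arm swap is a pure relabelling of the arms", {
  mix <- strategySchedule("MIXING", period = 50)
  sp <- strainPanel(0.4)
  g0 <- growthForStrategy(mix, sp, 10)
  g1 <- growthForStrategy(mix, sp, 60)   # one period later
  expect_equal(unname(g0[, c(2, 1)]), unname(g1))
  # hence the population-level growth is invariant under the swap
  expect_equal(abxtradeoff:::.effectiveGrowth(mix, sp, 10, stdPd),
               abxtradeoff:::.effectiveGrowth(mix, sp, 60, stdPd))
})

test_that("configuration errors are reported", {
  expect_error(strategySchedule("PULSED"), "unknown strategy")
  expect_error(dosesAt(strategySchedule("SINGLE"), -1), "nonnegative")
  expect_error(
    runToEquilibrium(strategySchedule("CYCLING", period = 50.05),
                     strainPanel(1)),
    "integer multiple")
})
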