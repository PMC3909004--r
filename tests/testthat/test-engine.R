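test_that("baseline scenarios reach their closed-form equilibria", {
  ctl <- equilibriumAt("CONTROL", 0.5)
  expect_true(converged(ctl))
  expect_equal(xHat(ctl), 0.5, tolerance = 1e-6)

  none <- equilibriumAt("NONE", 0.5)
  expect_true(converged(none))
  expect_lt(xHat(none), 1e-9)

  sgl <- equilibriumAt("SINGLE", 0.5)
  expect_equal(xHat(sgl), 0.25 / 0.9, tolerance = 1e-6)
  expect_identical(dominantStrain(sgl), "R1")
})

test_that("frequency is conserved along trajectories", {
  for (st in c("SINGLE", "CYCLING", "COCKTAIL_SEP")) {
    tr <- integrateTrajectory(strategySchedule(st, period = 10),
                              strainPanel(0.6), tMax = 200)
    drift <- max(abs(rowSums(tr[, c("x", "s", "r1", "r2", "r3")]) - 1))
    expect_lt(drift, 1e-9)
  }
})

test_that("halving the step leaves converged equilibria unchanged to 1e-8", {
  s1 <- equilibriumAt("COCKTAIL_SEP", 0.4,
                      settings = IntegrationSettings(dt = 0.1))
  s2 <- equilibriumAt("COCKTAIL_SEP", 0.4,
                      settings = IntegrationSettings(dt = 0.05))
  expect_equal(xHat(s1), xHat(s2), tolerance = 1e-8)
})

test_that("the integrator converges at fourth order in the step size", {
  sp <- strainPanel(0.5)
  sched <- strategySchedule("SINGLE")
  endState <- function(dt) {
    tr <- integrateTrajectory(sched, sp, tMax = 20,
                              settings = IntegrationSettings(dt = dt))
    as.numeric(tr[nrow(tr), c("x", "s", "r1", "r2", "r3")])
  }
  y4 <- endState(0.4); y2 <- endState(0.2); y1 <- endState(0.1)
  e1 <- max(abs(y4 - y2))
  e2 <- max(abs(y2 - y1))
  expect_gt(e1 / e2, 8)   # a fourth-order method gains ~16x per halving
  expect_lt(e1 / e2, 32)
})

test_that("equilibria are independent of the starting composition", {
  inits <- list(c(0.96, 0.01, 0.01, 0.01, 0.01),
                c(0.50, 0.20, 0.10, 0.10, 0.10),
                c(0.10, 0.30, 0.25, 0.25, 0.10))
  xs <- vapply(inits, function(y0)
    xHat(runToEquilibrium(strategySchedule("COCKTAIL_SEP"), strainPanel(0.2),
                          init = y0)), numeric(1))
  expect_lt(max(xs) - min(xs), 1e-6)
})

test_that("hitting the time limit flags the run instead of failing silently", {
  res <- equilibriumAt("SINGLE", 0.5,
                       settings = IntegrationSettings(maxTime = 5))
  expect_false(converged(res))
  expect_equal(res@timeToConvergence, 5)
})

test_that("cycle averages do not depend on the size of the averaging window", {
  a <- equilibriumAt("CYCLING", 1, period = 50,
                     settings = IntegrationSettings(cycleAveragePeriods = 1000L))
  b <- equilibriumAt("CYCLING", 1, period = 50,
                     settings = IntegrationSettings(cycleAveragePeriods = 200L))
  expect_equal(xHat(a), xHat(b), tolerance = 1e-5)
})

test_that("trajectories match an independent integrator", {
  skip_if_not_installed("deSolve")
  sp <- strainPanel(0.3)
  g <- growthVector(sp, 120, 120, "separate")
  rhs <- function(t, y, parms) {
    names(y) <- c("x", "s", "r1", "r2", "r3")
    list(unname(populationDeriv(y, g, stdEpi)))
  }
  y0 <- c(x = 0.96, s = 0.01, r1 = 0.01, r2 = 0.01, r3 = 0.01)
  ref <- deSolve::rk4(y0, seq(0, 30, by = 0.1), rhs, parms = NULL)
  tr <- integrateTrajectory(strategySchedule("COCKTAIL_SEP"), sp, tMax = 30)
  expect_equal(as.numeric(tr[nrow(tr), c("x", "s", "r1", "r2", "r3")]),
               as.numeric(ref[nrow(ref), -1]), tolerance = 1e-10)
})
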