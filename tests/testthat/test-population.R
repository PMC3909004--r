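test_that("the disease-free state is a fixed point", {
  state <- populationState(x = 1)
  g <- c(S = 0.25, R1 = 0, R2 = -0.25, R3 = -0.1)
  expect_equal(unname(populationDeriv(state, g, stdEpi)), rep(0, 5))
})

test_that("the hand-computed resistance-free equilibrium is stationary", {
  # x = s = 1/2 with fully drugged sensitive bacteria: infection betaXS
  # exactly balances clearance (gS - gamma) S
  state <- populationState(x = 0.5, s = 0.5)
  g <- c(S = -0.25, R1 = -0.25, R2 = -0.25, R3 = -0.25)
  d <- populationDeriv(state, g, stdEpi)
  expect_equal(d[["s"]], 0)
  expect_equal(d[["x"]], 0)
})

test_that("derivative components always sum to zero (closed system)", {
  set.seed(11)
  for (i in 1:50) {
    y <- runif(5); y <- y / sum(y)
    state <- populationState(y[1], y[2], y[3], y[4], y[5])
    g <- runif(4, -0.75, 0.25)
    names(g) <- c("S", "R1", "R2", "R3")
    expect_lt(abs(sum(populationDeriv(state, g, stdEpi))), 1e-14)
  }
})

test_that("uninfected dynamics follow infection loss plus clearance gain", {
  state <- populationState(0.4, 0.3, 0.1, 0.15, 0.05)
  g <- c(S = -0.2, R1 = 0, R2 = -0.3, R3 = -0.4)
  d <- populationDeriv(state, g, stdEpi)
  w <- c(1, 0.9, 0.9, 0.9)
  expected <- -stdEpi@beta * state[["x"]] * sum(w * state[2:5]) -
    sum((g - stdEpi@gamma) * state[2:5])
  expect_equal(d[["x"]], expected)
})

test_that("compiled and reference right-hand sides agree along a trajectory", {
  sched <- strategySchedule("COCKTAIL_SEP")
  sp <- strainPanel(0.3)
  g <- growthVector(sp, 120, 120, "separate")
  tr <- integrateTrajectory(sched, sp, tMax = 5,
                            settings = IntegrationSettings(dt = 0.5))
  # redo the same RK4 steps in plain R through populationDeriv
  y <- populationState(0.96, 0.01, 0.01, 0.01, 0.01)
  dt <- 0.5
  for (i in seq_len(10)) {
    k1 <- populationDeriv(y, g, stdEpi)
    k2 <- populationDeriv(y + dt / 2 * k1, g, stdEpi)
    k3 <- populationDeriv(y + dt / 2 * k2, g, stdEpi)
    k4 <- populationDeriv(y + dt * k3, g, stdEpi)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(as.numeric(tr[11, c("x", "s", "r1", "r2", "r3")]),
               unname(y), tolerance = 1e-14)
})

test_that("per-capita recovery matches its defining ratio", {
  state <- populationState(0, 1)
  g <- c(S = -0.25, R1 = 0, R2 = 0, R3 = 0)
  expect_equal(perCapitaRecovery(state, g, stdEpi), 0.5)
  # no net clearance when growth balances immune clearance
  g0 <- rep(stdEpi@gamma, 4); names(g0) <- c("S", "R1", "R2", "R3")
  state2 <- populationState(0, 0.5, 0.5)
  expect_equal(perCapitaRecovery(state2, g0, stdEpi), 0)
  expect_error(perCapitaRecovery(populationState(1), g, stdEpi), "undefined")
})

test_that("dominant strain reporting handles ties", {
  expect_identical(dominantStrain(populationState(0.1, 0.1, 0.3, 0.3, 0.2)),
                   c("R1", "R2"))
  expect_identical(dominantStrain(populationState(0.2, 0.5, 0.1, 0.1, 0.1)),
                   "S")
})
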