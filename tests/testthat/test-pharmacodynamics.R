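test_that("single-drug response crosses zero exactly at the MIC", {
  pds <- list(stdPd, Pharmacodynamics(0.5, -1, 1), Pharmacodynamics(0.3, -0.1, 2))
  for (pd in pds)
    for (mic in c(1e-6, 0.5, 1, 240, 1e4))
      expect_equal(growthSingle(mic, mic, pd), 0, tolerance = 1e-12)
})

test_that("single-drug response is bounded, monotone and has the right limits", {
  doses <- c(0, 1, 10, 60, 120, 240, 480, 1e4, 1e8)
  g <- growthSingle(doses, mic = 240, stdPd)
  expect_equal(g[1], stdPd@phiMax)
  expect_true(all(diff(g) < 0))
  expect_true(all(g <= stdPd@phiMax & g >= stdPd@phiMin))
  # saturation at phiMin for dose far above the MIC floor
  expect_equal(growthSingle(240, 1e-6, stdPd), -0.25, tolerance = 1e-7)
})

test_that("cocktail responses reduce to the single-drug form when one dose is zero", {
  for (micA in c(1e-6, 120, 240)) {
    expect_identical(growthCombined(90, 0, micA, 240), growthSingle(90, micA))
    expect_identical(growthSeparate(90, 0, micA, 240), growthSingle(90, micA))
  }
  # the negligible-MIC-ratio reduction: a tiny dose against a huge MIC
  expect_equal(growthCombined(120, 1e-10, 240, 240), growthSingle(120, 240),
               tolerance = 1e-6)
})

test_that("combined and separate cocktails take their reference values", {
  expect_equal(growthCombined(0, 0, 240, 240), 0.25)
  expect_equal(growthSeparate(0, 0, 240, 240), 0.25)
  # sensitive strain under the full cocktail saturates at phiMin
  expect_equal(growthCombined(120, 120, 1e-6, 1e-6), -0.25, tolerance = 1e-6)
  # double-resistant strain, no tradeoff: two one-sixth damage terms
  expect_equal(growthSeparate(120, 120, 240, 240), 0.25 - 2 / 6,
               tolerance = 1e-12)
  # single-resistant strain: one bounded and one saturated damage term
  expect_equal(growthSeparate(120, 120, 240, 1e-6), 0.25 - 1 / 6 - 0.5,
               tolerance = 1e-6)
  # combined pools the MIC-scaled doses: at u = 1 the response is zero
  expect_equal(growthCombined(120, 120, 240, 240), 0, tolerance = 1e-12)
})

test_that("both cocktail responses are symmetric under drug relabelling", {
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 0, 300); b <- runif(1, 0, 300)
    mA <- runif(1, 1, 300); mB <- runif(1, 1, 300)
    expect_equal(growthCombined(a, b, mA, mB), growthCombined(b, a, mB, mA),
                 tolerance = 1e-14)
    expect_equal(growthSeparate(a, b, mA, mB), growthSeparate(b, a, mB, mA),
                 tolerance = 1e-14)
  }
})

test_that("separate never exceeds combined at equal doses (double damage)", {
  grid <- expand.grid(a = c(30, 120, 240), b = c(30, 120, 240),
                      mA = c(60, 240), mB = c(60, 240))
  sep <- with(grid, growthSeparate(a, b, mA, mB))
  cmb <- with(grid, growthCombined(a, b, mA, mB))
  expect_true(all(sep <= cmb + 1e-12))
  # and separate can fall below phiMin while combined cannot
  expect_lt(growthSeparate(240, 240, 1e-6, 1e-6), stdPd@phiMin)
  expect_gte(growthCombined(240, 240, 1e-6, 1e-6), stdPd@phiMin)
})

test_that("tradeoff map scales the double-resistant MICs and clamps at the floor", {
  expect_equal(unname(tradeoffMics(0.5)), c(120, 120))
  expect_equal(unname(tradeoffMics(0)), c(240, 240))
  expect_equal(unname(tradeoffMics(1)), c(1e-6, 1e-6))
  expect_equal(unname(tradeoffMics(0.75)), c(60, 60))
  expect_error(tradeoffMics(-0.1), "omega")
  expect_error(tradeoffMics(1.5), "omega")
})

test_that("strain panel encodes the resistance schema", {
  sp <- strainPanel(0.25)
  expect_equal(unname(micA(sp)), c(1e-6, 240, 1e-6, 180))
  expect_equal(unname(micB(sp)), c(1e-6, 1e-6, 240, 180))
  expect_identical(sp@paysCost, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("invalid doses and MICs are rejected", {
  expect_error(growthSingle(-1, 240), "nonnegative")
  expect_error(growthSingle(10, 1e-9), "floor")
  expect_error(growthCombined(10, -2, 240, 240), "nonnegative")
  expect_error(growthVector(strainPanel(0), 240, 240, "single"),
               "one nonzero dose")
})
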