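#' Net growth rate under a single drug
#'
#' Hill-type pharmacodynamic function of drug concentration.  With Hill
#' exponent `k` and dose/MIC ratio `u = a / mic`,
#' \deqn{G(a) = \phi_{max} - \frac{(\phi_{max}-\phi_{min})\,u^k}
#'   {u^k - \phi_{min}/\phi_{max}},}
#' which equals `phiMax` at zero dose, crosses zero exactly at the MIC
#' (`u = 1`) for any parameter values, and saturates at `phiMin` at high
#' dose.  The function is strictly decreasing in the dose.
#'
#' @param a drug concentration (nonnegative; vectorised).
#' @param mic minimal inhibitory concentration, at least the MIC floor
#'   (vectorised).
#' @param pd a [Pharmacodynamics] object.
#' @return net growth rate(s) per unit time, in `[phiMin, phiMax]`.
#' @seealso [growthCombined()], [growthSeparate()]
#' @examples
#' growthSingle(0, 240)    # 0.25, drug-free growth
#' growthSingle(240, 240)  # 0, zero crossing at the MIC
#' @export
growthSingle <- function(a, mic, pd = Pharmacodynamics()) {
  .checkDose(a)
  .checkMic(mic)
  pd@phiMax - .drugEffect(a / mic, pd)
}

#' Net growth rate under a combined (suppressive) two-drug cocktail
#'
#' The two drugs act on the same cellular target, so their MIC-scaled
#' concentrations are pooled into a single Hill term: with
#' `u = a/micA + b/micB` the growth rate is `phiMax - E(u)` where `E` is the
#' drug-effect term of [growthSingle()].  There is a single negative
#' (drug-effect) term, so the cocktail can never depress growth below
#' `phiMin`.  When one dose is zero and the matching MIC ratio is
#' negligible the function reduces to [growthSingle()] for the other drug.
#'
#' @param a,b concentrations of drugs A and B (nonnegative; vectorised).
#' @param micA,micB the strain's MICs against drugs A and B.
#' @inheritParams growthSingle
#' @return net growth rate(s) per unit time, in `[phiMin, phiMax]`.
#' @examples
#' growthCombined(120, 120, micA = 240, micB = 240) # scaled doses sum to 1
#' @export
growthCombined <- function(a, b, micA, micB, pd = Pharmacodynamics()) {
  .checkDose(a); .checkDose(b)
  .checkMic(micA); .checkMic(micB)
  pd@phiMax - .drugEffect(a / micA + b / micB, pd)
}

#' Net growth rate under a separate (additive) two-drug cocktail
#'
#' The two drugs act on distinct targets and inflict independent damage:
#' `G = phiMax - E(a/micA) - E(b/micB)` with two negative drug-effect
#' terms.  Unlike the combined cocktail the growth rate can fall below
#' `phiMin` (double damage, down to `2*phiMin - phiMax`).  With one dose at
#' zero it reduces to [growthSingle()].
#'
#' @inheritParams growthCombined
#' @return net growth rate(s) per unit time.
#' @examples
#' growthSeparate(120, 120, micA = 240, micB = 240) # 0.25 - 1/6 - 1/6
#' @export
growthSeparate <- function(a, b, micA, micB, pd = Pharmacodynamics()) {
  .checkDose(a); .checkDose(b)
  .checkMic(micA); .checkMic(micB)
  pd@phiMax - .drugEffect(a / micA, pd) - .drugEffect(b / micB, pd)
}

# Drug-effect term E(u) = (phiMax - phiMin) u^k / (u^k - phiMin/phiMax).
# E(0) = 0, E(1) = phiMax, E(Inf) = phiMax - phiMin.
.drugEffect <- function(u, pd) {
  uk <- u^pd@hillK
  (pd@phiMax - pd@phiMin) * uk / (uk - pd@phiMin / pd@phiMax)
}

.micFloorDefault <- 1e-6

.checkDose <- function(a) {
  if (any(!is.finite(a)) || any(a < 0))
    stop("drug concentrations must be finite and nonnegative")
  invisible(a)
}

.checkMic <- function(mic, floor = .micFloorDefault) {
  if (any(!is.finite(mic)) || any(mic < floor))
    stop(sprintf("MICs must be finite and at least the floor %g", floor))
  invisible(mic)
}

#' Tradeoff map from single-resistant to double-resistant MICs
#'
#' The double-resistant strain's MICs are pleiotropically constrained by the
#' tradeoff strength `omega`: `micA3 = (1 - omega) * baseMicA1` and
#' `micB3 = (1 - omega) * baseMicB2`, then clamped up to the MIC floor.
#' `omega = 0` yields a super-resistant strain (full MICs against both
#' drugs); `omega = 1` a super-sensitive one (both MICs at the floor);
#' `omega = 1/2` is the linear tradeoff.
#'
#' @param omega tradeoff strength in `[0, 1]`.
#' @param baseMicA1,baseMicB2 MICs of the single-resistant strains `R1` and
#'   `R2` against their respective drugs.
#' @param micFloor smallest admissible MIC; zero MICs are reset to it.
#' @return named numeric of length 2: `micA3`, `micB3`.
#' @examples
#' tradeoffMics(0.5) # linear tradeoff: c(120, 120)
#' @export
tradeoffMics <- function(omega, baseMicA1 = 240, baseMicB2 = 240,
                         micFloor = .micFloorDefault) {
  if (length(omega) != 1L || !is.finite(omega) || omega < 0 || omega > 1)
    stop("'omega' must be a single value in [0, 1]")
  c(micA3 = max((1 - omega) * baseMicA1, micFloor),
    micB3 = max((1 - omega) * baseMicB2, micFloor))
}

#' Construct the standard four-strain panel for a given tradeoff strength
#'
#' Builds the [StrainSet] of the model: `S` with both MICs at the floor,
#' `R1` resistant to drug A only (`micA = baseMicA1`), `R2` resistant to
#' drug B only (`micB = baseMicB2`), and `R3` with both MICs derived via
#' [tradeoffMics()].  All resistant strains pay the transmission cost.
#'
#' @inheritParams tradeoffMics
#' @return a [StrainSet].
#' @examples
#' strainPanel(omega = 0.5)
#' @export
strainPanel <- function(omega, baseMicA1 = 240, baseMicB2 = 240,
                        micFloor = .micFloorDefault) {
  m3 <- tradeoffMics(omega, baseMicA1, baseMicB2, micFloor)
  new("StrainSet",
      strain = c("S", "R1", "R2", "R3"),
      micA = c(micFloor, baseMicA1, micFloor, m3[["micA3"]]),
      micB = c(micFloor, micFloor, baseMicB2, m3[["micB3"]]),
      paysCost = c(FALSE, TRUE, TRUE, TRUE),
      omega = omega, micFloor = micFloor)
}

#' Growth rates of a strain panel under given doses
#'
#' Evaluates the pharmacodynamic model for all four strains of a panel at
#' the doses `(a, b)`, under the `model` appropriate to the strategy:
#' `"single"` (one drug at a time; with both doses zero the growth is the
#' drug-free `phiMax`), `"combined"` or `"separate"`.
#'
#' @param strains a [StrainSet].
#' @param a,b concentrations of drugs A and B.
#' @param model `"single"`, `"combined"` or `"separate"`.
#' @inheritParams growthSingle
#' @return named numeric(4) of growth rates for `S`, `R1`, `R2`, `R3`.
#' @export
growthVector <- function(strains, a, b, model = c("single", "combined",
                                                  "separate"),
                         pd = Pharmacodynamics()) {
  model <- match.arg(model)
  g <- switch(model,
    single = {
      if (a > 0 && b > 0)
        stop("the single-drug model admits only one nonzero dose at a time")
      if (a > 0) growthSingle(a, strains@micA, pd)
      else if (b > 0) growthSingle(b, strains@micB, pd)
      else rep(pd@phiMax, 4L)
    },
    combined = growthCombined(a, b, strains@micA, strains@micB, pd),
    separate = growthSeparate(a, b, strains@micA, strains@micB, pd))
  names(g) <- strains@strain
  g
}
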