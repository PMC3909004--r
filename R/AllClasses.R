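#' @import methods
NULL

#' Pharmacodynamic response parameters
#'
#' Parameters of the Hill-type pharmacodynamic function that maps drug
#' concentration to bacterial net growth rate: `phiMax` is the drug-free
#' maximal growth rate, `phiMin` the (negative) minimal growth rate at very
#' high dose, and `hillK` the Hill exponent governing the steepness of the
#' dose response.  All model scenarios shipped with the package use
#' `hillK = 1`.
#'
#' @slot phiMax numeric(1), drug-free maximal net growth rate (per unit time),
#'   strictly positive.
#' @slot phiMin numeric(1), high-dose minimal net growth rate (per unit time),
#'   strictly negative.
#' @slot hillK numeric(1), dimensionless Hill exponent, strictly positive.
#' @export
setClass("Pharmacodynamics",
  representation(phiMax = "numeric", phiMin = "numeric", hillK = "numeric"))

setValidity("Pharmacodynamics", function(object) {
  msg <- character()
  if (length(object@phiMax) != 1L || !is.finite(object@phiMax) ||
      object@phiMax <= 0)
    msg <- c(msg, "'phiMax' must be a single positive number")
  if (length(object@phiMin) != 1L || !is.finite(object@phiMin) ||
      object@phiMin >= 0)
    msg <- c(msg, "'phiMin' must be a single negative number")
  if (length(object@hillK) != 1L || !is.finite(object@hillK) ||
      object@hillK <= 0)
    msg <- c(msg, "'hillK' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param phiMax,phiMin,hillK see the slot descriptions.
#' @return `Pharmacodynamics()` returns a validated object with the standard
#'   parameter values as defaults.
#' @rdname Pharmacodynamics-class
#' @examples
#' pd <- Pharmacodynamics()
#' growthSingle(0, mic = 240, pd) # drug-free growth equals phiMax
#' @export
Pharmacodynamics <- function(phiMax = 0.25, phiMin = -0.25, hillK = 1) {
  new("Pharmacodynamics", phiMax = phiMax, phiMin = phiMin, hillK = hillK)
}

#' Epidemiological parameters of the hospital transmission model
#'
#' @slot beta numeric(1), infection rate of uninfected patients per unit time.
#' @slot sigma numeric(1), dimensionless superinfection factor scaling the
#'   rate at which sensitive bacteria take over resistant-infected patients.
#' @slot gamma numeric(1), drug-independent immune clearance rate per unit
#'   time.
#' @slot cost numeric(1), dimensionless fitness cost of carrying resistance,
#'   in `[0, 1)`; it discounts the transmission of resistant strains and sets
#'   the superinfection takeover rate `sigma * cost * beta`.
#' @export
setClass("EpiParams",
  representation(beta = "numeric", sigma = "numeric", gamma = "numeric",
                 cost = "numeric"))

setValidity("EpiParams", function(object) {
  msg <- character()
  for (nm in c("beta", "sigma", "gamma", "cost")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single nonnegative number", nm))
  }
  if (length(object@cost) == 1L && is.finite(object@cost) &&
      object@cost >= 1)
    msg <- c(msg, "'cost' must be < 1")
  if (length(msg)) msg else TRUE
})

#' @param beta,sigma,gamma,cost see the slot descriptions.
#' @return `EpiParams()` returns a validated object with the standard
#'   parameter values as defaults.
#' @rdname EpiParams-class
#' @export
EpiParams <- function(beta = 1, sigma = 0.25, gamma = 0.25, cost = 0.1) {
  new("EpiParams", beta = beta, sigma = sigma, gamma = gamma, cost = cost)
}

#' Panel of bacterial strains and their MICs against the two drugs
#'
#' Holds the four strains of the model: `S` (sensitive to both drugs), `R1`
#' (resistant to drug A only), `R2` (resistant to drug B only) and `R3`
#' (double-resistant, with both MICs shrunk by the tradeoff parameter
#' `omega`).  MICs of zero are reset to the floor `micFloor` at construction
#' time so that dose/MIC ratios are always defined.
#'
#' @slot strain character(4), strain labels `S`, `R1`, `R2`, `R3`.
#' @slot micA,micB numeric(4), minimal inhibitory concentrations against
#'   drugs A and B (concentration units), each at least `micFloor`.
#' @slot paysCost logical(4), whether the strain pays the resistance cost.
#' @slot omega numeric(1), tradeoff strength used to derive the `R3` MICs.
#' @slot micFloor numeric(1), smallest admissible MIC.
#' @export
setClass("StrainSet",
  representation(strain = "character", micA = "numeric", micB = "numeric",
                 paysCost = "logical", omega = "numeric",
                 micFloor = "numeric"))

setValidity("StrainSet", function(object) {
  msg <- character()
  if (!identical(object@strain, c("S", "R1", "R2", "R3")))
    msg <- c(msg, "strains must be labelled S, R1, R2, R3 in this order")
  if (length(object@micA) != 4L || length(object@micB) != 4L)
    msg <- c(msg, "'micA' and 'micB' must have length 4")
  if (any(object@micA < object@micFloor) || any(object@micB < object@micFloor))
    msg <- c(msg, "all MICs must be at least 'micFloor'")
  if (!identical(object@paysCost, c(FALSE, TRUE, TRUE, TRUE)))
    msg <- c(msg, "'paysCost' must be FALSE for S and TRUE for R1, R2, R3")
  if (length(msg)) msg else TRUE
})

#' Strategy schedules for deploying the two drugs
#'
#' A `StrategySchedule` encodes one named deployment strategy as a
#' time-dependent assignment of drug doses to one or two patient treatment
#' arms under a fixed per-patient dose budget:
#'
#' * `NONE`: no drugs.
#' * `CONTROL`: drug A at the full budget, with the resistant compartments
#'   pinned to zero (resistance "cannot evolve").
#' * `SINGLE`: drug A at the full budget for every patient.
#' * `CYCLING`: the whole population receives drug A for a period of length
#'   `period`, then drug B, alternating.
#' * `MIXING`: two equal halves of the population receive drugs A and B in
#'   antiphase, the assignment swapping every `period`.
#' * `COCKTAIL_CMB`, `COCKTAIL_SEP`: both drugs at half budget each for all
#'   patients, under the combined (suppressive) or separate (additive)
#'   pharmacodynamics.
#'
#' @slot name character(1), one of the strategy names above.
#' @slot period numeric(1), alternation period in model time units
#'   (`CYCLING`/`MIXING` only; `NA` otherwise).
#' @slot doseBudget numeric(1), total drug concentration administered per
#'   patient at all times (except `NONE`).
#' @slot nArms integer(1), number of treatment arms (2 for `MIXING`).
#' @slot armWeights numeric, population weight of each arm, summing to one.
#' @export
setClass("StrategySchedule",
  representation(name = "character", period = "numeric",
                 doseBudget = "numeric", nArms = "integer",
                 armWeights = "numeric"))

.strategyNames <- c("NONE", "CONTROL", "SINGLE", "CYCLING", "MIXING",
                    "COCKTAIL_CMB", "COCKTAIL_SEP")

setValidity("StrategySchedule", function(object) {
  msg <- character()
  if (!(object@name %in% .strategyNames))
    msg <- c(msg, paste0("unknown strategy '", object@name, "'"))
  if (object@name %in% c("CYCLING", "MIXING") &&
      (!is.finite(object@period) || object@period <= 0))
    msg <- c(msg, "'period' must be positive for CYCLING and MIXING")
  if (!is.finite(object@doseBudget) || object@doseBudget < 0)
    msg <- c(msg, "'doseBudget' must be nonnegative")
  if (abs(sum(object@armWeights) - 1) > 1e-12)
    msg <- c(msg, "'armWeights' must sum to 1")
  if (length(object@armWeights) != object@nArms)
    msg <- c(msg, "'armWeights' length must equal 'nArms'")
  if (length(msg)) msg else TRUE
})

#' Integration and equilibrium-detection settings
#'
#' @slot dt numeric(1), fixed Runge-Kutta step in model time units.  For
#'   periodic strategies the period must be an integer multiple of `dt` so
#'   that no step straddles a dose switch.
#' @slot convergenceTol numeric(1), sup-norm threshold at which a static
#'   regimen's one-step state change is declared converged.
#' @slot envelopeTol numeric(1), sup-norm threshold on the change of the
#'   per-cycle upper/lower envelopes of periodic regimens.  It is looser
#'   than `convergenceTol` because the cycling attractor carries a
#'   near-neutral mode (the phase asymmetry between the two single-resistant
#'   strains) whose final decimals relax only on very long timescales,
#'   while the cycle-averaged frequencies are already stable far below this
#'   tolerance.
#' @slot maxTime numeric(1), hard stop in model time units; runs that reach
#'   it are flagged as non-converged, never dropped silently.
#' @slot cycleAveragePeriods integer(1), number of half-cycle periods over
#'   which fluctuating equilibria are time-averaged after convergence.
#' @slot postConvergenceSteps integer(1), extra steps integrated after static
#'   convergence before the state is read off.
#' @export
setClass("IntegrationSettings",
  representation(dt = "numeric", convergenceTol = "numeric",
                 envelopeTol = "numeric", maxTime = "numeric",
                 cycleAveragePeriods = "integer",
                 postConvergenceSteps = "integer"))

setValidity("IntegrationSettings", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "'dt' must be positive")
  if (object@convergenceTol <= 0)
    msg <- c(msg, "'convergenceTol' must be positive")
  if (object@envelopeTol <= 0)
    msg <- c(msg, "'envelopeTol' must be positive")
  if (object@maxTime <= 0) msg <- c(msg, "'maxTime' must be positive")
  if (object@cycleAveragePeriods < 1L)
    msg <- c(msg, "'cycleAveragePeriods' must be at least 1")
  if (object@cycleAveragePeriods %% 2L != 0L)
    msg <- c(msg, "'cycleAveragePeriods' must be even (whole drug cycles)")
  if (object@postConvergenceSteps < 0L)
    msg <- c(msg, "'postConvergenceSteps' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @param dt,convergenceTol,envelopeTol,maxTime,cycleAveragePeriods,postConvergenceSteps
#'   see the slot descriptions.
#' @return `IntegrationSettings()` returns a validated settings object.
#' @rdname IntegrationSettings-class
#' @export
IntegrationSettings <- function(dt = 0.1, convergenceTol = 1e-12,
                                envelopeTol = 1e-9, maxTime = 2e5,
                                cycleAveragePeriods = 1000L,
                                postConvergenceSteps = 0L) {
  new("IntegrationSettings", dt = dt, convergenceTol = convergenceTol,
      envelopeTol = envelopeTol, maxTime = maxTime,
      cycleAveragePeriods = as.integer(cycleAveragePeriods),
      postConvergenceSteps = as.integer(postConvergenceSteps))
}

#' Equilibrium (or cycle-averaged) outcome of one scenario
#'
#' @slot strategy character(1), strategy name.
#' @slot omega numeric(1), tradeoff strength of the scenario.
#' @slot period numeric(1), alternation period (`NA` for static strategies).
#' @slot xHat numeric(1), equilibrium (cycle-averaged, when fluctuating)
#'   frequency of uninfected patients.
#' @slot strainFreqs numeric(4), equilibrium frequencies of `S`, `R1`, `R2`,
#'   `R3`.
#' @slot dominant character, most common strain(s); ties are reported as a
#'   vector (e.g. `c("R1", "R2")` in symmetric scenarios).
#' @slot recoveryPerCapita numeric(1), per-capita recovery rate of infected
#'   patients at equilibrium.
#' @slot converged logical(1), whether the convergence criterion was met
#'   before `maxTime`.
#' @slot timeToConvergence numeric(1), model time at which convergence was
#'   declared.
#' @slot drift numeric(1), largest deviation of the total frequency from one
#'   observed along the run.
#' @export
setClass("EquilibriumResult",
  representation(strategy = "character", omega = "numeric",
                 period = "numeric", xHat = "numeric",
                 strainFreqs = "numeric", dominant = "character",
                 recoveryPerCapita = "numeric", converged = "logical",
                 timeToConvergence = "numeric", drift = "numeric"))

#' Dominant-strain switching threshold of a strategy
#'
#' @slot strategy character(1), strategy name.
#' @slot period numeric(1), alternation period used (if any).
#' @slot omegaStar numeric(1), tradeoff value at which the equilibrium
#'   dominant strain switches (`NA` when no switch occurs in `[0, 1]`).
#' @slot fromStrain,toStrain character, dominant strain set below and above
#'   the threshold.
#' @slot bracket numeric(2), final bisection bracket.
#' @export
setClass("ThresholdResult",
  representation(strategy = "character", period = "numeric",
                 omegaStar = "numeric", fromStrain = "character",
                 toStrain = "character", bracket = "numeric"))
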