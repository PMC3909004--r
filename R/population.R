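#' Construct and validate a population state
#'
#' The model tracks frequencies of five patient compartments in a closed
#' hospital: `x` (uninfected), `s` (infected with sensitive bacteria), `r1`,
#' `r2` (infected with single-resistant bacteria) and `r3` (infected with
#' double-resistant bacteria).  Frequencies must be in `[0, 1]` and sum to
#' one.
#'
#' @param x,s,r1,r2,r3 compartment frequencies.
#' @param tol tolerance on the closure constraint `x+s+r1+r2+r3 = 1`.
#' @return named numeric(5) in the canonical order.
#' @export
populationState <- function(x, s = 0, r1 = 0, r2 = 0, r3 = 0, tol = 1e-9) {
  y <- c(x = x, s = s, r1 = r1, r2 = r2, r3 = r3)
  if (any(!is.finite(y)))
    stop("population state must be finite")
  if (any(y < -tol) || any(y > 1 + tol))
    stop("compartment frequencies must lie in [0, 1]")
  if (abs(sum(y) - 1) > tol)
    stop("compartment frequencies must sum to 1 (closed system)")
  y
}

.stateNames <- c("x", "s", "r1", "r2", "r3")
.strainNames <- c("S", "R1", "R2", "R3")

# Per-strain transmission coefficients beta*(1-c) and superinfection
# takeover coefficients sigma*c*beta; takeover succeeds in proportion to the
# resident strain's competitive deficit, and only resistant residents are
# taken over.
.infRates <- function(epi, strains) {
  epi@beta * (1 - epi@cost * strains@paysCost)
}

.supRates <- function(epi, strains) {
  epi@sigma * epi@cost * epi@beta * as.numeric(strains@paysCost)
}

#' Time derivative of the five-compartment hospital model
#'
#' Right-hand side of the closed-system transmission dynamics.  Uninfected
#' patients are infected by strain `i` at rate `beta*(1-c_i)*x*strain_i`
#' (the resistance cost `c` discounts transmission); sensitive bacteria take
#' over resistant-infected patients at rate `sigma*c*beta*s*strain_i`;
#' infected patients are cleared back to the uninfected pool at rate
#' `-(G_i - gamma)*strain_i`, where `G_i` is the pharmacodynamic growth rate
#' under the doses in force.  Every gain in one compartment appears as a
#' loss in another, so the components of the derivative sum to zero exactly.
#'
#' @param state named numeric(5) as from [populationState()].
#' @param growth named numeric(4) of strain growth rates, as from
#'   [growthVector()].
#' @param epi an [EpiParams] object.
#' @param pinResistant logical; when `TRUE` the derivatives of `r1`, `r2`,
#'   `r3` are forced to zero (the `CONTROL` scenario, in which resistance
#'   cannot evolve).
#' @return named numeric(5), the time derivative of `state`.
#' @export
populationDeriv <- function(state, growth, epi = EpiParams(),
                            pinResistant = FALSE) {
  if (any(!is.finite(state)) || any(!is.finite(growth)))
    stop("non-finite values in state or growth vector")
  x <- state[[1L]]
  comp <- state[2:5]
  infRate <- epi@beta * c(1, rep(1 - epi@cost, 3L))
  supRate <- epi@sigma * epi@cost * epi@beta
  inf <- infRate * x * comp
  sup <- supRate * comp[[1L]] * comp[2:4]
  clr <- (growth - epi@gamma) * comp
  d <- c(-sum(inf) - sum(clr),
         inf[[1L]] + sum(sup) + clr[[1L]],
         inf[2:4] - sup + clr[2:4])
  if (pinResistant) d[3:5] <- 0
  names(d) <- .stateNames
  d
}

#' Per-capita recovery rate of infected patients
#'
#' The population recovery flux is
#' `z = -sum_i (G_i - gamma) * strain_i`, the rate at which cured patients
#' re-enter the uninfected pool; the per-capita rate is `z` divided by the
#' total infected frequency.  It is nonnegative whenever `G_i <= gamma` for
#' all strains, which holds throughout the standard parameter range.
#'
#' @inheritParams populationDeriv
#' @return numeric(1), per-capita recovery rate per unit time.
#' @export
perCapitaRecovery <- function(state, growth, epi = EpiParams()) {
  infected <- sum(state[2:5])
  if (infected <= 0)
    stop("per-capita recovery is undefined for a fully uninfected population")
  z <- -sum((growth - epi@gamma) * state[2:5])
  z / infected
}

#' @rdname dominantStrain
#' @export
setGeneric("dominantStrain",
           function(object, tol = 1e-9) standardGeneric("dominantStrain"))

#' Most common bacterial strain in the infected population
#'
#' Returns the strain label(s) attaining the maximum frequency among the
#' infected compartments.  Strains within `tol` of the maximum are reported
#' together, so exactly symmetric scenarios yield the tie `c("R1", "R2")`.
#'
#' @param object a population state (named numeric(5)) or an
#'   [EquilibriumResult].
#' @param tol absolute tolerance for declaring a tie.
#' @return character vector of dominant strain label(s).
#' @rdname dominantStrain
#' @export
setMethod("dominantStrain", "numeric", function(object, tol = 1e-9) {
  freqs <- object[2:5]
  .strainNames[freqs >= max(freqs) - tol]
})

#' @rdname dominantStrain
#' @export
setMethod("dominantStrain", "EquilibriumResult", function(object, tol = 1e-9) {
  object@dominant
})
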