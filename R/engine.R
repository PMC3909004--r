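#' @useDynLib abxtradeoff, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.defaultInit <- function(schedule) {
  if (schedule@name == "CONTROL")
    populationState(x = 0.99, s = 0.01)
  else
    populationState(x = 0.96, s = 0.01, r1 = 0.01, r2 = 0.01, r3 = 0.01)
}

.isPeriodic <- function(schedule) schedule@name %in% c("CYCLING", "MIXING")

.stepsPerPeriod <- function(schedule, settings) {
  n <- schedule@period / settings@dt
  if (abs(n - round(n)) > 1e-8)
    stop("the period must be an integer multiple of 'dt' so that no ",
         "integration step straddles a dose switch")
  as.integer(round(n))
}

# Growth vectors seen by the population in the two half-cycles of a periodic
# strategy (identical for static ones).  For CYCLING these alternate; for
# MIXING the arm-averaged growth is the same in both half-cycles.
.phaseGrowth <- function(schedule, strains, pd) {
  if (.isPeriodic(schedule)) {
    list(.effectiveGrowth(schedule, strains, 0, pd),
         .effectiveGrowth(schedule, strains, schedule@period, pd))
  } else {
    g <- .effectiveGrowth(schedule, strains, 0, pd)
    list(g, g)
  }
}

#' Integrate a scenario and record the trajectory
#'
#' Fixed-step classical Runge-Kutta (RK4) integration of the
#' five-compartment model under a deployment strategy, recording the state
#' at every step.  Doses are piecewise constant and period boundaries are
#' aligned with the step grid, so no step straddles a dose switch.
#'
#' @param schedule a [StrategySchedule].
#' @param strains a [StrainSet], e.g. from [strainPanel()].
#' @param epi an [EpiParams] object.
#' @param pd a [Pharmacodynamics] object.
#' @param init initial state (named numeric(5)); defaults to a mostly
#'   uninfected population with each strain seeded at 1%, or `x = 0.99`,
#'   `s = 0.01` for `CONTROL`.
#' @param tMax integration horizon in model time units.
#' @param settings an [IntegrationSettings] object (only `dt` is used here).
#' @return a `data.frame` with columns `time`, the five compartment
#'   frequencies, and the per-arm doses in force.
#' @examples
#' tr <- integrateTrajectory(strategySchedule("CONTROL"), strainPanel(0.5),
#'                           tMax = 20)
#' tail(tr, 3)
#' @export
integrateTrajectory <- function(schedule, strains, epi = EpiParams(),
                                pd = Pharmacodynamics(), init = NULL,
                                tMax = 100, settings = IntegrationSettings()) {
  if (is.null(init)) init <- .defaultInit(schedule)
  init <- populationState(init[[1]], init[[2]], init[[3]], init[[4]],
                          init[[5]])
  dt <- settings@dt
  infRate <- .infRates(epi, strains)
  supRate <- .supRates(epi, strains)
  pin <- schedule@name == "CONTROL"
  segLen <- if (.isPeriodic(schedule)) .stepsPerPeriod(schedule, settings)
            else as.integer(ceiling(tMax / dt))
  nTotal <- as.integer(ceiling(tMax / dt))
  phases <- .phaseGrowth(schedule, strains, pd)

  rows <- vector("list", ceiling(nTotal / segLen) + 1L)
  y <- unname(init)
  done <- 0L
  seg <- 0L
  while (done < nTotal) {
    n <- min(segLen, nTotal - done)
    g <- phases[[seg %% 2L + 1L]]
    m <- .engineRecord(y, g, infRate, supRate, epi@gamma, dt, n, pin)
    y <- m[nrow(m), ]
    keep <- if (done == 0L) m else m[-1L, , drop = FALSE]
    rows[[seg + 1L]] <- keep
    done <- done + n
    seg <- seg + 1L
  }
  states <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  colnames(states) <- .stateNames
  time <- seq(0, by = dt, length.out = nrow(states))
  doses <- t(vapply(time, function(tt) as.numeric(t(dosesAt(schedule, tt))),
                    numeric(2L * schedule@nArms)))
  colnames(doses) <- paste0(rep(c("doseA", "doseB"), schedule@nArms),
                            rep(seq_len(schedule@nArms), each = 2L))
  data.frame(time = time, states, doses, check.names = FALSE)
}

#' Run a scenario to equilibrium
#'
#' Static regimens (`NONE`, `CONTROL`, `SINGLE`, both cocktails) are
#' integrated until the one-step sup-norm change of the state falls below
#' `convergenceTol`.  Periodic regimens (`CYCLING`, `MIXING`) are integrated
#' until the per-cycle upper and lower envelopes of every compartment change
#' by less than `envelopeTol` between consecutive cycles, after which the
#' state is time-averaged over `cycleAveragePeriods` further periods.  Runs
#' that hit `maxTime` first are returned with `converged = FALSE`, never
#' dropped.
#'
#' @inheritParams integrateTrajectory
#' @return an [EquilibriumResult].
#' @examples
#' res <- runToEquilibrium(strategySchedule("CONTROL"), strainPanel(0.5))
#' xHat(res) # 0.5: the closed form (gamma - phiMin) / beta
#' @export
runToEquilibrium <- function(schedule, strains, epi = EpiParams(),
                             pd = Pharmacodynamics(), init = NULL,
                             settings = IntegrationSettings()) {
  if (is.null(init)) init <- .defaultInit(schedule)
  init <- populationState(init[[1]], init[[2]], init[[3]], init[[4]],
                          init[[5]])
  dt <- settings@dt
  infRate <- .infRates(epi, strains)
  supRate <- .supRates(epi, strains)
  phases <- .phaseGrowth(schedule, strains, pd)

  if (.isPeriodic(schedule)) {
    spp <- .stepsPerPeriod(schedule, settings)
    maxCycles <- max(1, floor(settings@maxTime / (2 * schedule@period)))
    out <- .enginePeriodic(unname(init), phases[[1L]], phases[[2L]],
                           infRate, supRate, epi@gamma, dt, spp, maxCycles,
                           settings@envelopeTol,
                           settings@cycleAveragePeriods)
    state <- out$avgState
    recovery <- out$zBar / sum(state[2:5])
    tConv <- out$cycles * 2 * schedule@period
  } else {
    pin <- schedule@name == "CONTROL"
    maxSteps <- ceiling(settings@maxTime / dt)
    out <- .engineStatic(unname(init), phases[[1L]], infRate, supRate,
                         epi@gamma, dt, settings@convergenceTol, maxSteps,
                         pin)
    state <- out$state
    if (settings@postConvergenceSteps > 0L) {
      m <- .engineRecord(state, phases[[1L]], infRate, supRate, epi@gamma,
                         dt, settings@postConvergenceSteps, pin)
      state <- m[nrow(m), ]
    }
    infected <- sum(state[2:5])
    recovery <- if (infected > 0)
      -sum((phases[[1L]] - epi@gamma) * state[2:5]) / infected
    else NA_real_
    tConv <- out$steps * dt
  }
  names(state) <- .stateNames
  freqs <- state[2:5]
  names(freqs) <- .strainNames
  new("EquilibriumResult",
      strategy = schedule@name, omega = strains@omega,
      period = schedule@period, xHat = unname(state[[1L]]),
      strainFreqs = freqs, dominant = dominantStrain(state),
      recoveryPerCapita = recovery, converged = out$converged,
      timeToConvergence = tConv, drift = out$drift)
}
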