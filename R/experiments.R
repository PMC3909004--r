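#' Sweep equilibria over tradeoff strengths and strategies
#'
#' Runs [runToEquilibrium()] on every combination of strategy, tradeoff
#' strength `omega` and (for periodic strategies) period, and returns one
#' tidy row per scenario with the full parameter set echoed for provenance.
#' The sweep is deterministic: identical inputs produce identical tables.
#' Non-converged cells are flagged in the `converged` column, never dropped.
#'
#' @param strategies character vector of strategy names.
#' @param omega numeric vector of tradeoff strengths in `[0, 1]`.
#' @param period numeric vector of alternation periods applied to `CYCLING`
#'   and `MIXING` (static strategies are run once per `omega`).
#' @param epi,pd,settings model parameters and integration settings.
#' @param doseBudget total dose per patient.
#' @return a `data.frame` keyed by (`strategy`, `omega`, `period`).
#' @examples
#' sweepEquilibria("COCKTAIL_SEP", omega = c(0, 1))$xHat
#' @export
sweepEquilibria <- function(strategies = c("NONE", "CONTROL", "SINGLE",
                                           "CYCLING", "MIXING",
                                           "COCKTAIL_CMB", "COCKTAIL_SEP"),
                            omega = seq(0, 1, by = 0.01),
                            period = 50,
                            epi = EpiParams(), pd = Pharmacodynamics(),
                            settings = IntegrationSettings(),
                            doseBudget = 240) {
  grid <- do.call(rbind, lapply(strategies, function(st) {
    p <- if (st %in% c("CYCLING", "MIXING")) period else NA_real_
    expand.grid(strategy = st, omega = omega, period = p,
                stringsAsFactors = FALSE)
  }))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- grid$strategy[i]
    sched <- strategySchedule(st, period = if (is.na(grid$period[i])) 50
                                           else grid$period[i],
                              doseBudget = doseBudget)
    res <- runToEquilibrium(sched, strainPanel(grid$omega[i]), epi, pd,
                            settings = settings)
    as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  out$beta <- epi@beta; out$sigma <- epi@sigma
  out$gamma <- epi@gamma; out$cost <- epi@cost
  out$phiMax <- pd@phiMax; out$phiMin <- pd@phiMin; out$hillK <- pd@hillK
  out$doseBudget <- doseBudget
  out$dt <- settings@dt; out$convergenceTol <- settings@convergenceTol
  rownames(out) <- NULL
  out
}

#' Locate the tradeoff threshold at which the dominant strain switches
#'
#' Bisects the tradeoff strength `omega` on the identity of the equilibrium
#' dominant strain.  The interval `[0, 1]` is narrowed until the bracket is
#' at most `tolerance` wide; the threshold is reported as the bracket
#' midpoint together with the dominant strain sets on either side.  If the
#' dominant strain is the same at both endpoints an explicit no-threshold
#' result is returned (`omegaStar = NA`).
#'
#' @param strategy strategy name.
#' @param period alternation period for `CYCLING`/`MIXING`.
#' @param tolerance final bracket width on `omega`.
#' @param epi,pd,settings model parameters and integration settings.
#' @return a [ThresholdResult].
#' @examples
#' \donttest{
#' findDominanceThreshold("COCKTAIL_CMB") # R3 gives way to S near 0.86
#' }
#' @export
findDominanceThreshold <- function(strategy, period = 50, tolerance = 0.005,
                                   epi = EpiParams(),
                                   pd = Pharmacodynamics(),
                                   settings = IntegrationSettings()) {
  sched <- strategySchedule(strategy, period = period)
  domAt <- function(om)
    runToEquilibrium(sched, strainPanel(om), epi, pd,
                     settings = settings)@dominant
  lo <- 0; hi <- 1
  domLo <- domAt(lo)
  domHi <- domAt(hi)
  if (setequal(domLo, domHi))
    return(new("ThresholdResult", strategy = sched@name,
               period = sched@period, omegaStar = NA_real_,
               fromStrain = domLo, toStrain = domHi, bracket = c(lo, hi)))
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (setequal(domAt(mid), domLo)) lo <- mid else hi <- mid
  }
  new("ThresholdResult", strategy = sched@name, period = sched@period,
      omegaStar = (lo + hi) / 2, fromStrain = domLo, toStrain = domHi,
      bracket = c(lo, hi))
}

#' Closed-form equilibrium frequency of uninfected patients
#'
#' For static regimens, when a single infected strain persists at
#' equilibrium the uninfected frequency satisfies
#' \deqn{\hat X = \frac{\gamma - G_i}{\beta\,(1 - c\,[\textrm{pays cost}])},}
#' where `G_i` is the strain's pharmacodynamic growth under the strategy's
#' (constant) doses.  By default the formula is evaluated at the strain that
#' would win the competition (the smallest `xHat` across strains, i.e. the
#' strain able to persist at the lowest uninfected frequency); pass
#' `dominant` to evaluate it at the strain identified by a numerical run.
#' No closed form exists for the fluctuating `CYCLING` and `MIXING`
#' regimens, for which `NA` is returned.
#'
#' @param strategy strategy name.
#' @param omega tradeoff strength.
#' @param epi,pd model parameters.
#' @param dominant optional strain label at which to evaluate the formula.
#' @param doseBudget total dose per patient.
#' @return named numeric(1): the equilibrium uninfected frequency, named by
#'   the strain used; `NA` for `CYCLING`/`MIXING`.
#' @examples
#' analyticEquilibrium("SINGLE", omega = 0.5)       # 0.2778, R1 dominant
#' analyticEquilibrium("COCKTAIL_SEP", omega = 1)   # 0.7407
#' @export
analyticEquilibrium <- function(strategy, omega, epi = EpiParams(),
                                pd = Pharmacodynamics(), dominant = NULL,
                                doseBudget = 240) {
  sched <- strategySchedule(strategy, doseBudget = doseBudget)
  if (.isPeriodic(sched))
    return(stats::setNames(NA_real_, "not-available"))
  strains <- strainPanel(omega)
  g <- .effectiveGrowth(sched, strains, 0, pd)
  denom <- epi@beta * (1 - epi@cost * strains@paysCost)
  xhat <- (epi@gamma - g) / denom
  names(xhat) <- strains@strain
  if (sched@name == "CONTROL") return(pmin(pmax(xhat["S"], 0), 1))
  if (!is.null(dominant)) {
    dominant <- match.arg(dominant, .strainNames)
    return(pmin(pmax(xhat[dominant], 0), 1))
  }
  pmin(pmax(xhat[which.min(xhat)], 0), 1)
}

#' Pair equilibrium uninfected frequency with per-capita recovery
#'
#' Extracts `(xHat, recoveryPerCapita)` pairs per strategy from a sweep
#' table (see [sweepEquilibria()]) and reports the sign of their rank
#' association (Spearman) within each strategy.  Strategies represented by
#' fewer than two distinct points have an undefined association, reported
#' as `NA`.
#'
#' @param sweep a `data.frame` from [sweepEquilibria()].
#' @return a list with `pairs` (one row per scenario) and `association`
#'   (one row per strategy with the Spearman rank correlation and its sign).
#' @export
recoveryVsXhat <- function(sweep) {
  pairs <- sweep[, c("strategy", "omega", "period", "xHat",
                     "recoveryPerCapita")]
  association <- do.call(rbind, lapply(split(pairs, pairs$strategy),
    function(d) {
      ok <- is.finite(d$xHat) & is.finite(d$recoveryPerCapita)
      d <- d[ok, ]
      rho <- if (nrow(d) >= 2L && stats::sd(d$xHat) > 0 &&
                 stats::sd(d$recoveryPerCapita) > 0)
        stats::cor(d$xHat, d$recoveryPerCapita, method = "spearman")
      else NA_real_
      data.frame(strategy = d$strategy[1L], n = nrow(d), spearmanRho = rho,
                 positiveAssociation = if (is.na(rho)) NA else rho > 0)
    }))
  rownames(association) <- NULL
  list(pairs = pairs, association = association)
}
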