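#' Construct a deployment strategy schedule
#'
#' @param name one of `NONE`, `CONTROL`, `SINGLE`, `CYCLING`, `MIXING`,
#'   `COCKTAIL_CMB`, `COCKTAIL_SEP` (see [StrategySchedule]).
#' @param period alternation period in model time units, used by `CYCLING`
#'   and `MIXING`.
#' @param doseBudget total drug concentration per patient; every drug-using
#'   strategy administers exactly this amount at all times.
#' @return a validated [StrategySchedule].
#' @examples
#' strategySchedule("CYCLING", period = 50)
#' @export
strategySchedule <- function(name, period = 50, doseBudget = 240) {
  name <- toupper(name)
  if (!name %in% .strategyNames)
    stop("unknown strategy '", name, "'; valid names are: ",
         paste(.strategyNames, collapse = ", "))
  periodic <- name %in% c("CYCLING", "MIXING")
  nArms <- if (name == "MIXING") 2L else 1L
  new("StrategySchedule", name = name,
      period = if (periodic) period else NA_real_,
      doseBudget = doseBudget, nArms = nArms,
      armWeights = rep(1 / nArms, nArms))
}

#' @rdname dosesAt
#' @export
setGeneric("dosesAt", function(schedule, t) standardGeneric("dosesAt"))

#' Doses administered by a strategy at a given time
#'
#' Returns the per-arm concentrations of drugs A and B in force at model
#' time `t`.  `CYCLING` administers drug A on even periods and drug B on odd
#' ones (parity of `floor(t / period)`); `MIXING`'s second arm is in exact
#' antiphase with its first; the cocktails split the budget equally between
#' the drugs; `SINGLE` and `CONTROL` administer drug A at the full budget;
#' `NONE` administers nothing.  Doses are piecewise constant and
#' right-continuous at period boundaries.
#'
#' @param schedule a [StrategySchedule].
#' @param t model time, nonnegative.
#' @return numeric matrix with one row per arm and columns `a`, `b`; the
#'   rows of every drug-using strategy sum to the dose budget.
#' @examples
#' dosesAt(strategySchedule("MIXING", period = 50), 0)
#' @rdname dosesAt
#' @export
setMethod("dosesAt", "StrategySchedule", function(schedule, t) {
  if (!is.finite(t) || t < 0) stop("'t' must be a nonnegative time")
  full <- schedule@doseBudget
  half <- full / 2
  doses <- switch(schedule@name,
    NONE = c(0, 0),
    CONTROL = ,
    SINGLE = c(full, 0),
    COCKTAIL_CMB = ,
    COCKTAIL_SEP = c(half, half),
    CYCLING = if (floor(t / schedule@period) %% 2 == 0) c(full, 0)
              else c(0, full),
    MIXING = {
      onA <- floor(t / schedule@period) %% 2 == 0
      rbind(if (onA) c(full, 0) else c(0, full),
            if (onA) c(0, full) else c(full, 0))
    })
  matrix(doses, ncol = 2,
         dimnames = list(paste0("arm", seq_len(schedule@nArms)),
                         c("a", "b")))
})

# Pharmacodynamic composition used by a strategy.
.pdModel <- function(schedule) {
  switch(schedule@name,
         COCKTAIL_CMB = "combined",
         COCKTAIL_SEP = "separate",
         "single")
}

#' @rdname growthForStrategy
#' @export
setGeneric("growthForStrategy",
  function(schedule, strains, t, pd = Pharmacodynamics())
    standardGeneric("growthForStrategy"))

#' Per-arm strain growth rates under a strategy at a given time
#'
#' Evaluates the pharmacodynamic growth of every strain in each treatment
#' arm at the doses returned by [dosesAt()].  The cocktails use the combined
#' or separate two-drug composition; all one-drug-at-a-time strategies use
#' the single-drug response against the MIC of whichever drug is in force.
#'
#' @param schedule a [StrategySchedule].
#' @param strains a [StrainSet].
#' @param t model time.
#' @param pd a [Pharmacodynamics] object.
#' @return numeric matrix, strains (rows `S`, `R1`, `R2`, `R3`) by arms.
#' @rdname growthForStrategy
#' @export
setMethod("growthForStrategy", "StrategySchedule",
  function(schedule, strains, t, pd = Pharmacodynamics()) {
    doses <- dosesAt(schedule, t)
    model <- .pdModel(schedule)
    g <- vapply(seq_len(nrow(doses)), function(j)
      growthVector(strains, doses[j, "a"], doses[j, "b"], model, pd),
      numeric(4L))
    dimnames(g) <- list(.strainNames, rownames(doses))
    g
  })

# Population-level growth vector experienced by each strain: the
# arm-weight-averaged growth.  Under MIXING each infected compartment is
# exposed to both assignments in proportion to the arm weights (randomised
# assignment at the population scale), which makes the effective growth
# invariant under arm swaps.
.effectiveGrowth <- function(schedule, strains, t, pd) {
  g <- growthForStrategy(schedule, strains, t, pd)
  as.numeric(g %*% schedule@armWeights)
}
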