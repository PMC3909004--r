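# Shared fixtures: standard parameters and a few canonical scenarios.
stdPd <- Pharmacodynamics()
stdEpi <- EpiParams()

# Percentage helper for equilibrium frequencies.
pct <- function(res) 100 * xHat(res)

# Equilibrium of a strategy at a tradeoff strength, standard parameters.
equilibriumAt <- function(strategy, omega, period = 50,
                          settings = IntegrationSettings()) {
  runToEquilibrium(strategySchedule(strategy, period = period),
                   strainPanel(omega), stdEpi, stdPd, settings = settings)
}
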