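#' @rdname EquilibriumResult-class
#' @param object an [EquilibriumResult] or [ThresholdResult].
#' @export
setGeneric("xHat", function(object) standardGeneric("xHat"))

#' @rdname EquilibriumResult-class
#' @export
setMethod("xHat", "EquilibriumResult", function(object) object@xHat)

#' @rdname EquilibriumResult-class
#' @export
setGeneric("strainFrequencies",
           function(object) standardGeneric("strainFrequencies"))

#' @rdname EquilibriumResult-class
#' @export
setMethod("strainFrequencies", "EquilibriumResult",
          function(object) object@strainFreqs)

#' @rdname EquilibriumResult-class
#' @export
setGeneric("recoveryRate", function(object) standardGeneric("recoveryRate"))

#' @rdname EquilibriumResult-class
#' @export
setMethod("recoveryRate", "EquilibriumResult",
          function(object) object@recoveryPerCapita)

#' @rdname EquilibriumResult-class
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname EquilibriumResult-class
#' @export
setMethod("converged", "EquilibriumResult", function(object) object@converged)

#' @rdname ThresholdResult-class
#' @param object a [ThresholdResult].
#' @export
setGeneric("omegaStar", function(object) standardGeneric("omegaStar"))

#' @rdname ThresholdResult-class
#' @export
setMethod("omegaStar", "ThresholdResult", function(object) object@omegaStar)

#' MIC accessors
#'
#' @param object a [StrainSet].
#' @return named numeric(4) of MICs against drug A or B.
#' @rdname StrainSet-class
#' @export
setGeneric("micA", function(object) standardGeneric("micA"))

#' @rdname StrainSet-class
#' @export
setMethod("micA", "StrainSet",
          function(object) stats::setNames(object@micA, object@strain))

#' @rdname StrainSet-class
#' @export
setGeneric("micB", function(object) standardGeneric("micB"))

#' @rdname StrainSet-class
#' @export
setMethod("micB", "StrainSet",
          function(object) stats::setNames(object@micB, object@strain))

setMethod("show", "StrainSet", function(object) {
  cat("StrainSet (omega = ", format(object@omega), ")\n", sep = "")
  print(data.frame(strain = object@strain, micA = object@micA,
                   micB = object@micB, paysCost = object@paysCost))
  invisible(object)
})

setMethod("show", "StrategySchedule", function(object) {
  cat("StrategySchedule:", object@name)
  if (!is.na(object@period)) cat(" (period =", object@period, ")")
  cat("\n  dose budget:", object@doseBudget,
      "| arms:", object@nArms, "\n")
  invisible(object)
})

setMethod("show", "EquilibriumResult", function(object) {
  cat("EquilibriumResult:", object@strategy,
      sprintf("(omega = %s%s)\n", format(object@omega),
              if (is.na(object@period)) ""
              else paste0(", period = ", format(object@period))))
  cat(sprintf("  X-hat = %.6f | dominant: %s | per-capita recovery = %s\n",
              object@xHat, paste(object@dominant, collapse = "/"),
              format(object@recoveryPerCapita, digits = 6)))
  cat("  strain frequencies:",
      paste(sprintf("%s=%.4g", names(object@strainFreqs),
                    object@strainFreqs), collapse = ", "), "\n")
  cat(sprintf("  converged: %s (t = %s) | max drift = %.2e\n",
              object@converged, format(object@timeToConvergence),
              object@drift))
  invisible(object)
})

setMethod("show", "ThresholdResult", function(object) {
  cat("ThresholdResult:", object@strategy, "\n")
  if (is.na(object@omegaStar)) {
    cat("  no dominance switch in [0, 1]; dominant:",
        paste(object@fromStrain, collapse = "/"), "\n")
  } else {
    cat(sprintf("  omega* = %.4f (bracket [%.4f, %.4f]): %s -> %s\n",
                object@omegaStar, object@bracket[1L], object@bracket[2L],
                paste(object@fromStrain, collapse = "/"),
                paste(object@toStrain, collapse = "/")))
  }
  invisible(object)
})

#' Coerce an equilibrium result to a one-row data frame
#'
#' @param x an [EquilibriumResult].
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a one-row `data.frame` with all result fields, the dominant
#'   strain set collapsed as e.g. `"R1/R2"`.
#' @export
as.data.frame.EquilibriumResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(strategy = x@strategy, omega = x@omega, period = x@period,
             xHat = x@xHat, s = x@strainFreqs[["S"]],
             r1 = x@strainFreqs[["R1"]], r2 = x@strainFreqs[["R2"]],
             r3 = x@strainFreqs[["R3"]],
             dominant = paste(x@dominant, collapse = "/"),
             recoveryPerCapita = x@recoveryPerCapita,
             converged = x@converged,
             timeToConvergence = x@timeToConvergence, drift = x@drift,
             stringsAsFactors = FALSE)
}
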