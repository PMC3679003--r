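# Accessors and show methods.

#' @rdname accessors
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("ciValues", function(x) standardGeneric("ciValues"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("getTrace", function(x, well) standardGeneric("getTrace"))
#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("vmValues", function(x) standardGeneric("vmValues"))
#' @rdname accessors
#' @export
setGeneric("pulses", function(x) standardGeneric("pulses"))

#' Accessors for assay objects
#'
#' Small read-only accessors: `wellId()`, `traceTimes()`, `ciValues()` and
#' `provenance()` for [ImpedanceTrace-class]; `annotations()`, `protocol()`,
#' `provenance()` and `getTrace()` for [PlateExperiment-class]; `cellId()`,
#' `traceTimes()`, `vmValues()` and `protocol()` for
#' [EphysRecording-class]; `pulses()` for [StimulusProtocol-class].
#'
#' @param x the object.
#' @param well well id to extract from a plate.
#' @name accessors
NULL

#' @rdname accessors
setMethod("wellId", "ImpedanceTrace", function(x) x@wellId)
#' @rdname accessors
setMethod("traceTimes", "ImpedanceTrace", function(x) x@times)
#' @rdname accessors
setMethod("ciValues", "ImpedanceTrace", function(x) x@ci)
#' @rdname accessors
setMethod("provenance", "ImpedanceTrace", function(x) x@provenance)

#' @rdname accessors
setMethod("traceTimes", "PlateExperiment",
          function(x) SummarizedExperiment::rowData(x)$time_s)
#' @rdname accessors
setMethod("provenance", "PlateExperiment",
          function(x) S4Vectors::metadata(x)$provenance)
#' @rdname accessors
setMethod("protocol", "PlateExperiment",
          function(x) S4Vectors::metadata(x)$protocol)
#' @rdname accessors
setMethod("annotations", "PlateExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(well = rownames(cd), construct = cd$construct, role = cd$role,
             row.names = NULL)
})
#' @rdname accessors
setMethod("getTrace", "PlateExperiment", function(x, well) {
  m <- SummarizedExperiment::assay(x, "ci")
  if (!well %in% colnames(m)) stop("unknown well: ", well)
  ImpedanceTrace(well, traceTimes(x), m[, well], provenance(x))
})

#' @rdname accessors
setMethod("cellId", "EphysRecording", function(x) x@cellId)
#' @rdname accessors
setMethod("traceTimes", "EphysRecording", function(x) x@times)
#' @rdname accessors
setMethod("vmValues", "EphysRecording", function(x) x@vm)
#' @rdname accessors
setMethod("protocol", "EphysRecording", function(x) x@protocol)

#' @rdname accessors
setMethod("pulses", "StimulusProtocol", function(x) x@pulses)

setMethod("show", "ImpedanceTrace", function(object) {
  cat(sprintf("ImpedanceTrace '%s': %d samples, dt = %.3g s, provenance = %s\n",
              object@wellId, length(object@times),
              diff(object@times[1:2]), object@provenance))
})

setMethod("show", "LightPulse", function(object) {
  sp <- object@spectrum
  desc <- switch(sp@kind,
    flat_band = sprintf("flat %g-%g nm", sp@lambdaMin, sp@lambdaMax),
    gaussian_band = sprintf("gaussian %g nm (sd %g)", sp@lambdaPeak,
                            sp@bandwidth),
    monochromatic = sprintf("line %g nm", sp@lambdaPeak))
  cat(sprintf("LightPulse: onset %g s, duration %g s, %s, %.3g photons/cm2/s\n",
              object@onset, object@duration, desc, object@flux))
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol with %d pulse(s)\n", length(object@pulses)))
  for (p in object@pulses) show(p)
})

setMethod("show", "PigmentModel", function(object) {
  cat(sprintf(paste0("PigmentModel '%s' (%s): lambda_max %g nm, gain %g,\n",
                     "  alpha %g, beta %g, delta %g, rho %g, dip %g\n"),
              object@label, object@pigmentClass, object@lambdaMax, object@gain,
              object@alpha, object@beta, object@delta, object@rho,
              object@dip))
})

setMethod("show", "EphysRecording", function(object) {
  cat(sprintf("EphysRecording '%s': %.1f s at %g Hz\n", object@cellId,
              diff(range(object@times)), object@sampleRate))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g (n = %s)%s\n",
              object@method, object@statistic, object@p,
              paste(object@n, collapse = ", "),
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "CohortResult", function(object) {
  cat(sprintf("CohortResult: %d cells, %d responsive / %d non-responsive (threshold %g mV)\n",
              nrow(object@deltas), object@nResponsive,
              object@nNonResponsive, object@threshold))
  show(object@test)
})

#' Extract the per-cell delta table from a cohort result
#' @param x a [CohortResult-class].
#' @return data.frame with per-cell windowed deltas and labels.
#' @export
cohortDeltas <- function(x) x@deltas

#' Extract the cohort paired test from a cohort result
#' @param x a [CohortResult-class].
#' @return a [TestResult-class].
#' @export
cohortTest <- function(x) x@test
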