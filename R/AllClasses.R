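#' @import methods
#' @importFrom stats setNames
NULL

.SPECTRUM_KINDS <- c("flat_band", "gaussian_band", "monochromatic")
.PIGMENT_CLASSES <- c("rho_like", "tmt_slow", "tmt_fast", "enc_low_gain",
                      "mutant_null", "non_opsin_control")
.WELL_ROLES <- c("test", "baseline_control", "untransfected")
.PROVENANCE_LEVELS <- c("raw", "normalized", "corrected", "rebaselined")

# ---------------------------------------------------------------------------
# Light stimuli and pigment models
# ---------------------------------------------------------------------------

#' SpectrumModel: emission spectrum of a light source
#'
#' Describes the spectral shape of a stimulus as one of three idealized
#' templates: a flat band between two wavelength edges (broadband "white"
#' source), a Gaussian band around a peak (color filter), or a monochromatic
#' line. Wavelengths are in nanometres.
#'
#' @slot kind one of `"flat_band"`, `"gaussian_band"`, `"monochromatic"`.
#' @slot lambdaMin,lambdaMax band edges in nm (flat_band only).
#' @slot lambdaPeak peak wavelength in nm (gaussian_band, monochromatic).
#' @slot bandwidth Gaussian sd in nm (gaussian_band only).
#'
#' @exportClass SpectrumModel
setClass("SpectrumModel",
  representation(kind = "character", lambdaMin = "numeric",
                 lambdaMax = "numeric", lambdaPeak = "numeric",
                 bandwidth = "numeric"))

setValidity("SpectrumModel", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.SPECTRUM_KINDS, collapse = ", ")))
  wl <- c(object@lambdaMin, object@lambdaMax, object@lambdaPeak)
  wl <- wl[is.finite(wl)]
  if (any(wl <= 200 | wl >= 1200))
    msg <- c(msg, "wavelengths must lie in (200, 1200) nm")
  if (identical(object@kind, "flat_band") &&
      (!is.finite(object@lambdaMin) || !is.finite(object@lambdaMax) ||
       object@lambdaMin >= object@lambdaMax))
    msg <- c(msg, "flat_band requires lambdaMin < lambdaMax")
  if (identical(object@kind, "gaussian_band") &&
      (!is.finite(object@bandwidth) || object@bandwidth <= 0))
    msg <- c(msg, "gaussian_band requires bandwidth > 0")
  if (object@kind %in% c("gaussian_band", "monochromatic") &&
      !is.finite(object@lambdaPeak))
    msg <- c(msg, "lambdaPeak required")
  if (length(msg)) msg else TRUE
})

#' LightPulse: a single light stimulation epoch
#'
#' @slot onset pulse onset in seconds from acquisition start.
#' @slot duration pulse duration in seconds (> 0).
#' @slot spectrum a [SpectrumModel-class].
#' @slot flux total photon flux in photons cm^-2 s^-1 (>= 0; a zero-flux
#'   pulse is a valid "sham" used to define analysis windows for dark
#'   controls).
#'
#' @exportClass LightPulse
setClass("LightPulse",
  representation(onset = "numeric", duration = "numeric",
                 spectrum = "SpectrumModel", flux = "numeric"))

setValidity("LightPulse", function(object) {
  msg <- character()
  if (!is.finite(object@onset)) msg <- c(msg, "onset must be finite")
  if (!is.finite(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  if (!is.finite(object@flux) || object@flux < 0)
    msg <- c(msg, "flux must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StimulusProtocol: an ordered, non-overlapping list of light pulses
#'
#' @slot pulses list of [LightPulse-class] objects, sorted by onset and
#'   pairwise non-overlapping.
#'
#' @exportClass StimulusProtocol
setClass("StimulusProtocol", representation(pulses = "list"))

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (!all(vapply(object@pulses, is, logical(1), "LightPulse")))
    msg <- c(msg, "all pulses must be LightPulse objects")
  if (length(object@pulses) > 1L) {
    on <- vapply(object@pulses, slot, numeric(1), "onset")
    off <- on + vapply(object@pulses, slot, numeric(1), "duration")
    if (is.unsorted(on, strictly = FALSE))
      msg <- c(msg, "pulses must be sorted by onset")
    else if (any(off[-length(off)] > on[-1L]))
      msg <- c(msg, "pulses must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' PigmentModel: spectral and kinetic parameters of a photopigment class
#'
#' Parameterizes how a pigment-expressing well responds to light in the
#' two-state kinetic model used by [simulateImpedancePlate()]: active
#' fraction R and desensitized fraction D evolve as
#' \deqn{R' = \alpha E (1 - R - D) - \beta R, \quad
#'       D' = \delta R \cdot 1[\mathrm{light}] - \rho D,}
#' where E is the normalized photoactivation drive from
#' [effectiveDrive()]. Classes `mutant_null` (Schiff-base lysine mutant)
#' and `non_opsin_control` force E = 0.
#'
#' @slot label free-text construct label.
#' @slot lambdaMax absorption peak in nm.
#' @slot pigmentClass one of `"rho_like"`, `"tmt_slow"`, `"tmt_fast"`,
#'   `"enc_low_gain"`, `"mutant_null"`, `"non_opsin_control"`.
#' @slot gain dimensionless coupling of active pigment to cell index.
#' @slot alpha activation scale, s^-1 per unit drive.
#' @slot beta deactivation rate, s^-1.
#' @slot delta desensitization rate, s^-1 (light-gated).
#' @slot rho resensitization rate, s^-1.
#' @slot dip amplitude of the transient impedance drop right after light
#'   onset (HEK-cell shape; 0 for Neuro-2A defaults).
#'
#' @exportClass PigmentModel
setClass("PigmentModel",
  representation(label = "character", lambdaMax = "numeric",
                 pigmentClass = "character", gain = "numeric", alpha = "numeric",
                 beta = "numeric", delta = "numeric", rho = "numeric",
                 dip = "numeric"))

setValidity("PigmentModel", function(object) {
  msg <- character()
  if (!object@pigmentClass %in% .PIGMENT_CLASSES)
    msg <- c(msg, sprintf("class must be one of %s",
                          paste(.PIGMENT_CLASSES, collapse = ", ")))
  rates <- c(object@alpha, object@beta, object@delta, object@rho)
  if (any(!is.finite(rates) | rates < 0))
    msg <- c(msg, "rates alpha, beta, delta, rho must be >= 0")
  if (!is.finite(object@lambdaMax) || object@lambdaMax <= 200 ||
      object@lambdaMax >= 1200)
    msg <- c(msg, "lambdaMax must lie in (200, 1200) nm")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Impedance data
# ---------------------------------------------------------------------------

#' ImpedanceTrace: one well's cell-index time series
#'
#' The cell index (CI) is the dimensionless impedance-derived readout of an
#' electrode-bearing culture plate. A trace carries a provenance flag that
#' records how far along the processing chain
#' raw -> normalized -> corrected -> rebaselined it has travelled; the
#' analysis functions enforce that transitions only move forward.
#'
#' @slot wellId well identifier.
#' @slot times seconds from acquisition start; uniformly spaced, ascending.
#' @slot ci cell-index values, same length as `times`.
#' @slot provenance one of `"raw"`, `"normalized"`, `"corrected"`,
#'   `"rebaselined"`.
#'
#' @exportClass ImpedanceTrace
setClass("ImpedanceTrace",
  representation(wellId = "character", times = "numeric", ci = "numeric",
                 provenance = "character"))

.uniformSpacing <- function(times, rtol = 1e-6) {
  if (length(times) < 2L) return(FALSE)
  d <- diff(times)
  if (any(d <= 0)) return(FALSE)
  dt <- d[1L]
  all(abs(d - dt) <= rtol * dt)
}

setValidity("ImpedanceTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@ci))
    msg <- c(msg, "times and ci must have the same length")
  if (length(object@times) < 2L)
    msg <- c(msg, "a trace needs at least 2 samples")
  else if (!.uniformSpacing(object@times))
    msg <- c(msg, "times must be ascending and uniformly spaced (1e-6 rel tol)")
  if (!all(is.finite(object@ci)))
    msg <- c(msg, "ci values must be finite")
  if (length(object@provenance) != 1L ||
      !object@provenance %in% .PROVENANCE_LEVELS)
    msg <- c(msg, "invalid provenance")
  if (length(msg)) msg else TRUE
})

#' PlateExperiment: a plate of impedance traces on a shared time grid
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]. The single
#' assay `"ci"` is a time-by-well matrix; `rowData` holds the shared time
#' grid (`time_s`); `colData` holds the per-well annotation (`construct`,
#' `role`); `metadata` carries the [StimulusProtocol-class], the plate-wide
#' provenance flag and, for simulated plates, the seed and generator
#' parameters.
#'
#' @exportClass PlateExperiment
setClass("PlateExperiment", contains = "SummarizedExperiment")

setValidity("PlateExperiment", function(object) {
  msg <- character()
  if (!"ci" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'ci' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("construct", "role") %in% colnames(cd)))
    msg <- c(msg, "colData must have columns 'construct' and 'role'")
  else if (!all(cd$role %in% .WELL_ROLES))
    msg <- c(msg, sprintf("well roles must be one of %s",
                          paste(.WELL_ROLES, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!"time_s" %in% colnames(rd))
    msg <- c(msg, "rowData must have column 'time_s'")
  else if (!.uniformSpacing(rd$time_s))
    msg <- c(msg, "time grid must be ascending and uniformly spaced")
  prov <- S4Vectors::metadata(object)$provenance
  if (is.null(prov) || !prov %in% .PROVENANCE_LEVELS)
    msg <- c(msg, "metadata()$provenance missing or invalid")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Electrophysiology data
# ---------------------------------------------------------------------------

#' EphysRecording: a whole-cell membrane-potential recording
#'
#' @slot cellId cell identifier.
#' @slot times seconds; ascending, uniformly spaced.
#' @slot vm membrane potential in mV, same length as `times`.
#' @slot protocol a single-pulse [StimulusProtocol-class]; the pulse must lie
#'   fully inside the recorded span.
#' @slot sampleRate sampling rate in Hz.
#'
#' @exportClass EphysRecording
setClass("EphysRecording",
  representation(cellId = "character", times = "numeric", vm = "numeric",
                 protocol = "StimulusProtocol", sampleRate = "numeric"))

setValidity("EphysRecording", function(object) {
  msg <- character()
  if (length(object@times) != length(object@vm))
    msg <- c(msg, "times and vm must have the same length")
  if (length(object@times) < 2L || !.uniformSpacing(object@times))
    msg <- c(msg, "times must be ascending and uniformly spaced")
  if (!all(is.finite(object@vm)))
    msg <- c(msg, "vm must be finite")
  if (length(object@protocol@pulses) != 1L)
    msg <- c(msg, "protocol must contain exactly one pulse")
  else {
    p <- object@protocol@pulses[[1L]]
    if (p@onset < object@times[1L] ||
        p@onset + p@duration > object@times[length(object@times)])
      msg <- c(msg, "light pulse must lie fully inside the recording span")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Results
# ---------------------------------------------------------------------------

#' TestResult: outcome of a two-sample or paired statistical test
#'
#' @slot statistic the test statistic (U for Mann-Whitney, t for paired t).
#' @slot p two-sided p value in \[0, 1\].
#' @slot method one of `"mann_whitney_exact"`, `"mann_whitney_normal"`,
#'   `"paired_t"`.
#' @slot n sample sizes per group.
#' @slot degenerate TRUE when the statistic is reported from a degenerate
#'   configuration (e.g. zero-variance paired differences).
#'
#' @exportClass TestResult
setClass("TestResult",
  representation(statistic = "numeric", p = "numeric", method = "character",
                 n = "integer", degenerate = "logical"))

setValidity("TestResult", function(object) {
  if (is.finite(object@p) && (object@p < 0 || object@p > 1))
    "p must lie in [0, 1]" else TRUE
})

#' CohortResult: per-cell windowed deltas, labels, and the cohort paired test
#'
#' @slot deltas data.frame with one row per cell: `cell_id`, `v_ref`,
#'   `delta_m1`, `delta_p1`, `delta_p2` (mV) and `label`
#'   (`"responsive"`/`"non_responsive"`).
#' @slot nResponsive,nNonResponsive label counts (sum to cohort size).
#' @slot test paired t test of delta(-1) vs delta(+1) across the cohort.
#' @slot threshold classification threshold in mV.
#'
#' @exportClass CohortResult
setClass("CohortResult",
  representation(deltas = "data.frame", nResponsive = "integer",
                 nNonResponsive = "integer", test = "TestResult",
                 threshold = "numeric"))

setValidity("CohortResult", function(object) {
  if (object@nResponsive + object@nNonResponsive != nrow(object@deltas))
    "label counts must sum to cohort size" else TRUE
})
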