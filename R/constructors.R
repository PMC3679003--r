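# User-facing constructors for the stimulus / pigment / trace classes.

#' Spectrum constructors
#'
#' `flatBandSpectrum()` models a broadband source with uniform photon-flux
#' density between two wavelength edges (the white LED used for standard
#' stimulation is 450-750 nm). `gaussianBandSpectrum()` models a color
#' filter as a Gaussian passband around a peak. `monochromaticSpectrum()`
#' is a single line (e.g. the 950-nm near-infrared control).
#'
#' @param lambdaMin,lambdaMax band edges in nm.
#' @param lambdaPeak peak wavelength in nm.
#' @param bandwidth Gaussian sd in nm (default 20).
#' @return a [SpectrumModel-class].
#' @examples
#' flatBandSpectrum(450, 750)
#' gaussianBandSpectrum(450)
#' monochromaticSpectrum(950)
#' @export
flatBandSpectrum <- function(lambdaMin, lambdaMax) {
  new("SpectrumModel", kind = "flat_band", lambdaMin = lambdaMin,
      lambdaMax = lambdaMax, lambdaPeak = NA_real_, bandwidth = NA_real_)
}

#' @rdname flatBandSpectrum
#' @export
gaussianBandSpectrum <- function(lambdaPeak, bandwidth = 20) {
  new("SpectrumModel", kind = "gaussian_band", lambdaMin = NA_real_,
      lambdaMax = NA_real_, lambdaPeak = lambdaPeak, bandwidth = bandwidth)
}

#' @rdname flatBandSpectrum
#' @export
monochromaticSpectrum <- function(lambdaPeak) {
  new("SpectrumModel", kind = "monochromatic", lambdaMin = NA_real_,
      lambdaMax = NA_real_, lambdaPeak = lambdaPeak, bandwidth = NA_real_)
}

#' Construct a light pulse
#'
#' @param onset onset in seconds from acquisition start.
#' @param duration duration in seconds.
#' @param spectrum a [SpectrumModel-class].
#' @param flux total photon flux in photons cm^-2 s^-1. A zero-flux pulse is
#'   a sham: it defines analysis windows without stimulating.
#' @return a [LightPulse-class].
#' @export
lightPulse <- function(onset, duration, spectrum = flatBandSpectrum(450, 750),
                       flux = 1.3e16) {
  new("LightPulse", onset = onset, duration = duration, spectrum = spectrum,
      flux = flux)
}

#' Construct a stimulus protocol from light pulses
#'
#' @param ... [LightPulse-class] objects, or a single list of them.
#' @return a [StimulusProtocol-class].
#' @export
stimulusProtocol <- function(...) {
  pulses <- list(...)
  if (length(pulses) == 1L && is.list(pulses[[1L]]) &&
      !is(pulses[[1L]], "LightPulse"))
    pulses <- pulses[[1L]]
  new("StimulusProtocol", pulses = pulses)
}

#' Construct a pigment model
#'
#' See [PigmentModel-class] for the meaning of the kinetic parameters and
#' [defaultPigments()] for the calibrated per-class defaults.
#'
#' @param label construct label.
#' @param class pigment class.
#' @param lambdaMax absorption peak, nm.
#' @param gain,alpha,beta,delta,rho,dip kinetic parameters.
#' @return a [PigmentModel-class].
#' @export
pigmentModel <- function(label, class, lambdaMax = 497, gain = 0.5,
                         alpha = 0.008, beta = 0.010, delta = 0.002,
                         rho = 5e-4, dip = 0) {
  new("PigmentModel", label = label, lambdaMax = lambdaMax,
      pigmentClass = class,
      gain = gain, alpha = alpha, beta = beta, delta = delta, rho = rho,
      dip = dip)
}

#' Calibrated default pigment models per class
#'
#' The defaults encode the qualitative assay phenotypes: the rhodopsin-like
#' positive control peaks about 3 min into a saturating white pulse and
#' relaxes with a ~100 s time constant after light-off; group-2-like
#' pigments (`tmt_fast`) deactivate markedly faster than group-1/3-like
#' pigments (`tmt_slow`); `enc_low_gain` couples to the cell index at 0.3x
#' the TMT gain; `mutant_null` (Schiff-base lysine to alanine) and
#' `non_opsin_control` produce no drive at all.
#'
#' @return named list of [PigmentModel-class] objects.
#' @export
defaultPigments <- function() {
  list(
    rho_like = pigmentModel("rhodopsin", "rho_like", lambdaMax = 497),
    tmt_slow = pigmentModel("tmt_group13", "tmt_slow", lambdaMax = 460,
                            beta = 0.003),
    tmt_fast = pigmentModel("tmt_group2", "tmt_fast", lambdaMax = 460,
                            beta = 0.020),
    enc_low_gain = pigmentModel("encephalopsin", "enc_low_gain",
                                lambdaMax = 460, gain = 0.15),
    mutant_null = pigmentModel("schiff_base_null", "mutant_null",
                               lambdaMax = 460),
    non_opsin_control = pigmentModel("oxytocin_receptor",
                                     "non_opsin_control", lambdaMax = 497,
                                     gain = 0)
  )
}

#' Construct an impedance trace
#'
#' @param wellId well identifier.
#' @param times seconds, uniformly spaced ascending.
#' @param ci cell-index values.
#' @param provenance processing stage; new traces are `"raw"`.
#' @return an [ImpedanceTrace-class].
#' @export
ImpedanceTrace <- function(wellId, times, ci, provenance = "raw") {
  new("ImpedanceTrace", wellId = wellId, times = as.numeric(times),
      ci = as.numeric(ci), provenance = provenance)
}

#' Construct a plate experiment from a CI matrix
#'
#' @param ci time-by-well numeric matrix with well ids as column names.
#' @param times shared time grid in seconds (length `nrow(ci)`).
#' @param annotations data.frame with columns `well`, `construct`, `role`
#'   covering every column of `ci`.
#' @param protocol a [StimulusProtocol-class].
#' @param provenance plate-wide processing stage.
#' @param metadata extra metadata entries (seed, generator parameters, ...).
#' @return a [PlateExperiment-class].
#' @export
PlateExperiment <- function(ci, times, annotations, protocol,
                            provenance = "raw", metadata = list()) {
  if (is.null(colnames(ci)))
    stop("ci matrix must have well ids as column names")
  missing <- setdiff(colnames(ci), annotations$well)
  if (length(missing))
    stop("annotation error: wells without annotation: ",
         paste(missing, collapse = ", "))
  ann <- annotations[match(colnames(ci), annotations$well), , drop = FALSE]
  bad <- setdiff(unique(ann$role), .WELL_ROLES)
  if (length(bad))
    stop("annotation error: unknown role(s): ", paste(bad, collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ci = ci),
    rowData = S4Vectors::DataFrame(time_s = as.numeric(times)),
    colData = S4Vectors::DataFrame(construct = ann$construct, role = ann$role,
                                   row.names = colnames(ci)),
    metadata = c(list(protocol = protocol, provenance = provenance),
                 metadata))
  new("PlateExperiment", se)
}

#' Construct an electrophysiology recording
#'
#' @param cellId cell identifier.
#' @param times seconds, uniformly spaced.
#' @param vm membrane potential in mV.
#' @param protocol single-pulse [StimulusProtocol-class].
#' @param sampleRate sampling rate in Hz.
#' @return an [EphysRecording-class].
#' @export
EphysRecording <- function(cellId, times, vm, protocol, sampleRate) {
  new("EphysRecording", cellId = cellId, times = as.numeric(times),
      vm = as.numeric(vm), protocol = protocol, sampleRate = sampleRate)
}
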