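# Canned stimulus protocols matching the standard assay designs.

#' Standard plate stimulation protocol
#'
#' A single white-light pulse preceded by an equally long dark phase (used
#' by the AUC-ratio statistic) and followed by enough darkness for the
#' kinetics probe. Defaults: 600 s (10 min) white pulse starting at 720 s.
#'
#' @param onset pulse onset in seconds.
#' @param duration pulse duration in seconds.
#' @param flux photon flux; default white LED 1.3e16.
#' @param spectrum a [SpectrumModel-class]; default flat 450-750 nm.
#' @return a [StimulusProtocol-class].
#' @export
defaultPlateProtocol <- function(onset = 720, duration = 600,
                                 flux = defaultFluxes()[["white"]],
                                 spectrum = flatBandSpectrum(450, 750)) {
  stimulusProtocol(lightPulse(onset, duration, spectrum, flux))
}

#' Wavelength-sensitivity protocol: white pulse, then a color pulse
#'
#' The spectral assay first stimulates every well with a 10-min white pulse
#' and, 60 min later, with a 10-min color pulse; the color response is then
#' expressed as a percentage of the same well's white response
#' ([spectralPercentAUC()]), cancelling well-to-well variation.
#'
#' @param color one of `"blue"`, `"green"`, `"red"`, `"nir"`, selecting the
#'   filter peak (450 / 528 / 605 / 950 nm) and its measured flux, or a
#'   [LightPulse-class] to use verbatim as the second pulse.
#' @param whiteOnset onset of the white pulse, s.
#' @param duration duration of both pulses, s.
#' @param gap dark gap between white offset and color onset, s (default
#'   3600).
#' @return a two-pulse [StimulusProtocol-class].
#' @export
wavelengthProtocol <- function(color = "blue", whiteOnset = 720,
                               duration = 600, gap = 3600) {
  fluxes <- defaultFluxes()
  white <- lightPulse(whiteOnset, duration, flatBandSpectrum(450, 750),
                      fluxes[["white"]])
  colorOnset <- whiteOnset + duration + gap
  if (is(color, "LightPulse")) {
    cp <- color
  } else {
    peak <- switch(color, blue = 450, green = 528, red = 605, nir = 950,
                   stop("unknown color: ", color))
    spec <- if (identical(color, "nir")) monochromaticSpectrum(950) else
      gaussianBandSpectrum(peak)
    cp <- lightPulse(colorOnset, duration, spec, fluxes[[color]])
  }
  stimulusProtocol(white, cp)
}

#' Standard slice-recording protocol
#'
#' 2 min darkness, a 1-min light pulse, then 2 min of dark recovery. The
#' default source is the broadband halogen lamp at 2.53e16 photons
#' cm^-2 s^-1; `sham = TRUE` sets the flux to zero to produce the
#' dark-control protocol with identical analysis windows.
#'
#' @param sham logical; zero-flux pulse for dark controls.
#' @param onset pulse onset, s (default 120).
#' @param duration pulse duration, s (default 60).
#' @param flux photon flux of the pulse.
#' @return a [StimulusProtocol-class].
#' @export
defaultEphysProtocol <- function(sham = FALSE, onset = 120, duration = 60,
                                 flux = defaultFluxes()[["halogen"]]) {
  stimulusProtocol(lightPulse(onset, duration, flatBandSpectrum(450, 750),
                              if (sham) 0 else flux))
}
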