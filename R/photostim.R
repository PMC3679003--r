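# Spectral sensitivity templates and the effective photoactivation drive.

#' Instrument photon fluxes used by the default protocols
#'
#' Total photon fluxes (photons cm^-2 s^-1) of the standard light sources:
#' white LED (450-750 nm), blue / green / red filtered light, the halogen
#' source used for slice stimulation, and the near-infrared control line.
#'
#' @return named numeric vector.
#' @export
defaultFluxes <- function() {
  c(white = 1.3e16, blue = 3.6e14, green = 1.9e14, red = 7.4e14,
    halogen = 2.53e16, nir = 7.4e14)
}

#' Relative spectral sensitivity of a pigment
#'
#' A Gaussian template in log-wavelength: peak value 1 at `lambdaMax`,
#' falling off symmetrically in log(lambda) with half-bandwidth `bw`
#' (log units, default 0.08). The template reproduces the ordinal spectral
#' facts the assay rests on — stronger blue than green activation for a
#' blue-shifted pigment, and essentially zero sensitivity of any visible
#' pigment at 950 nm — without committing to a full visual-pigment
#' nomogram (an extension hook).
#'
#' @param pigment a [PigmentModel-class]; must not be a
#'   `non_opsin_control`.
#' @param lambda wavelength(s) in nm, > 0.
#' @param bw template half-bandwidth in log-wavelength units.
#' @return relative sensitivity in \[0, 1\], vectorized over `lambda`.
#' @examples
#' spectralSensitivity(defaultPigments()$rho_like, c(497, 450, 950))
#' @export
spectralSensitivity <- function(pigment, lambda, bw = 0.08) {
  stopifnot(is(pigment, "PigmentModel"))
  if (pigment@pigmentClass == "non_opsin_control")
    stop("non_opsin_control has no spectral sensitivity")
  if (any(!is.finite(lambda) | lambda <= 0))
    stop("wavelengths must be positive")
  exp(-0.5 * (log(lambda / pigment@lambdaMax) / bw)^2)
}

# photon-flux density F(lambda) of a pulse on a wavelength grid, scaled so
# that the trapezoid integral over the grid equals the pulse's total flux.
.spectrumGrid <- function(spectrum, step = 0.25) {
  switch(spectrum@kind,
    flat_band = seq(spectrum@lambdaMin, spectrum@lambdaMax, by = step),
    gaussian_band = seq(max(201, spectrum@lambdaPeak - 6 * spectrum@bandwidth),
                        min(1199, spectrum@lambdaPeak + 6 * spectrum@bandwidth),
                        by = step),
    monochromatic = spectrum@lambdaPeak)
}

#' Photon-flux density of a pulse over a wavelength grid
#'
#' @param pulse a [LightPulse-class].
#' @param lambda wavelengths in nm; defaults to the spectrum's own support
#'   grid.
#' @return list with `lambda` and `density` (photons cm^-2 s^-1 nm^-1); for
#'   a monochromatic spectrum the `density` is the total flux at the single
#'   line (treated as a delta in integrals).
#' @export
photonFluxDensity <- function(pulse, lambda = NULL) {
  sp <- pulse@spectrum
  if (is.null(lambda)) lambda <- .spectrumGrid(sp)
  if (sp@kind == "monochromatic")
    return(list(lambda = sp@lambdaPeak, density = pulse@flux))
  shape <- switch(sp@kind,
    flat_band = as.numeric(lambda >= sp@lambdaMin & lambda <= sp@lambdaMax),
    gaussian_band = stats::dnorm(lambda, sp@lambdaPeak, sp@bandwidth))
  area <- pracma::trapz(lambda, shape)
  if (area <= 0) stop("empty spectrum support")
  list(lambda = lambda, density = pulse@flux * shape / area)
}

#' Reference flux for drive normalization
#'
#' The spectrally weighted flux collected by the rhodopsin-like reference
#' pigment (lambda_max 497 nm) under the default white pulse
#' (flat 450-750 nm at 1.3e16 photons cm^-2 s^-1). Dividing by this value
#' makes [effectiveDrive()] equal 1 for the reference pigment under the
#' default white stimulus, which is the saturating condition the kinetic
#' defaults are calibrated against.
#'
#' @param bw template half-bandwidth passed to [spectralSensitivity()].
#' @return photons cm^-2 s^-1 (scalar).
#' @export
referenceFlux <- local({
  cache <- new.env(parent = emptyenv())
  function(bw = 0.08) {
    key <- format(bw, digits = 15)
    if (is.null(cache[[key]])) {
      ref <- pigmentModel("reference", "rho_like", lambdaMax = 497)
      pulse <- lightPulse(0, 600, flatBandSpectrum(450, 750), 1.3e16)
      fd <- photonFluxDensity(pulse)
      cache[[key]] <- pracma::trapz(
        fd$lambda, fd$density * spectralSensitivity(ref, fd$lambda, bw))
    }
    cache[[key]]
  }
})

#' Effective photoactivation drive of a pulse on a pigment
#'
#' The normalized drive \eqn{E = \int F(\lambda) S(\lambda) d\lambda /
#' F_{ref}}, where F is the pulse's photon-flux density, S the pigment's
#' spectral sensitivity template and \eqn{F_{ref}} the reference flux of
#' [referenceFlux()]. E is linear in the pulse's total photon flux and
#' equals 1 for the rhodopsin-like reference under the default white pulse.
#' `mutant_null` and `non_opsin_control` pigments have zero drive
#' regardless of the stimulus (no functional chromophore / no opsin).
#'
#' @param pigment a [PigmentModel-class].
#' @param pulse a [LightPulse-class].
#' @param fRef reference flux; default [referenceFlux()].
#' @param bw template half-bandwidth in log-wavelength units.
#' @return dimensionless drive (0 for null classes).
#' @examples
#' effectiveDrive(defaultPigments()$rho_like,
#'                lightPulse(0, 600, flatBandSpectrum(450, 750), 1.3e16))
#' @export
effectiveDrive <- function(pigment, pulse, fRef = referenceFlux(bw), bw = 0.08) {
  stopifnot(is(pigment, "PigmentModel"), is(pulse, "LightPulse"))
  if (pigment@pigmentClass %in% c("mutant_null", "non_opsin_control")) return(0)
  if (pulse@flux == 0) return(0)
  fd <- photonFluxDensity(pulse)
  if (pulse@spectrum@kind == "monochromatic")
    return(fd$density * spectralSensitivity(pigment, fd$lambda, bw) / fRef)
  pracma::trapz(fd$lambda,
                fd$density * spectralSensitivity(pigment, fd$lambda, bw)) / fRef
}
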