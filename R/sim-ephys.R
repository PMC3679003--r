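# Synthetic whole-cell recordings: OU dark noise + planted light responses.

#' Generator parameters for synthetic recording cohorts
#'
#' Each cell's membrane potential is a mean-reverting
#' (Ornstein-Uhlenbeck) process around its own resting potential,
#' \deqn{dV = -\theta (V - V_{rest}) dt + \sigma dW,}
#' simulated by its exact AR(1) discretization and started from the
#' stationary distribution. Responsive cells additionally receive a
#' saturating depolarization of amplitude A during the light window
#' (exponential rise, exponential decay after light-off). Optionally,
#' stereotyped spikes are injected by inhomogeneous-Poisson thinning; the
#' windowed-mean statistics are designed to be robust to them.
#'
#' The dark-noise level (`ouSd`) is a calibration: it is set so that
#' windowed deltas of dark-only cells stay far below the 10 mV bound while
#' planted responses of at least 12 mV are always recovered.
#'
#' @param restingMean mean resting potential across cells, mV.
#' @param restingSd sd of resting potential across cells, mV.
#' @param ouRate OU mean-reversion rate theta, s^-1.
#' @param ouSd stationary sd of the OU dark noise, mV.
#' @param ampRange range (min, max) of the uniform light-evoked amplitude
#'   distribution for responsive cells, mV.
#' @param riseTau,decayTau response rise and post-light decay time
#'   constants, s (0 = instantaneous).
#' @param sampleRate simulation sampling rate, Hz.
#' @param postDark dark tail recorded after light-off, s.
#' @param spike list: `enabled`, `rateHz` (dark spike rate), `ampMv`,
#'   `widthMs`, `lightFactor` (rate multiplier during light for responsive
#'   cells).
#' @return list of class `EphysGenParams`.
#' @export
ephysGenParams <- function(restingMean = -30.91, restingSd = 5,
                           ouRate = 0.05, ouSd = 0.6,
                           ampRange = c(12, 35), riseTau = 2, decayTau = 10,
                           sampleRate = 1000, postDark = 120,
                           spike = list(enabled = FALSE, rateHz = 1,
                                        ampMv = 60, widthMs = 4,
                                        lightFactor = 2)) {
  stopifnot(ouRate > 0, ouSd >= 0, restingSd >= 0, sampleRate > 0,
            length(ampRange) == 2L, all(ampRange > 0),
            ampRange[1L] <= ampRange[2L], riseTau >= 0, decayTau >= 0)
  structure(list(restingMean = restingMean, restingSd = restingSd,
                 ouRate = ouRate, ouSd = ouSd, ampRange = ampRange,
                 riseTau = riseTau, decayTau = decayTau,
                 sampleRate = sampleRate, postDark = postDark,
                 spike = spike),
            class = "EphysGenParams")
}

# OU noise of length n at spacing dt, stationary start (exact AR(1)).
.ouNoise <- function(n, dt, rate, sd) {
  if (sd == 0) return(rep(0, n))
  phi <- exp(-rate * dt)
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  e[1L] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# deterministic light-evoked depolarization waveform on `times`.
.responseWaveform <- function(times, onset, offset, amp, riseTau, decayTau) {
  r <- numeric(length(times))
  inl <- times >= onset & times < offset
  r[inl] <- if (riseTau > 0)
    amp * (1 - exp(-(times[inl] - onset) / riseTau)) else amp
  post <- times >= offset
  vOff <- if (riseTau > 0)
    amp * (1 - exp(-(offset - onset) / riseTau)) else amp
  r[post] <- if (decayTau > 0)
    vOff * exp(-(times[post] - offset) / decayTau) else 0
  r
}

# spike train by thinning; returns additive waveform on `times`.
.spikeWaveform <- function(times, dt, sp, lightOn, lightOff, responsive) {
  maxRate <- sp$rateHz * max(1, if (responsive) sp$lightFactor else 1)
  span <- times[length(times)] - times[1L]
  nCand <- stats::rpois(1, maxRate * span)
  if (nCand == 0) return(numeric(length(times)))
  cand <- sort(stats::runif(nCand, times[1L], times[length(times)]))
  rate <- ifelse(responsive & cand >= lightOn & cand < lightOff,
                 sp$rateHz * sp$lightFactor, sp$rateHz)
  keep <- cand[stats::runif(nCand) < rate / maxRate]
  w <- numeric(length(times))
  halfW <- sp$widthMs / 1000 / 2
  for (tk in keep) {
    idx <- which(times >= tk - halfW & times <= tk + halfW)
    if (length(idx))
      w[idx] <- w[idx] + sp$ampMv * cos(pi * (times[idx] - tk) / (2 * halfW))
  }
  w
}

#' Simulate a cohort of whole-cell recordings
#'
#' Generates `nCells` recordings under the given single-pulse protocol, of
#' which `nResponsive` (chosen at random) carry a planted light response.
#' Cells respond only if the pulse has nonzero flux, so a sham (zero-flux)
#' protocol yields a pure dark-control cohort with identical analysis
#' windows. The same seed always yields a bit-identical cohort.
#'
#' @param nCells cohort size.
#' @param nResponsive number of planted responders (0 <= nResponsive <=
#'   nCells).
#' @param protocol single-pulse [StimulusProtocol-class]; default
#'   [defaultEphysProtocol()].
#' @param params an `EphysGenParams` list; see [ephysGenParams()].
#' @param seed integer seed (mandatory).
#' @return list with `recordings` (list of [EphysRecording-class]) and
#'   `truth` (data.frame: `cell_id`, `responsive`, `v_rest`, `amplitude`).
#' @examples
#' coh <- simulateEphysCohort(4, 1, seed = 1)
#' coh$truth
#' @export
simulateEphysCohort <- function(nCells, nResponsive,
                                protocol = defaultEphysProtocol(),
                                params = ephysGenParams(), seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic generation")
  if (nResponsive < 0 || nResponsive > nCells)
    stop("invalid counts: need 0 <= nResponsive <= nCells")
  stopifnot(is(protocol, "StimulusProtocol"),
            length(protocol@pulses) == 1L)
  pulse <- protocol@pulses[[1L]]
  onset <- pulse@onset; offset <- onset + pulse@duration
  dt <- 1 / params$sampleRate
  times <- seq(0, offset + params$postDark, by = dt)

  set.seed(seed)
  respIdx <- if (nResponsive > 0) sort(sample.int(nCells, nResponsive))
             else integer(0)
  ids <- sprintf("cell%02d", seq_len(nCells))
  recs <- vector("list", nCells)
  vRest <- amp <- numeric(nCells)
  for (i in seq_len(nCells)) {
    vRest[i] <- stats::rnorm(1, params$restingMean, params$restingSd)
    responsive <- i %in% respIdx
    amp[i] <- if (responsive)
      stats::runif(1, params$ampRange[1L], params$ampRange[2L]) else 0
    vm <- vRest[i] + .ouNoise(length(times), dt, params$ouRate, params$ouSd)
    if (responsive && pulse@flux > 0)
      vm <- vm + .responseWaveform(times, onset, offset, amp[i],
                                   params$riseTau, params$decayTau)
    if (isTRUE(params$spike$enabled))
      vm <- vm + .spikeWaveform(times, dt, params$spike, onset, offset,
                                responsive && pulse@flux > 0)
    recs[[i]] <- EphysRecording(ids[i], times, vm, protocol,
                                params$sampleRate)
  }
  list(recordings = recs,
       truth = data.frame(cell_id = ids,
                          responsive = seq_len(nCells) %in% respIdx,
                          v_rest = vRest, amplitude = amp))
}
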