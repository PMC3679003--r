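# Synthetic impedance plates: two-state pigment kinetics + plate noise model.

#' Generator parameters for synthetic impedance plates
#'
#' The generator produces, for each well, a cell-index trace
#' \deqn{CI(t) = C_0 g_w \, drift(t) \, (1 + g R(t) - d \cdot dip(t)) +
#'   \epsilon(t)}
#' where R(t) is the active-pigment fraction from the two-state model of
#' [PigmentModel-class], drift is a slow shared plate trend, \eqn{g_w} a
#' multiplicative well gain, dip a brief post-onset impedance drop (the
#' HEK-cell shape; amplitude d = 0 for the Neuro-2A defaults) and
#' \eqn{\epsilon} additive sampling noise.
#'
#' @param pigments named list of [PigmentModel-class] per class; defaults
#'   from [defaultPigments()].
#' @param C0 baseline cell-index level (> 0).
#' @param driftPerHour linear plate drift rate per hour (shared by all
#'   wells, so baseline correction can remove it).
#' @param gainSd sd of the lognormal multiplicative well-to-well gain.
#' @param noiseSd sd of the additive per-sample noise (CI units).
#' @param dipTau time constant of the post-onset dip, s.
#' @param dt output sampling interval, s (instrument default 15).
#' @param odeStep internal fixed RK4 step, s; must divide `dt`.
#' @param postDark dark tail simulated after the last pulse, s.
#' @return list of class `ImpedanceGenParams`.
#' @export
impedanceGenParams <- function(pigments = defaultPigments(), C0 = 2.0,
                               driftPerHour = 0.01, gainSd = 0.05,
                               noiseSd = 0.005, dipTau = 60, dt = 15,
                               odeStep = 1, postDark = 600) {
  stopifnot(C0 > 0, gainSd >= 0, noiseSd >= 0, dipTau > 0,
            dt > 0, odeStep > 0, abs(dt / odeStep - round(dt / odeStep)) < 1e-9)
  structure(list(pigments = pigments, C0 = C0, driftPerHour = driftPerHour,
                 gainSd = gainSd, noiseSd = noiseSd, dipTau = dipTau,
                 dt = dt, odeStep = odeStep, postDark = postDark),
            class = "ImpedanceGenParams")
}

# integrate the two-state model for one pigment under a protocol.
# returns R(t) on `times` (fixed-step RK4 via deSolve at `step` resolution).
.pigmentTrajectory <- function(pigment, proto, times, step) {
  drives <- vapply(proto@pulses, function(p) effectiveDrive(pigment, p),
                   numeric(1))
  on <- vapply(proto@pulses, slot, numeric(1), "onset")
  off <- on + vapply(proto@pulses, slot, numeric(1), "duration")
  driveAt <- function(t) {
    i <- which(t >= on & t < off)
    if (length(i)) drives[i[1L]] else 0
  }
  if (all(drives == 0)) return(rep(0, length(times)))
  odeTimes <- seq(times[1L], times[length(times)], by = step)
  rhs <- function(t, y, parms) {
    e <- driveAt(t)
    light <- e > 0
    list(c(parms$alpha * e * (1 - y[1L] - y[2L]) - parms$beta * y[1L],
           parms$delta * y[1L] * light - parms$rho * y[2L]))
  }
  sol <- deSolve::ode(c(R = 0, D = 0), odeTimes, rhs,
                      parms = list(alpha = pigment@alpha, beta = pigment@beta,
                                   delta = pigment@delta, rho = pigment@rho),
                      method = "rk4")
  idx <- round((times - times[1L]) / step) + 1L
  sol[idx, "R"]
}

#' Simulate an impedance plate experiment
#'
#' Integrates the two-state pigment model once per pigment class present in
#' the layout (fixed-step RK4; the trajectory is deterministic), then adds
#' the per-well gain, shared drift, onset dip and sampling noise. The same
#' seed always yields a bit-identical plate.
#'
#' @param layout data.frame with columns `well` and `class` (a name in
#'   `params$pigments`); optional `label` (defaults to the pigment label)
#'   and `role` (defaults to `"baseline_control"` for
#'   `non_opsin_control` wells and `"test"` otherwise). At least one
#'   well must end up `baseline_control`.
#' @param protocol a [StimulusProtocol-class].
#' @param params an `ImpedanceGenParams` list; see [impedanceGenParams()].
#' @param seed integer seed (mandatory: the generator is stochastic).
#' @return a raw [PlateExperiment-class]; `metadata()` carries the seed,
#'   the parameters and the layout.
#' @examples
#' pe <- simulateImpedancePlate(
#'   data.frame(well = c("A1", "A2"),
#'              class = c("rho_like", "non_opsin_control")),
#'   defaultPlateProtocol(), seed = 1)
#' @export
simulateImpedancePlate <- function(layout, protocol,
                                   params = impedanceGenParams(), seed) {
  stopifnot(is(protocol, "StimulusProtocol"), is.data.frame(layout))
  if (missing(seed)) stop("seed is mandatory for stochastic generation")
  if (!all(c("well", "class") %in% names(layout)))
    stop("layout needs columns 'well' and 'class'")
  unknown <- setdiff(unique(layout$class), names(params$pigments))
  if (length(unknown))
    stop("layout/annotation mismatch: unknown class(es): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(layout$well)) stop("duplicate well ids in layout")
  if (is.null(layout$role))
    layout$role <- ifelse(layout$class == "non_opsin_control",
                          "baseline_control", "test")
  if (!any(layout$role == "baseline_control"))
    stop("layout must include at least one baseline_control well")
  if (is.null(layout$label))
    layout$label <- vapply(layout$class,
                           function(cl) params$pigments[[cl]]@label,
                           character(1))

  on <- vapply(protocol@pulses, slot, numeric(1), "onset")
  off <- on + vapply(protocol@pulses, slot, numeric(1), "duration")
  span <- ceiling((max(off) + params$postDark) / params$dt) * params$dt
  times <- seq(0, span, by = params$dt)
  n <- length(times)

  classes <- unique(layout$class)
  traj <- lapply(setNames(classes, classes), function(cl)
    .pigmentTrajectory(params$pigments[[cl]], protocol, times,
                       params$odeStep))

  dip <- rep(0, n)
  for (k in seq_along(on))
    dip <- dip + ifelse(times >= on[k],
                        exp(-(times - on[k]) / params$dipTau), 0)
  drift <- 1 + params$driftPerHour * times / 3600

  set.seed(seed)
  ci <- matrix(NA_real_, n, nrow(layout),
               dimnames = list(NULL, layout$well))
  for (i in seq_len(nrow(layout))) {
    pg <- params$pigments[[layout$class[i]]]
    gw <- exp(stats::rnorm(1, 0, params$gainSd))
    shape <- 1 + pg@gain * traj[[layout$class[i]]] - pg@dip * dip
    ci[, i] <- params$C0 * gw * drift * shape +
      stats::rnorm(n, 0, params$noiseSd)
  }

  PlateExperiment(ci, times,
                  data.frame(well = layout$well, construct = layout$label,
                             role = layout$role),
                  protocol, provenance = "raw",
                  metadata = list(seed = seed, genParams = params,
                                  layout = layout))
}
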