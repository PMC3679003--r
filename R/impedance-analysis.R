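# The impedance (RTCA) quantification pipeline: normalization, baseline
# correction, AUC light-response ratio, spectral %AUC, kinetics, group tests.

#' @rdname normalizeCI
#' @export
setGeneric("normalizeCI", function(x, onset, ...) standardGeneric("normalizeCI"))
#' @rdname baselineCorrect
#' @export
setGeneric("baselineCorrect", function(x, controls, ...)
  standardGeneric("baselineCorrect"))

#' Normalize a cell-index trace to its pre-light value
#'
#' Divides every sample by the CI at the last time point strictly before
#' light onset, so the trace equals exactly 1 there. This removes the
#' well-to-well differences in absolute cell coverage; any common positive
#' gain applied to a raw plate cancels entirely.
#'
#' @param x a raw [ImpedanceTrace-class] or [PlateExperiment-class].
#' @param onset light onset in seconds; for a plate, defaults to the onset
#'   of the first protocol pulse.
#' @param ... unused.
#' @return the normalized object (provenance `"normalized"`).
#' @examples
#' tr <- ImpedanceTrace("w", c(0, 15, 30), c(1, 2, 4))
#' ciValues(normalizeCI(tr, onset = 20))  # 0.5 1 2
#' @export
setMethod("normalizeCI", "ImpedanceTrace", function(x, onset, ...) {
  if (x@provenance != "raw")
    stop("normalizeCI expects a raw trace (got ", x@provenance, ")")
  idx <- which(x@times < onset)
  if (!length(idx))
    stop("no-reference error: onset precedes the first sample")
  ref <- x@ci[max(idx)]
  if (ref <= 0)
    stop("degenerate-well error: reference CI <= 0 in well ", x@wellId)
  ImpedanceTrace(x@wellId, x@times, x@ci / ref, provenance = "normalized")
})

#' @rdname normalizeCI
setMethod("normalizeCI", "PlateExperiment", function(x, onset, ...) {
  if (provenance(x) != "raw")
    stop("normalizeCI expects a raw plate (got ", provenance(x), ")")
  if (missing(onset)) {
    p <- protocol(x)@pulses
    if (!length(p)) stop("no pulses in protocol and no onset given")
    onset <- p[[1L]]@onset
  }
  times <- traceTimes(x)
  idx <- which(times < onset)
  if (!length(idx))
    stop("no-reference error: onset precedes the first sample")
  m <- SummarizedExperiment::assay(x, "ci")
  refs <- m[max(idx), ]
  if (any(refs <= 0))
    stop("degenerate-well error: reference CI <= 0 in well(s) ",
         paste(colnames(m)[refs <= 0], collapse = ", "))
  out <- x
  SummarizedExperiment::assay(out, "ci") <- sweep(m, 2L, refs, "/")
  S4Vectors::metadata(out)$provenance <- "normalized"
  S4Vectors::metadata(out)$normalization_onset <- onset
  out
})

#' Baseline-correct normalized traces against control wells
#'
#' Subtracts the pointwise mean of the normalized light-insensitive control
#' traces (non-opsin-transfected wells, e.g. Oxytocin receptor) from a
#' trace, removing shared plate trends unrelated to the light response. A
#' control corrected against itself alone is identically zero.
#'
#' @param x a normalized [ImpedanceTrace-class], or a normalized
#'   [PlateExperiment-class] (controls are its `baseline_control` wells and
#'   the subtraction is applied to all wells).
#' @param controls list of normalized control [ImpedanceTrace-class]s on
#'   the same time grid (trace method only).
#' @param ... unused.
#' @return the corrected object (provenance `"corrected"`).
#' @export
setMethod("baselineCorrect", "ImpedanceTrace", function(x, controls, ...) {
  if (x@provenance != "normalized")
    stop("baselineCorrect expects a normalized trace (got ",
         x@provenance, ")")
  if (is(controls, "ImpedanceTrace")) controls <- list(controls)
  if (!length(controls)) stop("empty control set")
  for (ctl in controls) {
    if (length(ctl@times) != length(x@times) ||
        any(abs(ctl@times - x@times) > 1e-9))
      stop("grid mismatch between trace and control")
    if (ctl@provenance != "normalized")
      stop("controls must be normalized traces")
  }
  base <- rowMeans(do.call(cbind, lapply(controls, slot, "ci")))
  ImpedanceTrace(x@wellId, x@times, x@ci - base, provenance = "corrected")
})

#' @rdname baselineCorrect
setMethod("baselineCorrect", "PlateExperiment", function(x, controls, ...) {
  if (provenance(x) != "normalized")
    stop("baselineCorrect expects a normalized plate (got ",
         provenance(x), ")")
  ann <- annotations(x)
  ctlWells <- ann$well[ann$role == "baseline_control"]
  if (!length(ctlWells))
    stop("empty control set: no baseline_control wells on the plate")
  m <- SummarizedExperiment::assay(x, "ci")
  base <- rowMeans(m[, ctlWells, drop = FALSE])
  out <- x
  SummarizedExperiment::assay(out, "ci") <- m - base
  S4Vectors::metadata(out)$provenance <- "corrected"
  out
})

# trapezoid integral of the piecewise-linear trace over [a, b], with linear
# interpolation at the window boundaries.
.windowAUC <- function(times, values, a, b) {
  if (a < times[1L] - 1e-9 || b > times[length(times)] + 1e-9)
    stop("windowing error: trace does not cover [", a, ", ", b, "]")
  inner <- times > a & times < b
  tt <- c(a, times[inner], b)
  vv <- c(stats::approx(times, values, a)$y, values[inner],
          stats::approx(times, values, b)$y)
  pracma::trapz(tt, vv)
}

#' Relative light response (AUC ratio) of a corrected trace
#'
#' The light response of a well is quantified as the area under the curve
#' during the light pulse divided by the area during the immediately
#' preceding dark window of equal length. Because the corrected trace
#' hovers around zero in darkness (the dark AUC of a perfect non-responder
#' would be ~0, making the ratio ill-posed), the corrected trace is first
#' re-offset by +1; a flat-zero corrected trace then yields exactly 1.0.
#'
#' @param trace a corrected [ImpedanceTrace-class].
#' @param pulse the [LightPulse-class] to quantify.
#' @param protocol optional [StimulusProtocol-class]; when given, an error
#'   is raised if another pulse intrudes into the dark reference window.
#' @return one-row data.frame: `well`, `ratio`, `pulse_onset`,
#'   `dark_start`, `light_start`, `light_end`, `degenerate`.
#' @export
relativeLightResponse <- function(trace, pulse, protocol = NULL) {
  stopifnot(is(trace, "ImpedanceTrace"), is(pulse, "LightPulse"))
  if (trace@provenance != "corrected")
    stop("relativeLightResponse expects a corrected trace (got ",
         trace@provenance, ")")
  on <- pulse@onset; dur <- pulse@duration
  darkStart <- on - dur
  if (!is.null(protocol)) {
    for (p in protocol@pulses) {
      if (identical(p@onset, on)) next
      pOff <- p@onset + p@duration
      if (p@onset < on && pOff > darkStart)
        stop("windowing error: dark window collides with an earlier pulse")
    }
  }
  y <- trace@ci + 1  # rebaseline
  aucLight <- .windowAUC(trace@times, y, on, on + dur)
  aucDark <- .windowAUC(trace@times, y, darkStart, on)
  degenerate <- aucDark <= 0
  data.frame(well = trace@wellId,
             ratio = if (degenerate) NA_real_ else aucLight / aucDark,
             pulse_onset = on, dark_start = darkStart, light_start = on,
             light_end = on + dur, degenerate = degenerate)
}

#' Spectral response as percent of the white reference (%AUC)
#'
#' Expresses a well's color-light response as a percentage of its own
#' preceding white-light response, using the baseline-excess convention:
#' \deqn{\%AUC = 100 (r_{color} - 1) / (r_{white} - 1)}
#' so that a non-responding well scores ~0%, not ~100%. The white response
#' must exceed baseline by more than `tol`, otherwise the well is
#' uninformative.
#'
#' @param whiteStat,colorStat one-row data.frames from
#'   [relativeLightResponse()] for the same well, white pulse first.
#' @param tol minimal white baseline excess (ratio - 1) for the well to be
#'   informative.
#' @return one-row data.frame: `well`, `percent_auc`.
#' @export
spectralPercentAUC <- function(whiteStat, colorStat, tol = 1e-3) {
  if (!identical(whiteStat$well, colorStat$well))
    stop("white and color responses must come from the same well")
  if (whiteStat$pulse_onset >= colorStat$pulse_onset)
    stop("the white pulse must precede the color pulse")
  if (isTRUE(whiteStat$degenerate) || isTRUE(colorStat$degenerate))
    stop("degenerate response statistic")
  wx <- whiteStat$ratio - 1
  if (wx <= tol)
    stop("uninformative-well error: white response at baseline in well ",
         whiteStat$well)
  data.frame(well = whiteStat$well,
             percent_auc = 100 * (colorStat$ratio - 1) / wx)
}

#' Kinetics summary of a corrected response
#'
#' Locates the response peak within the light window extended by
#' `probeDt` seconds past light-off (first maximum on ties), and reports
#' the time to peak, the peak amplitude, the fraction of the peak lost by
#' the probe time \eqn{(peak - value(offset + probeDt)) / peak} (clamped to
#' \[0, 1\]), and a log-linear estimate of the post-peak decay rate.
#' Non-responding wells (peak <= 0) are flagged, not raised as errors.
#'
#' @param trace a corrected [ImpedanceTrace-class] covering
#'   `[onset, offset + probeDt]`.
#' @param pulse the [LightPulse-class].
#' @param probeDt decay probe offset after light-off, s (default 300).
#' @return one-row data.frame: `well`, `time_to_peak` (s from onset),
#'   `peak`, `decay_fraction`, `decay_rate` (s^-1, NA when not estimable),
#'   `no_response`.
#' @export
kineticsSummary <- function(trace, pulse, probeDt = 300) {
  stopifnot(is(trace, "ImpedanceTrace"), is(pulse, "LightPulse"),
            probeDt > 0)
  if (trace@provenance != "corrected")
    stop("kineticsSummary expects a corrected trace (got ",
         trace@provenance, ")")
  on <- pulse@onset; off <- on + pulse@duration
  probeT <- off + probeDt
  if (on < trace@times[1L] - 1e-9 ||
      probeT > trace@times[length(trace@times)] + 1e-9)
    stop("windowing error: trace does not cover [onset, offset + probeDt]")
  win <- trace@times >= on & trace@times < probeT
  tw <- trace@times[win]; yw <- trace@ci[win]
  iPeak <- which.max(yw)  # first maximum on ties
  peak <- yw[iPeak]
  if (peak <= 0)
    return(data.frame(well = trace@wellId, time_to_peak = NA_real_,
                      peak = NA_real_, decay_fraction = NA_real_,
                      decay_rate = NA_real_, no_response = TRUE))
  probeVal <- stats::approx(trace@times, trace@ci, probeT)$y
  decayFrac <- min(1, max(0, (peak - probeVal) / peak))
  post <- tw > tw[iPeak] & yw > 0 & tw >= off
  rate <- NA_real_
  if (sum(post) >= 3) {
    fit <- stats::lm.fit(cbind(1, tw[post]), log(yw[post]))
    rate <- -fit$coefficients[2L]
  }
  data.frame(well = trace@wellId, time_to_peak = tw[iPeak] - on,
             peak = peak, decay_fraction = decayFrac,
             decay_rate = unname(rate), no_response = FALSE)
}

#' Compare light-response ratios between two groups
#'
#' Two-sided Mann-Whitney test of two groups of relative light responses
#' (e.g. wild-type versus Schiff-base-mutant wells), with the star
#' convention of [significanceStars()].
#'
#' @param statsA,statsB numeric vectors of AUC ratios.
#' @return list with `test` (a [TestResult-class]) and `stars`.
#' @export
compareGroups <- function(statsA, statsB) {
  if (!length(statsA) || !length(statsB)) stop("empty group")
  res <- mannWhitneyU(statsA, statsB)
  list(test = res, stars = significanceStars(res@p))
}

#' Run the full impedance quantification pipeline on a plate
#'
#' Normalizes to the last pre-light sample, baseline-corrects against the
#' plate's control wells, and computes the AUC light-response ratio and
#' kinetics summary for every well and every quantifiable pulse. With a
#' multi-pulse spectral protocol (white pulse first), the %AUC of each
#' later pulse relative to the white pulse is reported as well. Wells that
#' fail a degeneracy guard are excluded from the tables and listed in
#' `excluded`, never dropped silently.
#'
#' @param plate a raw [PlateExperiment-class].
#' @param probeDt kinetics decay probe offset, s.
#' @return list with `responses`, `kinetics`, `spectral` (NULL for
#'   single-pulse protocols), and `excluded` (data.frame well/reason).
#' @export
analyzeImpedancePlate <- function(plate, probeDt = 300) {
  stopifnot(is(plate, "PlateExperiment"))
  proto <- protocol(plate)
  norm <- normalizeCI(plate)
  corr <- baselineCorrect(norm)
  ann <- annotations(plate)
  tmax <- max(traceTimes(plate))
  responses <- kinetics <- list()
  excluded <- data.frame(well = character(), reason = character())
  for (w in ann$well) {
    tr <- getTrace(corr, w)
    for (k in seq_along(proto@pulses)) {
      p <- proto@pulses[[k]]
      if (p@onset - p@duration >= 0) {
        st <- tryCatch(relativeLightResponse(tr, p, proto),
                       error = function(e) NULL)
        if (!is.null(st)) {
          if (st$degenerate) {
            excluded <- rbind(excluded,
                              data.frame(well = w, reason = "dark AUC <= 0"))
          } else {
            st$pulse <- k
            responses[[length(responses) + 1L]] <- st
          }
        }
      }
      if (p@onset + p@duration + probeDt <= tmax + 1e-9) {
        ks <- kineticsSummary(tr, p, probeDt)
        ks$pulse <- k
        kinetics[[length(kinetics) + 1L]] <- ks
      }
    }
  }
  responses <- if (length(responses)) do.call(rbind, responses) else NULL
  kinetics <- if (length(kinetics)) do.call(rbind, kinetics) else NULL
  spectral <- NULL
  if (!is.null(responses) && length(proto@pulses) >= 2L) {
    sp <- list()
    for (w in unique(responses$well)) {
      rw <- responses[responses$well == w, ]
      white <- rw[rw$pulse == 1L, ]
      for (k in setdiff(unique(rw$pulse), 1L)) {
        col <- rw[rw$pulse == k, ]
        if (nrow(white) == 1L && nrow(col) == 1L) {
          pa <- tryCatch(spectralPercentAUC(white, col),
                         error = function(e) NULL)
          if (is.null(pa)) {
            excluded <- rbind(excluded,
                              data.frame(well = w,
                                         reason = "white response at baseline"))
          } else {
            pa$pulse <- k
            sp[[length(sp) + 1L]] <- pa
          }
        }
      }
    }
    spectral <- if (length(sp)) do.call(rbind, sp) else NULL
  }
  addAnn <- function(df) {
    if (is.null(df)) return(NULL)
    cbind(df, ann[match(df$well, ann$well), c("construct", "role")],
          row.names = NULL)
  }
  list(responses = addAnn(responses), kinetics = addAnn(kinetics),
       spectral = addAnn(spectral), excluded = unique(excluded))
}
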