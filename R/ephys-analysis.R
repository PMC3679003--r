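# Patch-clamp quantification: windowed delta-Vm, responsiveness classifier,
# cohort paired test.

#' Windowed membrane-potential deltas around a light pulse
#'
#' The response magnitude of a recording is summarized by three deltas,
#' each the mean membrane potential over a 1-min window minus the reference
#' value taken at the last sample immediately before light onset (time 0):
#' the last dark minute before the pulse (t = -1), the light minute
#' (t = +1), and the first dark minute after light cessation (t = +2).
#' Windows are closed-open: `[a, b)` includes samples with a <= t < b.
#'
#' @param rec an [EphysRecording-class] spanning at least
#'   `[onset - window, offset + window]`; the pulse must be at least one
#'   window long.
#' @param window window length in seconds (default 60).
#' @return one-row data.frame: `cell_id`, `v_ref`, `delta_m1`, `delta_p1`,
#'   `delta_p2` (mV).
#' @examples
#' coh <- simulateEphysCohort(1, 0, seed = 1)
#' windowedDeltas(coh$recordings[[1]])
#' @export
windowedDeltas <- function(rec, window = 60) {
  stopifnot(is(rec, "EphysRecording"))
  pulse <- rec@protocol@pulses[[1L]]
  onset <- pulse@onset; offset <- onset + pulse@duration
  if (pulse@duration < window)
    stop("pulse shorter than the analysis window")
  t <- rec@times
  if (onset - window < t[1L] - 1e-9 ||
      offset + window > t[length(t)] + 1e-9)
    stop("insufficient pre/post coverage for the analysis windows")
  pre <- which(t < onset)
  if (!length(pre)) stop("no sample before light onset")
  vRef <- rec@vm[max(pre)]
  winMean <- function(a, b) mean(rec@vm[t >= a - 1e-9 & t < b - 1e-9])
  data.frame(cell_id = rec@cellId, v_ref = vRef,
             delta_m1 = winMean(onset - window, onset) - vRef,
             delta_p1 = winMean(onset, onset + window) - vRef,
             delta_p2 = winMean(offset, offset + window) - vRef)
}

#' Classify a cell as light-responsive
#'
#' A cell is called responsive when its light-window delta reaches the
#' threshold while its dark-window delta stays below it:
#' `|delta(+1)| >= threshold` and `|delta(-1)| < threshold`. The 10 mV
#' default operationalizes the empirical dark-stability bound (dark-only
#' deltas never approach 10 mV); it is a configuration value, not a claim
#' that the bound is a law.
#'
#' @param wd one-row data.frame from [windowedDeltas()] (or any list with
#'   `delta_m1` and `delta_p1`).
#' @param threshold classification threshold in mV (default 10).
#' @return `"responsive"` or `"non_responsive"`.
#' @export
classifyResponsive <- function(wd, threshold = 10) {
  if (abs(wd$delta_p1) >= threshold && abs(wd$delta_m1) < threshold)
    "responsive" else "non_responsive"
}

#' Analyze a cohort of recordings
#'
#' Computes the windowed deltas and the responsiveness label for every
#' cell, and tests the cohort-level difference between the dark (-1) and
#' light (+1) windows with the paired Student's t test.
#'
#' @param recs list of [EphysRecording-class] (>= 2 cells).
#' @param threshold classification threshold in mV.
#' @param window window length in seconds.
#' @return a [CohortResult-class].
#' @examples
#' coh <- simulateEphysCohort(6, 2, seed = 1)
#' cohortAnalysis(coh$recordings)
#' @export
cohortAnalysis <- function(recs, threshold = 10, window = 60) {
  if (length(recs) < 2L) stop("need at least 2 cells for the paired test")
  deltas <- do.call(rbind, lapply(recs, windowedDeltas, window = window))
  deltas$label <- vapply(seq_len(nrow(deltas)), function(i)
    classifyResponsive(deltas[i, ], threshold), character(1))
  test <- pairedT(deltas$delta_p1, deltas$delta_m1)
  new("CohortResult", deltas = deltas,
      nResponsive = sum(deltas$label == "responsive"),
      nNonResponsive = sum(deltas$label == "non_responsive"),
      test = test, threshold = threshold)
}
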