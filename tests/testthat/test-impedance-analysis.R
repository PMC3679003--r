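# Normalization, baseline correction, AUC ratio, %AUC, kinetics, groups.

test_that("normalization divides by the last pre-onset sample", {
  tr <- ImpedanceTrace("w", c(0, 15, 30), c(1, 2, 4))
  expect_equal(ciValues(normalizeCI(tr, onset = 20)), c(0.5, 1, 2))
  # constant trace -> all ones
  tr <- ImpedanceTrace("w", c(0, 15, 30), c(2, 2, 2))
  expect_equal(ciValues(normalizeCI(tr, onset = 16)), c(1, 1, 1))
  # guards
  expect_error(normalizeCI(ImpedanceTrace("w", c(0, 15), c(0, 1)),
                           onset = 10), "degenerate-well")
  expect_error(normalizeCI(ImpedanceTrace("w", c(10, 25), c(1, 1)),
                           onset = 5), "no-reference")
})

test_that("baseline correction subtracts the mean control trace", {
  t <- seq(0, 45, 15)
  x <- ImpedanceTrace("w", t, rep(1, 4), provenance = "normalized")
  # a control corrected against itself alone is identically zero
  expect_equal(ciValues(baselineCorrect(x, list(x))), rep(0, 4))
  # mean of two controls bracketing the test trace -> zeros
  c1 <- ImpedanceTrace("c1", t, rep(0.9, 4), provenance = "normalized")
  c2 <- ImpedanceTrace("c2", t, rep(1.1, 4), provenance = "normalized")
  expect_equal(ciValues(baselineCorrect(x, list(c1, c2))), rep(0, 4))
  # guards
  bad <- ImpedanceTrace("c", t + 1, rep(1, 4), provenance = "normalized")
  expect_error(baselineCorrect(x, list(bad)), "grid mismatch")
  expect_error(baselineCorrect(x, list()), "empty control")
})

test_that("AUC ratio matches the closed form on a triangular response", {
  # triangle peaking at 0.5 over exactly the 600-s light window, zero in
  # the dark window: ratio = (600 + 150) / 600 = 1.25
  t <- seq(0, 1320, 15)
  v <- triangleValues(t, 720, 1320, 0.5)
  st <- relativeLightResponse(correctedTrace(v), lightPulse(720, 600))
  expect_equal(st$ratio, 1.25, tolerance = 1e-12)
  # flat-zero corrected trace -> exactly 1 (no light response)
  st <- relativeLightResponse(correctedTrace(numeric(89)),
                              lightPulse(720, 600))
  expect_equal(st$ratio, 1.0, tolerance = 1e-12)
})

test_that("trapezoid AUC equals closed forms on piecewise-linear traces", {
  t <- seq(0, 600, 15)
  # linear ramp 0 -> 1 over [0, 600]: integral over [150, 450] = 0.5*300
  ramp <- t / 600
  expect_equal(OpsinAssays:::.windowAUC(t, ramp, 150, 450),
               0.5 * 300, tolerance = 1e-12)
  # window boundaries between samples are linearly interpolated
  expect_equal(OpsinAssays:::.windowAUC(t, ramp, 100, 200),
               (100 / 600 + 200 / 600) / 2 * 100, tolerance = 1e-12)
  expect_error(OpsinAssays:::.windowAUC(t, ramp, -10, 50), "cover")
})

test_that("AUC-ratio guards catch window collisions and degenerate wells", {
  proto <- stimulusProtocol(lightPulse(200, 300), lightPulse(700, 300))
  t <- seq(0, 1200, 15)
  tr <- correctedTrace(numeric(length(t)))
  # dark window [400, 700) collides with the first pulse (ends 500)
  expect_error(relativeLightResponse(tr, pulses(proto)[[2]], proto),
               "windowing error")
  # dark AUC <= 0 -> degenerate flag
  st <- relativeLightResponse(correctedTrace(rep(-1.5, length(t))),
                              lightPulse(600, 300))
  expect_true(st$degenerate)
})

test_that("%AUC uses the baseline-excess convention", {
  mk <- function(ratio, onset) data.frame(well = "w", ratio = ratio,
                                          pulse_onset = onset,
                                          degenerate = FALSE)
  expect_equal(spectralPercentAUC(mk(1.4, 100), mk(1.4, 5000))$percent_auc,
               100)
  expect_equal(spectralPercentAUC(mk(1.4, 100), mk(1.2, 5000))$percent_auc,
               50)
  # a non-responder scores ~0%, not ~100%
  expect_equal(spectralPercentAUC(mk(1.4, 100), mk(1.0, 5000))$percent_auc,
               0)
  expect_error(spectralPercentAUC(mk(1.0005, 100), mk(1.2, 5000)),
               "uninformative-well")
  expect_error(spectralPercentAUC(mk(1.4, 5000), mk(1.2, 100)),
               "precede")
})

test_that("kinetics summary locates peaks and recovers decay rates", {
  # triangle peaking mid-window
  t <- seq(0, 1800, 15)
  v <- triangleValues(t, 720, 1320, 0.4)
  ks <- kineticsSummary(correctedTrace(v), lightPulse(720, 600))
  expect_equal(ks$time_to_peak, 300)
  expect_equal(ks$peak, 0.4)
  # pure exponential tail after the peak: fitted rate within 2%
  beta <- 0.007
  v2 <- numeric(length(t))
  rise <- t >= 720 & t <= 1020
  v2[rise] <- 0.4 * (t[rise] - 720) / 300
  tail <- t > 1020
  v2[tail] <- 0.4 * exp(-beta * (t[tail] - 1020))
  ks2 <- kineticsSummary(correctedTrace(v2), lightPulse(720, 600))
  expect_equal(ks2$decay_rate, beta, tolerance = 0.02)
  # ties resolve to the earliest time
  v3 <- numeric(length(t)); v3[t >= 750 & t <= 900] <- 1
  ks3 <- kineticsSummary(correctedTrace(v3), lightPulse(720, 600))
  expect_equal(ks3$time_to_peak, 30)
  # peak <= 0 -> flagged summary, not an exception
  ks4 <- kineticsSummary(correctedTrace(rep(-0.1, length(t))),
                         lightPulse(720, 600))
  expect_true(ks4$no_response)
  expect_true(is.na(ks4$time_to_peak))
})

test_that("group comparison matches exhaustive rank enumeration", {
  res <- compareGroups(c(1.0, 1.1, 1.2), c(1.5, 1.6, 1.7))
  oracle <- bruteForceMW(c(1.0, 1.1, 1.2), c(1.5, 1.6, 1.7))
  expect_equal(res$test@statistic, oracle$u)
  expect_equal(res$test@p, oracle$p, tolerance = 1e-12)
  # identical groups -> p well above any significance level
  resEq <- compareGroups(c(1, 1.1, 1.2, 1.3), c(1, 1.1, 1.2, 1.3))
  expect_gt(resEq$test@p, 0.9)
})

test_that("the pipeline is invariant to a common positive gain", {
  layout <- data.frame(well = c("A1", "A2", "B1"),
                       class = c("rho_like", "mutant_null",
                                 "non_opsin_control"))
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(), seed = 13)
  res1 <- analyzeImpedancePlate(pe)
  scaled <- pe
  SummarizedExperiment::assay(scaled, "ci") <-
    SummarizedExperiment::assay(pe, "ci") * 7.3
  res2 <- analyzeImpedancePlate(scaled)
  expect_equal(res2$responses$ratio, res1$responses$ratio,
               tolerance = 1e-12)
  expect_equal(res2$kinetics$peak, res1$kinetics$peak, tolerance = 1e-12)
})

test_that("plate-level analysis reports spectral %AUC for two-pulse runs", {
  layout <- data.frame(well = c("A1", "B1"),
                       class = c("tmt_slow", "non_opsin_control"))
  pe <- simulateImpedancePlate(layout, wavelengthProtocol("blue"),
                               quietImpedanceParams(), seed = 1)
  res <- analyzeImpedancePlate(pe)
  sp <- res$spectral[res$spectral$well == "A1", ]
  expect_equal(nrow(sp), 1)
  expect_gt(sp$percent_auc, 0)
  expect_lt(sp$percent_auc, 100)  # color flux is far below white
})
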