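# The two-state impedance simulator: shape, conservation, determinism.

test_that("mutant wells without noise follow the pure drift baseline", {
  layout <- data.frame(well = c("A1", "B1"),
                       class = c("mutant_null", "non_opsin_control"))
  params <- impedanceGenParams(noiseSd = 0, gainSd = 0, driftPerHour = 0.02)
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(), params,
                               seed = 1)
  t <- traceTimes(pe)
  expected <- params$C0 * (1 + 0.02 * t / 3600)
  expect_equal(ciValues(getTrace(pe, "A1")), expected, tolerance = 1e-12)
  expect_equal(ciValues(getTrace(pe, "B1")), expected, tolerance = 1e-12)
})

test_that("noiseless reference response peaks inside the light window and
           decays at beta after light-off", {
  layout <- data.frame(well = c("A1", "B1"),
                       class = c("rho_like", "non_opsin_control"))
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(720, 600),
                               quietImpedanceParams(), seed = 1)
  corr <- baselineCorrect(normalizeCI(pe))
  tr <- getTrace(corr, "A1")
  t <- traceTimes(tr); y <- ciValues(tr)
  iPeak <- which.max(y)
  expect_gt(t[iPeak], 720)          # unique interior maximum in the window
  expect_lt(t[iPeak], 1320)
  expect_equal(sum(abs(y - max(y)) < 1e-12), 1)
  post <- t > 1320
  # post-offset: R' = -beta R exactly, so log-decay rate is beta = 0.010
  fit <- lm(log(y[post]) ~ t[post])
  expect_equal(unname(-coef(fit)[2]), 0.010, tolerance = 1e-6)
})

test_that("state fractions respect conservation along trajectories", {
  # 0 <= R, D, R+D <= 1 for any non-negative rates
  proto <- defaultPlateProtocol(300, 900)
  set.seed(33)
  for (i in 1:5) {
    pg <- pigmentModel("p", "rho_like",
                       alpha = runif(1, 0, 0.05), beta = runif(1, 0, 0.05),
                       delta = runif(1, 0, 0.02), rho = runif(1, 0, 0.01))
    R <- OpsinAssays:::.pigmentTrajectory(pg, proto, seq(0, 1800, 15), 1)
    expect_true(all(R >= -1e-12 & R <= 1 + 1e-12))
  }
})

test_that("without desensitization R converges to alpha*E/(alpha*E+beta)", {
  pg <- pigmentModel("p", "rho_like", delta = 0)
  proto <- defaultPlateProtocol(60, 7200)  # long saturating pulse, E = 1
  times <- seq(0, 7300, 15)
  R <- OpsinAssays:::.pigmentTrajectory(pg, proto, times, 1)
  limit <- pg@alpha / (pg@alpha + pg@beta)
  expect_equal(R[max(which(times < 7260))], limit, tolerance = 1e-6)
})

test_that("fast-class deactivation outruns slow-class deactivation", {
  pigs <- defaultPigments()
  expect_gt(pigs$tmt_fast@beta, pigs$tmt_slow@beta)
  layout <- data.frame(well = c("F1", "S1", "B1"),
                       class = c("tmt_fast", "tmt_slow",
                                 "non_opsin_control"))
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(720, 600),
                               quietImpedanceParams(), seed = 1)
  corr <- baselineCorrect(normalizeCI(pe))
  pulse <- pulses(protocol(pe))[[1]]
  kF <- kineticsSummary(getTrace(corr, "F1"), pulse)
  kS <- kineticsSummary(getTrace(corr, "S1"), pulse)
  expect_gt(kF$decay_fraction, kS$decay_fraction)
})

test_that("shared drift is removed by baseline correction at the noise scale", {
  layout <- data.frame(well = c(sprintf("C%d", 1:3), "X1"),
                       class = c(rep("non_opsin_control", 3), "mutant_null"),
                       role = c(rep("baseline_control", 3), "test"))
  params <- impedanceGenParams(driftPerHour = 0.05)
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(), params,
                               seed = 21)
  corr <- baselineCorrect(normalizeCI(pe))
  for (w in layout$well) {
    resid <- ciValues(getTrace(corr, w))
    expect_lt(max(abs(resid)), 3 * params$noiseSd)
  }
})

test_that("HEK-style dip produces the onset drop-then-recovery shape", {
  pigs <- defaultPigments()
  pigs$mutant_null@dip <- 0.15
  layout <- data.frame(well = c("H1", "B1"),
                       class = c("mutant_null", "non_opsin_control"))
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(720, 600),
                               quietImpedanceParams(pigments = pigs),
                               seed = 1)
  corr <- baselineCorrect(normalizeCI(pe))
  y <- ciValues(getTrace(corr, "H1")); t <- traceTimes(corr)
  justAfter <- y[t == 720]
  expect_lt(justAfter, -0.1)            # abrupt drop right after onset
  expect_gt(y[t == 1320], justAfter)    # followed by recovery
})
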