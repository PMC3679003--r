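# Readers, writers, provenance sidecars, and validity guards.

test_that("plate experiments round-trip through CSV within 1e-12", {
  layout <- data.frame(well = c("A1", "A2", "B1"),
                       class = c("rho_like", "mutant_null",
                                 "non_opsin_control"))
  pe <- simulateImpedancePlate(layout, defaultPlateProtocol(), seed = 11)
  dir <- withr::local_tempdir()
  writePlateExperiment(pe, dir)
  pe2 <- readPlateExperiment(dir)
  expect_equal(SummarizedExperiment::assay(pe2, "ci"),
               SummarizedExperiment::assay(pe, "ci"), tolerance = 1e-12)
  expect_equal(traceTimes(pe2), traceTimes(pe))
  expect_equal(annotations(pe2), annotations(pe))
  expect_equal(provenance(pe2), "raw")
  p1 <- pulses(protocol(pe))[[1]]; p2 <- pulses(protocol(pe2))[[1]]
  expect_equal(p2@onset, p1@onset)
  expect_equal(p2@flux, p1@flux)
})

test_that("trace-table reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  ann <- data.frame(well = "A1", construct = "x", role = "test")
  proto <- defaultPlateProtocol()

  # missing column
  write.csv(data.frame(well = "A1", t = 0:2, ci = 1), file.path(dir, "traces.csv"),
            row.names = FALSE)
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  jsonlite::write_json(list(protocol = list(), provenance = "raw"),
                       file.path(dir, "protocol.json"), auto_unbox = TRUE)
  expect_error(readPlateExperiment(dir), "format error")

  # non-uniform grid beyond tolerance (15-s dialect)
  write.csv(data.frame(well = "A1", time_s = c(0, 15, 31), ci = c(1, 1, 1)),
            file.path(dir, "traces.csv"), row.names = FALSE)
  expect_error(readPlateExperiment(dir), "grid error")

  # a well absent from the annotation table
  write.csv(data.frame(well = rep(c("A1", "A2"), each = 3),
                       time_s = rep(c(0, 15, 30), 2), ci = 1),
            file.path(dir, "traces.csv"), row.names = FALSE)
  expect_error(readPlateExperiment(dir), "annotation error")

  # unknown role
  write.csv(data.frame(well = c("A1", "A2"),
                       construct = "x", role = c("test", "mystery")),
            file.path(dir, "annotations.csv"), row.names = FALSE)
  expect_error(readPlateExperiment(dir), "annotation error")
})

test_that("well roles and provenance transitions are validated", {
  expect_error(PlateExperiment(
    matrix(1, 3, 1, dimnames = list(NULL, "A1")), c(0, 15, 30),
    data.frame(well = "A1", construct = "x", role = "bogus"),
    defaultPlateProtocol()), "unknown role")
  tr <- ImpedanceTrace("w", c(0, 15, 30), c(1, 1, 1),
                       provenance = "normalized")
  expect_error(normalizeCI(tr, onset = 20), "expects a raw trace")
  expect_error(kineticsSummary(tr, lightPulse(15, 15)), "corrected")
  expect_error(ImpedanceTrace("w", c(0, 15, 29), c(1, 1, 1)),
               "uniformly spaced")
  expect_error(ImpedanceTrace("w", c(0, 15, 30), c(1, NA, 1)), "finite")
})

test_that("ephys cohorts round-trip with truth labels", {
  coh <- simulateEphysCohort(3, 1, params = ephysGenParams(sampleRate = 50),
                             seed = 5)
  dir <- withr::local_tempdir()
  writeEphysCohort(coh, dir, seed = 5)
  coh2 <- readEphysCohort(dir)
  expect_length(coh2$recordings, 3)
  expect_equal(coh2$truth$responsive, coh$truth$responsive)
  expect_equal(vmValues(coh2$recordings[[2]]), vmValues(coh$recordings[[2]]),
               tolerance = 1e-12)
  expect_equal(coh2$recordings[[1]]@sampleRate, 50)
})

test_that("result writer emits tidy CSV plus a seed-stamped JSON sidecar", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "out.csv")

  # empty result set -> header-only CSV
  writeResults(data.frame(well = character(), ratio = numeric()), path,
               seed = 7)
  expect_equal(nrow(read.csv(path)), 0)
  expect_equal(names(read.csv(path)), c("well", "ratio"))

  # one record -> one row; sidecar echoes seed and config hash
  writeResults(data.frame(well = "A1", ratio = 1.25), path,
               config = defaultRunConfig(seed = 7), seed = 7)
  got <- read.csv(path)
  expect_equal(got$ratio, 1.25, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 7)
  expect_match(side$config_hash, "^[0-9a-f]{8}$")
  expect_equal(side$config$analysis$threshold_mv, 10)
})

test_that("run configuration reads YAML overlays onto defaults", {
  cfg0 <- defaultRunConfig()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 42", "analysis:", "  threshold_mv: 8"), path)
  cfg <- readRunConfig(path)
  expect_equal(cfg$seed, 42)
  expect_equal(cfg$analysis$threshold_mv, 8)
  expect_equal(cfg$analysis$window_s, cfg0$analysis$window_s)
  writeLines(c("analysis:", "  threshold_mv: -1"), path)
  expect_error(readRunConfig(path), "invalid config")
})

test_that("same seed reproduces generator output bit-identically", {
  layout <- data.frame(well = c("A1", "B1"),
                       class = c("tmt_fast", "non_opsin_control"))
  p1 <- simulateImpedancePlate(layout, defaultPlateProtocol(), seed = 9)
  p2 <- simulateImpedancePlate(layout, defaultPlateProtocol(), seed = 9)
  expect_identical(SummarizedExperiment::assay(p1, "ci"),
                   SummarizedExperiment::assay(p2, "ci"))
  c1 <- simulateEphysCohort(2, 1, params = ephysGenParams(sampleRate = 100),
                            seed = 4)
  c2 <- simulateEphysCohort(2, 1, params = ephysGenParams(sampleRate = 100),
                            seed = 4)
  expect_identical(vmValues(c1$recordings[[1]]), vmValues(c2$recordings[[1]]))
  expect_identical(c1$truth, c2$truth)
})
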