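# Readers and writers: tidy long-format CSV trace tables, cohort CSVs,
# result tables with JSON provenance sidecars.

# deterministic polynomial hash of a serialized object, as a short hex
# string; used to stamp outputs with the configuration that produced them.
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.protocolToList <- function(proto) {
  lapply(proto@pulses, function(p) {
    sp <- p@spectrum
    list(onset_s = p@onset, duration_s = p@duration, flux = p@flux,
         spectrum = list(kind = sp@kind, lambda_min = sp@lambdaMin,
                         lambda_max = sp@lambdaMax,
                         lambda_peak = sp@lambdaPeak,
                         bandwidth = sp@bandwidth))
  })
}

.protocolFromList <- function(x) {
  pulses <- lapply(x, function(p) {
    sp <- p$spectrum
    spec <- switch(sp$kind,
      flat_band = flatBandSpectrum(sp$lambda_min, sp$lambda_max),
      gaussian_band = gaussianBandSpectrum(sp$lambda_peak, sp$bandwidth),
      monochromatic = monochromaticSpectrum(sp$lambda_peak),
      stop("unknown spectrum kind: ", sp$kind))
    lightPulse(p$onset_s, p$duration_s, spec, p$flux)
  })
  stimulusProtocol(pulses)
}

#' Write / read a plate experiment as tidy CSV tables
#'
#' `writePlateExperiment()` writes three plain-text files into `dir`:
#' `traces.csv` (long format: `well`, `time_s`, `ci`), `annotations.csv`
#' (`well`, `construct`, `role`) and `protocol.json` (pulse list plus
#' provenance and, when present, the generating seed).
#' `readPlateExperiment()` reads them back, validating the shared uniform
#' time grid, the annotation coverage, and the well roles. Values
#' round-trip within 1e-12.
#'
#' @param plate a [PlateExperiment-class].
#' @param dir directory (created if needed).
#' @return `writePlateExperiment()` the directory, invisibly;
#'   `readPlateExperiment()` a [PlateExperiment-class].
#' @export
writePlateExperiment <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(plate, "ci")
  times <- traceTimes(plate)
  long <- data.frame(
    well = rep(colnames(m), each = nrow(m)),
    time_s = rep(times, times = ncol(m)),
    ci = as.vector(m))
  utils::write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(annotations(plate), file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  md <- S4Vectors::metadata(plate)
  jsonlite::write_json(
    list(protocol = .protocolToList(protocol(plate)),
         provenance = provenance(plate),
         seed = md$seed),
    file.path(dir, "protocol.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname writePlateExperiment
#' @param gridRtol relative tolerance for the uniform-grid check.
#' @export
readPlateExperiment <- function(dir, gridRtol = 1e-6) {
  long <- utils::read.csv(file.path(dir, "traces.csv"))
  need <- c("well", "time_s", "ci")
  if (!all(need %in% names(long)))
    stop("format error: traces.csv must have columns ",
         paste(need, collapse = ", "))
  ann <- utils::read.csv(file.path(dir, "annotations.csv"))
  if (!all(c("well", "construct", "role") %in% names(ann)))
    stop("format error: annotations.csv must have columns well, construct, role")
  bad <- setdiff(unique(ann$role), .WELL_ROLES)
  if (length(bad))
    stop("annotation error: unknown role(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(unique(long$well), ann$well)
  if (length(missing))
    stop("annotation error: wells without annotation: ",
         paste(missing, collapse = ", "))
  long <- long[order(match(long$well, unique(long$well)), long$time_s), ]
  wells <- unique(long$well)
  times <- sort(unique(long$time_s))
  if (length(times) < 2L || !.uniformSpacing(times, gridRtol))
    stop("grid error: time grid not uniform within tolerance")
  counts <- table(long$well)
  if (length(unique(counts)) != 1L ||
      counts[1L] != length(times))
    stop("grid error: traces do not share one time grid")
  m <- matrix(long$ci, nrow = length(times), ncol = length(wells),
              dimnames = list(NULL, wells))
  meta <- jsonlite::read_json(file.path(dir, "protocol.json"))
  PlateExperiment(m, times, ann, .protocolFromList(meta$protocol),
                  provenance = meta$provenance,
                  metadata = if (!is.null(meta$seed))
                    list(seed = meta$seed) else list())
}

#' Write / read a recording cohort as CSV tables
#'
#' `writeEphysCohort()` writes `recordings.csv` (long format: `cell_id`,
#' `time_s`, `vm_mv`), `truth_labels.csv` when truth labels accompany a
#' synthetic cohort, and `protocol.json` (pulse, sample rate, seed).
#'
#' @param cohort list with `recordings` (list of [EphysRecording-class])
#'   and optional `truth`, as returned by [simulateEphysCohort()].
#' @param dir directory.
#' @param seed optional generating seed echoed into the sidecar.
#' @return the directory (write) or a cohort list (read), invisibly for
#'   write.
#' @export
writeEphysCohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- cohort$recordings
  long <- do.call(rbind, lapply(recs, function(r)
    data.frame(cell_id = r@cellId, time_s = r@times, vm_mv = r@vm)))
  utils::write.csv(long, file.path(dir, "recordings.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth_labels.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(protocol = .protocolToList(recs[[1L]]@protocol),
         sample_rate = recs[[1L]]@sampleRate, seed = seed),
    file.path(dir, "protocol.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname writeEphysCohort
#' @export
readEphysCohort <- function(dir) {
  long <- utils::read.csv(file.path(dir, "recordings.csv"))
  if (!all(c("cell_id", "time_s", "vm_mv") %in% names(long)))
    stop("format error: recordings.csv must have cell_id, time_s, vm_mv")
  meta <- jsonlite::read_json(file.path(dir, "protocol.json"))
  proto <- .protocolFromList(meta$protocol)
  recs <- lapply(split(long, factor(long$cell_id,
                                    levels = unique(long$cell_id))),
                 function(d) {
    d <- d[order(d$time_s), ]
    EphysRecording(d$cell_id[1L], d$time_s, d$vm_mv, proto,
                   meta$sample_rate)
  })
  names(recs) <- NULL
  truthPath <- file.path(dir, "truth_labels.csv")
  truth <- if (file.exists(truthPath)) utils::read.csv(truthPath) else NULL
  list(recordings = recs, truth = truth)
}

#' Write a result table with a provenance sidecar
#'
#' Writes any flat result data.frame as tidy CSV plus a JSON sidecar
#' (`<path>.json`) echoing the run configuration, the seed, and a
#' deterministic hash of both, so every output names the run that produced
#' it. An empty result set yields a header-only CSV.
#'
#' @param results data.frame of flat records.
#' @param path output CSV path.
#' @param config run configuration list (default [defaultRunConfig()]).
#' @param seed seed used for the run, or NULL for deterministic pipelines.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path, config = defaultRunConfig(),
                         seed = NULL) {
  stopifnot(is.data.frame(results))
  utils::write.csv(results, path, row.names = FALSE)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  config <- strip(config)
  jsonlite::write_json(
    list(seed = seed, config = config,
         config_hash = .configHash(list(config = config, seed = seed)),
         package_version = as.character(utils::packageVersion("OpsinAssays"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
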