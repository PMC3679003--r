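# Run configuration: one central place for every tunable default, with a
# YAML reader that overlays user values onto the defaults.

#' Default run configuration
#'
#' All analysis and generator defaults in one nested list, the same
#' structure accepted as YAML by [readRunConfig()]. Blocks:
#' `analysis` (window length, classification threshold, kinetics probe
#' offset, normalization onset handling), `impedance_generator` and
#' `ephys_generator` (see [impedanceGenParams()], [ephysGenParams()]),
#' `stimulus` (default fluxes), and `io` (CSV dialect).
#'
#' @param seed integer seed recorded with the run; mandatory for any
#'   stochastic operation.
#' @return nested list of class `RunConfig`.
#' @export
defaultRunConfig <- function(seed = NULL) {
  ig <- impedanceGenParams()
  eg <- ephysGenParams()
  structure(list(
    seed = seed,
    analysis = list(window_s = 60, threshold_mv = 10, probe_dt_s = 300,
                    grid_rtol = 1e-6),
    impedance_generator = ig[setdiff(names(ig), "pigments")],
    ephys_generator = unclass(eg),
    stimulus = list(fluxes = as.list(defaultFluxes())),
    io = list(format = "csv")
  ), class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the corresponding defaults;
#' everything else keeps its default. Thresholds must be positive.
#'
#' @param path YAML file.
#' @return nested list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge2(cfg, user)
  if (cfg$analysis$threshold_mv <= 0 || cfg$analysis$window_s <= 0 ||
      cfg$analysis$probe_dt_s <= 0)
    stop("invalid config: thresholds and windows must be positive")
  class(cfg) <- "RunConfig"
  cfg
}
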