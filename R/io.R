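#' Read and write spike rasters as TSV
#'
#' Event-list TSV with columns `time_ms`, `neuron_id`, `population_id`
#' (sorted by time) and `#`-prefixed metadata header lines carrying the run
#' geometry, so rasters produced elsewhere can be fed to the analysis layer.
#'
#' @param raster a [spikeRaster()]
#' @param path file path
#' @return `readRaster` returns a [spikeRaster()]; `writeRaster` returns
#'   `path` invisibly
#' @export
writeRaster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration_ms=%g", attr(raster, "duration")),
               sprintf("# dt_ms=%g", attr(raster, "dt")),
               sprintf("# n_neurons=%s",
                       paste(attr(raster, "nNeurons"), collapse = ","))), con)
  write.table(as.data.frame(raster), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key, default = NA) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spikeRaster(df$time_ms, df$neuron_id, df$population_id,
              duration = as.numeric(meta("duration_ms",
                                         max(df$time_ms, 0) + 1)),
              dt = as.numeric(meta("dt_ms", 0.01)),
              nNeurons = as.integer(strsplit(
                meta("n_neurons", as.character(max(df$neuron_id, 1))),
                ",")[[1]]))
}

#' Write a rate series or curve as TSV with metadata header
#'
#' @param x a `rate_series`, `dmi_curve`, `prc_curve` or plain data frame
#' @param path file path
#' @param meta named list of metadata values written as `# key=value` lines
#' @return `path`, invisibly
#' @export
writeSeries <- function(x, path, meta = list()) {
  if (inherits(x, "rate_series")) {
    meta <- c(list(kernel_sigma_ms = x$kernelSigma, dt_ms = x$dt), meta)
    x <- data.frame(t_ms = x$t, rate = x$r)
  }
  if (inherits(x, "dmi_curve"))
    meta <- c(list(n_bins = attr(x, "nBins"), dt_ms = attr(x, "dt")), meta)
  if (inherits(x, "prc_curve"))
    meta <- c(list(pulse_amplitude = attr(x, "amplitude"),
                   pulse_width_ms = attr(x, "width")), meta)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' The file mirrors the spec constructors: top-level keys `population1`,
#' `population2`, `coupling`, `signal`, each holding the corresponding
#' constructor arguments (see [populationSpec()], [couplingSpec()],
#' [signalSpec()]).  Missing keys fall back to the defaults.
#'
#' @param path YAML file path
#' @return list with `pop1`, `pop2` (or NULL), `coupling` (or NULL),
#'   `signal` (or NULL)
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N` key as boolean FALSE; restore the one
  # single-letter field the constructors use
  cfg <- lapply(cfg, function(block) {
    if (is.list(block) && any(names(block) == "FALSE"))
      names(block)[names(block) == "FALSE"] <- "N"
    block
  })
  build <- function(key, fun) {
    if (is.null(cfg[[key]])) return(NULL)
    do.call(fun, cfg[[key]])
  }
  list(pop1 = if (is.null(cfg$population1)) populationSpec()
              else do.call(populationSpec, cfg$population1),
       pop2 = build("population2", populationSpec),
       coupling = build("coupling", couplingSpec),
       signal = build("signal", signalSpec))
}
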