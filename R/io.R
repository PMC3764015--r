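# Run configuration loading/validation and report writing.

.known_cfg_keys <- c("preset", "overrides", "protocol", "hypothesis",
                     "lesioned", "chi_scale", "days", "seed", "dt",
                     "burn_in_days", "record_stride_s", "wake_threshold",
                     "spectral_band_h", "activity_window_mode", "out_dir")

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration naming a preset (plus optional flat
#' parameter overrides), a protocol (`"nu_sweep"`, `"relay_modes"`,
#' `"degu_switch"`, `"scn_lesion"`, or `"ld"`/`"dd"`/`"ll"`), integrator
#' settings, and analysis options. Unknown keys and out-of-range values fail
#' loudly; defaults are filled and recorded.
#'
#' @param path YAML file path.
#' @return object of class `run_config` (validated named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), .known_cfg_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(list(
    preset = "human_nominal", overrides = list(), protocol = "ld",
    hypothesis = "both", lesioned = FALSE, chi_scale = 1,
    days = 30, seed = 1L, dt = 1, burn_in_days = 14, record_stride_s = 30,
    wake_threshold = NULL, spectral_band_h = c(2, 30),
    activity_window_mode = "non-overlapping", out_dir = "."
  ), y)
  stopifnot(cfg$days >= 1, cfg$dt > 0, cfg$chi_scale > 0)
  pre <- load_preset(cfg$preset)  # errors on unknown preset
  params <- apply_overrides(pre$params, cfg$overrides)  # range-validated
  if (!is.null(cfg$wake_threshold)) {
    params <- apply_overrides(params,
                              list(wake_threshold = cfg$wake_threshold))
  }
  cfg$params <- params
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' Inverse of [load_config()]: a written configuration reads back equal
#' (ignoring the derived `params` entry).
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  y <- unclass(cfg)
  y$params <- NULL
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Write an experiment report directory
#'
#' Writes `metrics.json`, CSV artifacts (traces, spectra, bout tables,
#' rasters, profiles as present in the report), and a `manifest.json`
#' listing every written file with its MD5 checksum and the full provenance
#' record. The layout is deterministic: writing the same report twice yields
#' identical checksums.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(obj, name) {
    path <- file.path(dir, name)
    if (is.data.frame(obj) || is.matrix(obj)) {
      write.csv(as.data.frame(obj), path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    written <<- c(written, name)
  }
  put(report$metrics, "metrics.json")
  if (!is.null(report$sim)) put(report$sim$trace, "trace.csv")
  if (!is.null(report$bouts)) put(as.data.frame(report$bouts), "bouts.csv")
  if (!is.null(report$spectrum)) put(report$spectrum, "spectrum.csv")
  if (!is.null(report$wake_profile)) put(report$wake_profile,
                                         "wake_profile.csv")
  if (!is.null(report$raster)) {
    put(unclass(report$raster) * 1L, "raster.csv")
  }
  manifest <- list(
    id = report$id,
    provenance = report$provenance,
    files = lapply(setNames(written, written), function(f) {
      list(md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}
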