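#' Run configuration
#'
#' Collects everything a pipeline run needs: the master seed, the preset
#' table (bundled by default, so every field is resolvable without any
#' external file), imaging settings, record duration and quantifier
#' defaults. Configurations round-trip through YAML via [write_config()] /
#' [read_config()].
#'
#' @param master_seed integer master seed; per-cilium and per-stage streams
#'   are derived from it with [derive_seed()].
#' @param preset_table_path optional path to a preset table file; `NULL`
#'   uses the bundled table.
#' @param imaging an [imaging_config] (or a named list of its fields).
#' @param record_duration record duration, s (default 2).
#' @param min_prominence,min_separation,velocity_fraction quantifier
#'   defaults, see [detect_beats()] and [segment_strokes()].
#' @param warmup warm-up discarded before each record, s.
#' @param out_dir output directory for pipeline products.
#' @return A validated `run_config` object.
#' @export
run_config <- function(master_seed = 1, preset_table_path = NULL,
                       imaging = imaging_config(), record_duration = 2,
                       min_prominence = 0.2, min_separation = 20,
                       velocity_fraction = 0.1, warmup = 1,
                       out_dir = ".") {
  if (is.list(imaging) && !inherits(imaging, "imaging_config"))
    imaging <- do.call(imaging_config, imaging)
  cfg <- structure(
    list(master_seed = master_seed, preset_table_path = preset_table_path,
         imaging = imaging, record_duration = record_duration,
         min_prominence = min_prominence, min_separation = min_separation,
         velocity_fraction = velocity_fraction, warmup = warmup,
         out_dir = out_dir),
    class = "run_config")
  validate_config(cfg)
}

config_fields <- c("master_seed", "preset_table_path", "imaging",
                   "record_duration", "min_prominence", "min_separation",
                   "velocity_fraction", "warmup", "out_dir")

#' Validate a run configuration
#'
#' Type- and range-checks every field and rejects unknown keys, reporting
#' all problems at once in a human-readable list rather than stopping at
#' the first.
#'
#' @param cfg a `run_config` or a named list of its fields.
#' @return The validated `run_config` (invisibly usable), with the resolved
#'   frame count attached as attribute `n_frames`.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  unknown <- setdiff(names(cfg), config_fields)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  chk(is.numeric(cfg$master_seed) && length(cfg$master_seed) == 1 &&
        cfg$master_seed == round(cfg$master_seed),
      "master_seed: must be a single integer")
  chk(is.null(cfg$preset_table_path) ||
        (is.character(cfg$preset_table_path) &&
           file.exists(cfg$preset_table_path)),
      "preset_table_path: file does not exist")
  img_ok <- tryCatch({
    if (!inherits(cfg$imaging, "imaging_config"))
      do.call(imaging_config, cfg$imaging)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(img_ok)) errs <- c(errs, paste0("imaging: ", img_ok))
  chk(is.numeric(cfg$record_duration) && cfg$record_duration > 0,
      "record_duration: must be > 0 (s)")
  chk(is.numeric(cfg$min_prominence) && cfg$min_prominence > 0,
      "min_prominence: must be > 0 (um)")
  chk(is.numeric(cfg$min_separation) && cfg$min_separation >= 0,
      "min_separation: must be >= 0 (ms)")
  chk(is.numeric(cfg$velocity_fraction) && cfg$velocity_fraction > 0 &&
        cfg$velocity_fraction < 1,
      "velocity_fraction: must be in (0, 1)")
  chk(is.numeric(cfg$warmup) && cfg$warmup >= 0, "warmup: must be >= 0 (s)")
  chk(is.character(cfg$out_dir) && length(cfg$out_dir) == 1,
      "out_dir: must be a single path")
  if (length(errs))
    stop("invalid run configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  if (!inherits(cfg, "run_config")) class(cfg) <- "run_config"
  attr(cfg, "n_frames") <- round(cfg$record_duration * cfg$imaging$fps)
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "Run config: seed %d, %g s records (%d frames), presets: %s\n",
    x$master_seed, x$record_duration, attr(x, "n_frames"),
    if (is.null(x$preset_table_path)) "bundled" else x$preset_table_path))
  cat(sprintf(
    "  quantifier: prominence %g um, separation %g ms, velocity fraction %g\n",
    x$min_prominence, x$min_separation, x$velocity_fraction))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' The fully resolved configuration (including imaging fields) is written;
#' reading and re-validating reproduces an identical configuration.
#'
#' @param cfg a `run_config`.
#' @param path output `.yaml` path.
#' @return `path` invisibly; `read_config()` returns a validated
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- unclass(cfg)
  lst$imaging <- unclass(lst$imaging)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)
  unknown <- setdiff(names(lst), config_fields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lst$imaging <- do.call(imaging_config, lst$imaging)
  cfg <- structure(lst, class = "run_config")
  validate_config(cfg)
}
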