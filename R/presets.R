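#' Condition presets
#'
#' A `condition_preset` bundles the kinematic parameters of one experimental
#' condition (a pH value, an ATP concentration, or a non-beating null
#' condition) with its planned cohort size. A default table encoding the pH
#' series (7.0-8.0), the ATP dose series, single-cilium representative
#' conditions and null conditions is shipped with the package; see
#' [preset_table()].
#'
#' @name condition_preset
NULL

required_preset_fields <- c("label", "mode", "t_eff", "t_rec",
                            "interval_mean", "amplitude", "n_cilia")
known_preset_fields <- c(required_preset_fields, "interval_sigma_log",
                         "target_cbf", "fluct_sd", "fluct_tau", "group",
                         "reference")

as_condition_preset <- function(rec, where = "") {
  miss <- setdiff(required_preset_fields, names(rec))
  if (length(miss))
    stop(sprintf("preset%s: missing required field(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(rec), known_preset_fields)
  if (length(unknown))
    stop(sprintf("preset%s: unknown field(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!rec$mode %in% c("rate_matched", "component_matched"))
    stop(sprintf("preset%s: unknown mode string '%s'", where, rec$mode),
         call. = FALSE)
  if (!is.numeric(rec$n_cilia) || rec$n_cilia < 1)
    stop(sprintf("preset%s: n_cilia must be >= 1", where), call. = FALSE)
  params <- beat_params(
    t_eff = rec$t_eff, t_rec = rec$t_rec,
    interval_mean = rec$interval_mean,
    interval_sigma_log = if (is.null(rec$interval_sigma_log)) 0.45
                         else rec$interval_sigma_log,
    amplitude = rec$amplitude, mode = rec$mode,
    target_cbf = rec$target_cbf,
    fluct_sd = if (is.null(rec$fluct_sd)) 0 else rec$fluct_sd,
    fluct_tau = if (is.null(rec$fluct_tau)) 300 else rec$fluct_tau)
  structure(list(label = rec$label, params = params,
                 n_cilia = as.integer(rec$n_cilia),
                 group = if (is.null(rec$group)) "other" else rec$group,
                 reference = isTRUE(rec$reference)),
            class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("Condition preset '%s' (group %s, n_cilia %d%s)\n", x$label,
              x$group, x$n_cilia, if (x$reference) ", reference" else ""))
  print(x$params)
  invisible(x)
}

#' Load a table of condition presets from a YAML or JSON file
#'
#' The file holds one record per condition with fields `label`, `mode`
#' (`rate_matched` or `component_matched`), `t_eff`, `t_rec`,
#' `interval_mean` (ms), `amplitude` (um), `n_cilia`, and optionally
#' `interval_sigma_log`, `target_cbf` (Hz), `fluct_sd`, `fluct_tau`,
#' `group`, `reference`. Every record is validated; labels must be unique.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list of [condition_preset] objects (class
#'   `preset_table`).
#' @seealso [preset_table()] for the bundled default table.
#' @export
load_preset_table <- function(path) {
  if (!file.exists(path))
    stop("preset table file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  recs <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("preset table must be .json, .yaml or .yml, got: .", ext,
         call. = FALSE))
  if (!is.list(recs) || length(recs) == 0)
    stop("preset table is empty: ", path, call. = FALSE)
  presets <- lapply(seq_along(recs), function(i)
    as_condition_preset(recs[[i]], where = sprintf(" #%d", i)))
  labels <- vapply(presets, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate preset labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  names(presets) <- labels
  class(presets) <- "preset_table"
  presets
}

#' @export
print.preset_table <- function(x, ...) {
  cat(sprintf("Preset table: %d conditions\n", length(x)))
  for (p in x)
    cat(sprintf("  %-14s group=%-14s n=%-3d amplitude=%.2f um%s\n",
                p$label, p$group, p$n_cilia, p$params$amplitude,
                if (!is.null(p$params$target_cbf))
                  sprintf(" target_cbf=%.2f Hz", p$params$target_cbf)
                else ""))
  invisible(x)
}

#' The bundled condition preset table
#'
#' Encodes the pH series 7.0-8.0 (beat-frequency targets 3.4-15.4 Hz,
#' amplitudes 0.57-1.45 um, effective strokes 136-37 ms, recovery stroke
#' 38 ms, rest-interval means 234-31 ms), the ATP dose series
#' (0.5-10 mM, sparse-beat regime), the Fig.-style representative
#' single-cilium conditions, and non-beating null conditions (unstimulated,
#' ATPgS, PKI-pretreated) with baseline fluctuation only.
#'
#' @return A `preset_table` (named list of [condition_preset]s).
#' @examples
#' tab <- preset_table()
#' tab[["pH8.0"]]$params$interval_mean
#' @export
preset_table <- function() {
  path <- system.file("extdata", "presets.json", package = "ciliabeat",
                      mustWork = TRUE)
  load_preset_table(path)
}

#' Fetch one preset, optionally switching its matching mode
#'
#' @param label preset label, e.g. `"pH7.0"`.
#' @param mode optional override: `"rate_matched"` (printed beat-frequency
#'   targets are hit exactly; used for CBF/CBD/ratio recovery) or
#'   `"component_matched"` (printed stroke durations and interval means are
#'   used verbatim; used for duration/interval recovery).
#' @param table a `preset_table`; the bundled table by default.
#' @return A [condition_preset].
#' @export
get_preset <- function(label, mode = NULL, table = preset_table()) {
  if (!label %in% names(table))
    stop("unknown preset label: ", label, call. = FALSE)
  p <- table[[label]]
  if (!is.null(mode) && mode != p$params$mode) {
    pr <- p$params
    if (mode == "rate_matched" && is.null(pr$target_cbf))
      stop("preset '", label, "' has no target_cbf; cannot rate-match",
           call. = FALSE)
    tgt <- pr$target_cbf
    if (is.null(tgt) && mode == "rate_matched")
      stop("preset '", label, "' has no target_cbf", call. = FALSE)
    p$params <- beat_params(
      t_eff = pr$t_eff, t_rec = pr$t_rec, interval_mean = pr$interval_mean,
      interval_sigma_log = pr$interval_sigma_log, amplitude = pr$amplitude,
      mode = mode, target_cbf = if (mode == "rate_matched") tgt else NULL,
      fluct_sd = pr$fluct_sd, fluct_tau = pr$fluct_tau)
  }
  p
}
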