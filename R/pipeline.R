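# End-to-end pipeline: generate -> calibrate -> limit -> project -> report,
# fully determined by one declarative config and one seed.

#' Build a pipeline run configuration
#'
#' All defaults together define a complete, reproducible run; the resolved
#' config is embedded in the run summary, and re-running that embedded config
#' reproduces the summary bit for bit.
#'
#' @param synthetic Named list of overrides for [synthetic_config()] (the
#'   `seed` there is always taken from `seed` below).
#' @param culture_table_path Optional CSV path; when given, effect parameters
#'   are calibrated from it via [calibrate_effects()] instead of taking the
#'   defaults/overrides in `effects`.
#' @param effects Named list of overrides for [effect_params()].
#' @param h0,h1,oa Calibration anchors / external P-replete decline used when
#'   calibrating from a culture table.
#' @param p_limitation Named list of overrides for [p_limitation_params()].
#' @param mask_mode `"argmin"`, `"threshold"`, `"all"` (every ocean cell
#'   treated as P-limited) or `"none"`.
#' @param mask_threshold Threshold for `"threshold"` mode.
#' @param scenarios Character vector from `c("oa_only", "oa_plus_p")`; may be
#'   empty, in which case only the reference integral is reported.
#' @param era Era to project (default `"2081-2100"`).
#' @param out_dir Optional output directory; when given, intermediate fields,
#'   the summary (JSON + text) and a log are written there.
#' @param seed Integer seed for every random draw in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = list(), culture_table_path = NULL,
                       effects = list(), h0 = 10^-8.01, h1 = 10^-7.81,
                       oa = -0.184, p_limitation = list(),
                       mask_mode = c("argmin", "threshold", "all", "none"),
                       mask_threshold = 0.5,
                       scenarios = c("oa_only", "oa_plus_p"),
                       era = "2081-2100", out_dir = NULL, seed = 1L) {
  mask_mode <- match.arg(mask_mode)
  bad <- setdiff(scenarios, c("oa_only", "oa_plus_p"))
  if (length(bad))
    abort_config(sprintf("unknown scenario(s): %s", paste(bad, collapse = ", ")))
  structure(list(synthetic = synthetic,
                 culture_table_path = culture_table_path,
                 effects = effects, h0 = h0, h1 = h1, oa = oa,
                 p_limitation = p_limitation, mask_mode = mask_mode,
                 mask_threshold = mask_threshold,
                 scenarios = scenarios, era = era, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]. `overrides` entries
#' of the form `"key=value"` (dotted keys reach nested lists, e.g.
#' `synthetic.ph_spread=0`) are applied after reading.
#'
#' @param path YAML file path.
#' @param overrides Character vector of `key=value` strings.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = character()) {
  if (!file.exists(path)) abort_io(sprintf("file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort_format("config file must hold a YAML mapping")
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort_config(sprintf("bad override '%s'", ov))
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    raw[[keys]] <- val
  }
  do.call(run_config, raw)
}

#' Run the full projection pipeline
#'
#' Stages, in order: generate the synthetic ocean state for the configured
#' era; calibrate (or take) the effect parameters; compute P limitation
#' factors and the P-limited mask; project each scenario; assemble the run
#' summary. Every random draw is governed by `config$seed`, so a (config,
#' seed) pair fully determines every output. When `config$out_dir` is set,
#' the state, mask, per-scenario fields, summary (JSON and text) and a
#' stage-level log are written there.
#'
#' @param config A [run_config()] (or a list of arguments for one, e.g. the
#'   `config` embedded in a previous run's summary).
#' @return A `run_summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  log_lines <- character()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %-9s %s",
                                       format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                       stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, trichoproj_error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class(e)[1])
    })
  }

  # generate
  state <- stage("generate", {
    syn <- config$synthetic; syn$seed <- config$seed
    generate_ocean_state(do.call(synthetic_config, syn), config$era)
  })
  note("generate", sprintf("era %s state on %d x %d grid", config$era,
                           length(state$grid$lat_centers),
                           length(state$grid$lon_centers)))

  # calibrate
  params <- stage("calibrate", {
    if (!is.null(config$culture_table_path)) {
      calibrate_effects(read_culture_table(config$culture_table_path),
                        h0 = config$h0, h1 = config$h1, oa = config$oa)
    } else {
      do.call(effect_params, config$effects)
    }
  })
  note("calibrate", sprintf("oa=%.4f oap_c=%.4f oap_n=%.4f",
                            params$oa, params$oap_c, params$oap_n))

  # limit
  ocean <- state$grid$ocean_mask
  mask <- stage("limit", {
    lim <- do.call(p_limitation_params, config$p_limitation)
    v <- p_limitation_factors(state$po4, state$dop, lim)
    switch(config$mask_mode,
           argmin = p_limited_mask(v$v_p, state$aux_limits, mode = "argmin"),
           threshold = p_limited_mask(v$v_p, mode = "threshold",
                                      threshold = config$mask_threshold),
           all = ifelse(ocean, TRUE, NA),
           none = ifelse(ocean, FALSE, NA))
  })
  frac_p <- sum(mask[ocean], na.rm = TRUE) / sum(ocean)
  note("limit", sprintf("mode %s: %.1f%% of ocean cells P-limited",
                        config$mask_mode, 100 * frac_p))

  # project
  projections <- stats::setNames(lapply(config$scenarios, function(sc)
    stage("project", project_nf(state, params, p_mask = mask, scenario = sc))),
    config$scenarios)
  for (sc in names(projections))
    note("project", sprintf("%s: delta %.3f Tg N yr-1", sc,
                            projections[[sc]]$global_delta))

  reference_tg <- global_integral(
    field_values(state$nf) * field_values(state$r_tr), state$grid)

  summary_obj <- structure(list(
    era = config$era,
    global_reference = reference_tg,
    scenarios = lapply(projections, function(p)
      list(reference = p$global_reference, projected = p$global_projected,
           delta = p$global_delta,
           percent_delta = 100 * p$global_delta / p$global_reference)),
    params = unclass(params),
    mask_stats = list(mode = config$mask_mode, fraction_p_limited = frac_p),
    seed = config$seed,
    version = as.character(utils::packageVersion("trichoproj")),
    config = unclass(strip_out_dir(config))),
    class = "run_summary")

  if (!is.null(config$out_dir)) {
    stage("report", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_state(state, file.path(config$out_dir, "state.csv"))
      utils::write.csv(ifelse(is.na(mask), NA_integer_, as.integer(mask)),
                       file.path(config$out_dir, "p_limited_mask.csv"),
                       row.names = FALSE)
      write_report(summary_obj, file.path(config$out_dir, "summary.json"))
      note("report", sprintf("outputs written to %s", config$out_dir))
      writeLines(log_lines, file.path(config$out_dir, "run.log"))
    })
  }
  attr(summary_obj, "log") <- log_lines
  attr(summary_obj, "projections") <- projections
  summary_obj
}

# the embedded config must reproduce the summary without touching out_dir
strip_out_dir <- function(config) { config$out_dir <- NULL; config }

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> era %s, seed %d, version %s\n",
              x$era, x$seed, x$version))
  cat(sprintf("  reference: %.3f Tg N yr-1; %s mask: %.1f%% P-limited\n",
              x$global_reference, x$mask_stats$mode,
              100 * x$mask_stats$fraction_p_limited))
  for (sc in names(x$scenarios)) {
    s <- x$scenarios[[sc]]
    cat(sprintf("  %-10s projected %8.3f  delta %8.3f Tg N yr-1 (%.2f%%)\n",
                sc, s$projected, s$delta, s$percent_delta))
  }
  invisible(x)
}

#' Write a run summary as JSON plus a text table
#'
#' Numeric fields are serialized at no less than 15 significant digits so
#' values round-trip through [read_report()] to well beyond reporting
#' precision; a human-readable table is written next to the JSON with
#' extension `.txt`.
#'
#' @param summary A `run_summary`.
#' @param path JSON output path.
#' @return Invisibly `path`.
#' @export
write_report <- function(summary, path) {
  ok <- tryCatch({
    jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write report to '%s'", path))

  txt <- c(sprintf("Trichodesmium N2 fixation projection (era %s, seed %d)",
                   summary$era, summary$seed),
           sprintf("reference integral: %.6f Tg N yr-1", summary$global_reference),
           sprintf("%-12s %12s %12s %12s", "scenario", "projected", "delta", "%"),
           vapply(names(summary$scenarios), function(sc) {
             s <- summary$scenarios[[sc]]
             sprintf("%-12s %12.6f %12.6f %12.4f", sc, s$projected, s$delta,
                     s$percent_delta)
           }, character(1)))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

#' Read back a JSON run summary
#' @param path Path written by [write_report()].
#' @return A `run_summary`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file '%s' does not exist", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$seed <- as.integer(x$seed)
  structure(x, class = "run_summary")
}
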