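# allowed configuration schema for run_pipeline(); unknown keys are
# rejected before any stage runs
.pipeline_schema <- list(
  seed = NULL,
  out_dir = NULL,
  log_level = NULL,
  simulate = c("enabled", "frequencies", "noise_sd"),
  analyze = c("enabled", "span", "degree", "harmonics", "smooth",
              "refine_frequency", "trace_files"),
  lvdt = c("enabled", "part"))

validate_config <- function(config) {
  unknown <- setdiff(names(config), names(.pipeline_schema))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    allowed <- .pipeline_schema[[k]]
    if (is.null(allowed)) next
    if (!is.list(config[[k]]))
      stopf("configuration block '%s' must be a mapping", k)
    bad <- setdiff(names(config[[k]]), allowed)
    if (length(bad))
      stopf("unknown key(s) in '%s': %s", k, paste(bad, collapse = ", "))
  }
  invisible(config)
}

pipe_log <- function(level, config_level, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, verbose = 2L)
  if (levels[[config_level %||% "info"]] >= levels[[level]])
    message(sprintf(fmt, ...))
}

#' Run the simulate-analyze-fit pipeline
#'
#' End-to-end driver: generates (or reads) oscillating-drop traces,
#' analyses them into a modulus table and a harmonic-ratio table, fits the
#' Lucassen-van den Tempel model per concentration, and writes all results
#' plus a JSON run manifest (package version, seeds, parameters) into
#' `out_dir`. Reruns with an identical configuration and seed produce
#' byte-identical numeric outputs.
#'
#' @param config configuration as a named list or path to a YAML file.
#'   Top-level keys: `seed`, `out_dir`, `log_level` (`quiet`/`info`/
#'   `verbose`), and blocks `simulate` (`enabled`, `frequencies`,
#'   `noise_sd`), `analyze` (`enabled`, `span`, `degree`, `harmonics`,
#'   `smooth`, `refine_frequency`, `trace_files`), `lvdt` (`enabled`,
#'   `part`). Unknown keys are rejected before any stage runs.
#' @param out_dir overrides `config$out_dir`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    stopf("an output directory is required (config key 'out_dir')")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  lvl <- config$log_level %||% "info"
  manifest <- list(
    package = "droprheo",
    version = as.character(packageVersion("droprheo")),
    seed = seed, config = config, stages = list(), seeds_used = list(),
    partial = FALSE)

  trace_files <- config$analyze$trace_files
  if (isTRUE(config$simulate$enabled %||% TRUE)) {
    pipe_log("info", lvl, "simulate: writing reference condition suite")
    sim_dir <- file.path(out_dir, "traces")
    trace_files <- generate_condition_suite(
      sim_dir,
      frequencies = as.numeric(config$simulate$frequencies %||% c(0.01, 0.1)),
      noise_sd = config$simulate$noise_sd %||% 0.1,
      seed = seed)
    manifest$stages$simulate <- list(n_files = length(trace_files))
    manifest$seeds_used$simulate <- seed + seq_along(trace_files)
  }

  if (isTRUE(config$analyze$enabled %||% TRUE)) {
    if (is.null(trace_files))
      stopf("analyze stage needs simulated traces or analyze$trace_files")
    pipe_log("info", lvl, "analyze: %d trace(s)", length(trace_files))
    traces <- lapply(trace_files, read_trace_csv)
    tab <- analyze_traces(
      traces,
      span = config$analyze$span %||% 0.3,
      degree = config$analyze$degree %||% 2L,
      n_harmonics = config$analyze$harmonics %||% 4L,
      smooth = config$analyze$smooth %||% TRUE,
      refine_frequency = config$analyze$refine_frequency %||% TRUE)
    write_modulus_csv(tab, file.path(out_dir, "modulus.csv"))
    ratio <- tab[, c("concentration_mM", "frequency_hz", "harmonic_ratio",
                     "quality_flag")]
    rows <- paste(fmt_num(ratio$concentration_mM), fmt_num(ratio$frequency_hz),
                  fmt_num(ratio$harmonic_ratio), ratio$quality_flag,
                  sep = ",")
    writeLines(c("concentration_mM,frequency_hz,harmonic_ratio,quality_flag",
                 rows), file.path(out_dir, "harmonic_ratios.csv"),
               useBytes = TRUE)
    manifest$stages$analyze <- list(n_traces = length(traces),
                                    out = c("modulus.csv",
                                            "harmonic_ratios.csv"))
  } else tab <- NULL

  if (isTRUE(config$lvdt$enabled %||% TRUE)) {
    if (is.null(tab)) {
      manifest$partial <- TRUE
      pipe_log("info", lvl, "lvdt: skipped (no modulus table)")
    } else {
      concs <- sort(unique(tab$concentration_mM))
      fits <- list()
      for (cc in concs) {
        sub <- tab[tab$concentration_mM == cc & tab$quality_flag == "ok", ]
        if (length(unique(sub$frequency_hz)) < 3L) next
        sp <- data.frame(frequency = sub$frequency_hz,
                         eps_real = sub$eps_real_mN_m,
                         eps_imag = sub$eps_imag_mN_m)
        ft <- fit_lvdt(sp, part = config$lvdt$part %||% "real")
        fits[[length(fits) + 1L]] <- data.frame(
          concentration_mM = cc,
          eps0_mN_m = coef(ft)[["eps0"]], nuD_hz = coef(ft)[["nu_d"]],
          eps0_sd = ft$se[["eps0"]], nuD_sd = ft$se[["nu_d"]],
          residual_rms = ft$residual_rms, n_points = ft$n_points)
      }
      if (length(fits)) {
        ftab <- do.call(rbind, fits)
        hdr <- paste(names(ftab), collapse = ",")
        rows <- if (nrow(ftab) == 1L) {
          paste(fmt_num(as.numeric(ftab[1L, ])), collapse = ",")
        } else {
          apply(vapply(names(ftab), function(cl)
            fmt_num(as.numeric(ftab[[cl]])), character(nrow(ftab))), 1L,
            paste, collapse = ",")
        }
        writeLines(c(hdr, rows), file.path(out_dir, "lvdt_fits.csv"),
                   useBytes = TRUE)
        manifest$stages$lvdt <- list(n_fits = nrow(ftab),
                                     out = "lvdt_fits.csv")
      } else {
        manifest$partial <- TRUE
        pipe_log("info", lvl, "lvdt: no concentration had >= 3 usable frequencies")
      }
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log("info", lvl, "done: results in %s", out_dir)
  invisible(manifest)
}
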