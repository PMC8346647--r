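## Delimited-text I/O and the end-to-end pipeline driver.
##
## User-facing files carry temperatures in degrees C and energies in
## kJ mol^-1 (instrument/report conventions, with units in the header
## names); everything internal is K and J mol^-1.

.THERMO_COLS <- c("time_s", "temperature_C", "mass_mg", "heat_flow_mW")

#' Write a thermogram to CSV
#'
#' Columns: `time_s`, `temperature_C`, `mass_mg`, `heat_flow_mW`,
#' `replicate_id`.
#'
#' @param tg a [thermogram()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  df <- data.frame(time_s = tg$time,
                   temperature_C = kelvin_to_celsius(tg$temperature),
                   mass_mg = tg$mass, heat_flow_mW = tg$heat_flow,
                   replicate_id = tg$replicate_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a thermogram from CSV
#'
#' Validates the required columns (`time_s`, `temperature_C`, `mass_mg`,
#' `heat_flow_mW`; `replicate_id` optional), the numeric content, and
#' temperature monotonicity (after collapsing duplicates within
#' tolerance). Parse problems report the offending line numbers.
#'
#' @param path CSV file as written by [write_thermogram()].
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) .stopf("cannot parse %s: %s", path,
                                            conditionMessage(e)))
  if (nrow(df) == 0) .stopf("empty thermogram file: %s", path)
  missing <- setdiff(.THERMO_COLS, names(df))
  if (length(missing) > 0)
    .stopf("%s: missing required column(s): %s", path,
           paste(missing, collapse = ", "))
  for (col in .THERMO_COLS) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (any(is.na(v)))
      .stopf("%s: non-numeric or missing values in column %s (data line%s %s)",
             path, col, if (length(bad) == 1) "" else "s",
             paste(utils::head(which(is.na(v)), 5) + 1, collapse = ", "))
    df[[col]] <- v
  }
  tk <- celsius_to_kelvin(df$temperature_C)
  dec <- which(diff(tk) < -1e-9)
  if (length(dec) > 0)
    .stopf("%s: temperature not non-decreasing (first violation at data line %d)",
           path, dec[1] + 2)
  thermogram(df$time_s, tk, df$mass_mg, df$heat_flow_mW,
             replicate_id = if ("replicate_id" %in% names(df))
               df$replicate_id[1] else "r1")
}

#' Write a rate curve (with optional per-component columns) to CSV
#'
#' @param curve a [rate_curve()]; if it carries a `"components"` attribute
#'   (from [mixture_rate()]), per-component columns `component_<i>_perK`
#'   are included.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_rate_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rate_curve"))
  df <- data.frame(temperature_C = kelvin_to_celsius(curve$temperature),
                   dx_dT_perK = curve$rate)
  comps <- attr(curve, "components")
  for (i in seq_along(comps))
    df[[sprintf("component_%d_perK", i)]] <- comps[[i]]$rate
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rate curve written by [write_rate_curve()]
#'
#' @param path CSV file.
#' @param source provenance tag for the curve.
#' @return A [rate_curve()].
#' @export
read_rate_curve <- function(path, source = "measured") {
  df <- utils::read.csv(path)
  if (!all(c("temperature_C", "dx_dT_perK") %in% names(df)))
    .stopf("%s: expected columns temperature_C, dx_dT_perK", path)
  rate_curve(celsius_to_kelvin(df$temperature_C), df$dx_dT_perK, source)
}

#' Write a fit parameter table to CSV
#'
#' @param fit a `fit_result`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_fit_csv <- function(fit, path) {
  utils::write.csv(fit_parameters(fit), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## small rolling hash over the deparsed config: a reproducibility
## fingerprint stamped into every artifact (not cryptographic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' @param input_paths thermogram CSV paths (replicates of one sample), or
#'   `NULL` when thermogram objects are passed to [run_pipeline()]
#'   directly.
#' @param window_C analysis window, degrees C.
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param n_components component count, or a vector to scan.
#' @param family distribution family, or a vector to scan.
#' @param k0 fixed pre-exponential factor, s^-1.
#' @param beta_C_min heating rate, C min^-1.
#' @param t_start_C furnace start temperature, C.
#' @param suggest also run the DTG/DSC concordance suggestion.
#' @param out_dir artifact directory (`NULL` disables writing).
#' @param seed integer seed (restart jitter).
#' @param max_restarts jittered restarts per fit.
#' @param verbose narrate stages via `message()`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_paths = NULL, window_C = c(200, 600),
                       sg_window = 21, sg_order = 3,
                       n_components = 1, family = "gaussian", k0 = 1.67e13,
                       beta_C_min = 5, t_start_C = 22, suggest = TRUE,
                       out_dir = NULL, seed = 1L, max_restarts = 2,
                       verbose = TRUE) {
  if (window_C[1] >= window_C[2]) .stopf("analysis window must be ordered")
  structure(list(input_paths = input_paths, window_C = window_C,
                 sg_window = sg_window, sg_order = sg_order,
                 n_components = n_components, family = family, k0 = k0,
                 beta_C_min = beta_C_min, t_start_C = t_start_C,
                 suggest = suggest, out_dir = out_dir, seed = as.integer(seed),
                 max_restarts = max_restarts, verbose = verbose),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Read (or accept) replicate thermograms, average them, preprocess to
#' DTG/DSC-derivative curves, optionally suggest a component count from
#' channel concordance, fit the DAEM (scanning counts/families when
#' vectors are supplied), and write artifacts: parameter CSV, fitted and
#' per-component curve CSV, and a key-value report stamped with the
#' config hash and seed.
#'
#' @param config a [run_config()].
#' @param thermograms optional list of [thermogram()]s overriding
#'   `config$input_paths`.
#' @return Invisibly, a list with `preprocessed`, `suggestion`, `fit`
#'   (selected `fit_result`), `scan` (when scanning), and `artifacts`
#'   (written paths).
#' @export
run_pipeline <- function(config, thermograms = NULL) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  stamp <- .config_hash(unclass(config))

  stage <- "ingest"
  result <- tryCatch({
    if (is.null(thermograms)) {
      if (is.null(config$input_paths)) .stopf("no input paths and no thermograms")
      say("[ingest] reading %d thermogram(s)", length(config$input_paths))
      thermograms <- lapply(config$input_paths, read_thermogram)
    }
    stage <- "preprocess"
    say("[preprocess] averaging %d replicate(s), smoothing (window %d, order %d)",
        length(thermograms), config$sg_window, config$sg_order)
    avg <- average_replicates(thermograms)
    window <- celsius_to_kelvin(config$window_C)
    prep <- preprocess_thermogram(avg, window, config$sg_window, config$sg_order)
    ## replicates are fit jointly (concatenated residuals); the averaged
    ## trace serves the concordance heuristics and the report display
    rep_dtg <- lapply(thermograms, function(tg)
      preprocess_thermogram(tg, window, config$sg_window, config$sg_order)$dtg)

    suggestion <- NULL
    if (isTRUE(config$suggest)) {
      stage <- "suggest"
      suggestion <- suggest_component_count(prep$dtg, prep$dsc_derivative)
      say("[suggest] DTG/DSC concordance suggests %d pseudo-component(s)",
          suggestion$n_components)
    }

    stage <- "fit"
    program <- heating_program(c_per_min_to_k_per_s(config$beta_C_min),
                               celsius_to_kelvin(config$t_start_C),
                               max(avg$temperature))
    base_cfg <- fit_config(n_components = config$n_components[1],
                           family = config$family[1], k0 = config$k0,
                           seed = config$seed,
                           max_restarts = config$max_restarts)
    scan <- NULL
    if (length(config$n_components) > 1 || length(config$family) > 1) {
      say("[fit] scanning n in {%s} x family in {%s}",
          paste(config$n_components, collapse = ","),
          paste(config$family, collapse = ","))
      scan <- model_scan(rep_dtg, config$n_components, config$family,
                         base_cfg, program)
      fit <- scan_select(scan)
      say("[fit] selected %s (R^2 = %.4f)", attr(fit, "key"), fit$r_squared)
    } else {
      say("[fit] %d-component %s DAEM, %d replicate curve(s) jointly",
          config$n_components, config$family, length(rep_dtg))
      fit <- fit_daem(rep_dtg, base_cfg, program)
      say("[fit] R^2 = %.4f", fit$r_squared)
    }

    stage <- "report"
    artifacts <- character(0)
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
      pfx <- file.path(config$out_dir, sprintf("daem_%s_seed%d", stamp, config$seed))
      ppath <- paste0(pfx, "_parameters.csv")
      write_fit_csv(fit, ppath)
      sim <- mixture_rate(fit$model, prep$dtg$temperature)
      cpath <- paste0(pfx, "_curves.csv")
      write_rate_curve(sim, cpath)
      plpath <- paste0(pfx, "_fit.png")
      grDevices::png(plpath, width = 900, height = 600)
      plot(fit, data = rep_dtg,
           main = sprintf("%d-component %s DAEM (R^2 = %.4f)",
                          length(fit$model$components),
                          fit_parameters(fit)$family[1], fit$r_squared))
      grDevices::dev.off()
      rpath <- paste0(pfx, "_report.txt")
      rep_lines <- c(
        sprintf("config_hash: %s", stamp),
        sprintf("seed: %d", config$seed),
        sprintf("family: %s", fit_parameters(fit)$family[1]),
        sprintf("n_components: %d", length(fit$model$components)),
        sprintf("r_squared: %.6f", fit$r_squared),
        sprintf("converged: %s", fit$converged),
        sprintf("component_%d_e_mean_kJ_mol: %.4f",
                seq_along(fit$model$components),
                vapply(fit$model$components, function(c) c$dist$e_mean, 1) / 1000),
        sprintf("component_%d_sigma_kJ_mol: %.4f",
                seq_along(fit$model$components),
                vapply(fit$model$components, function(c) c$dist$sigma, 1) / 1000),
        sprintf("component_%d_fraction: %.4f",
                seq_along(fit$model$components),
                vapply(fit$model$components, `[[`, 1, "fraction")))
      if (!is.null(suggestion))
        rep_lines <- c(rep_lines, sprintf("suggested_n_components: %d",
                                          suggestion$n_components))
      writeLines(rep_lines, rpath)
      artifacts <- c(ppath, cpath, rpath, plpath)
      say("[report] wrote %d artifact(s) under %s", length(artifacts),
          config$out_dir)
    }
    list(preprocessed = prep, suggestion = suggestion, fit = fit,
         scan = scan, artifacts = artifacts, config_hash = stamp)
  }, error = function(e) {
    .stopf("pipeline failed at stage [%s]: %s", stage, conditionMessage(e))
  })
  invisible(result)
}
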