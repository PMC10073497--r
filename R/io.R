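#' Path to a packaged example data file
#'
#' The package ships the plate study's published tables as plain-text
#' fixtures: `static_forces.csv` (static failure series),
#' `plate_campaign.csv` (the staircase campaign observations),
#' `load_cases_elastic.csv` (peak stresses from the linear-elastic
#' structural analysis), `load_cases_elastoplastic.csv` (peak stresses from
#' the elasto-plastic rerun), `material_ti64_eli.json` (ASTM F3001-14
#' minima) and `plate_config.yaml` (a full pipeline configuration).
#'
#' @param file File name; omit to list available files.
#' @return Full path, or a vector of file names when `file` is missing.
#' @examples
#' fatiguekit_example()
#' fatiguekit_example("load_cases_elastic.csv")
#' @export
fatiguekit_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "fatiguekit")))
  path <- system.file("extdata", file, package = "fatiguekit")
  if (path == "")
    stop(sprintf("no packaged file '%s'.", file), call. = FALSE)
  path
}

read_checked_csv <- function(path, required, numeric_cols, positive_cols) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  if (nrow(df) == 0)
    stop(sprintf("parse error in %s: no data rows.", path), call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("parse error in %s: missing column(s) %s.", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric value in column '%s', row %d.",
                   path, col, bad[1]), call. = FALSE)
    df[[col]] <- v
  }
  for (col in positive_cols) {
    bad <- which(df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("parse error in %s: non-positive value in column '%s', row %d.",
                   path, col, bad[1]), call. = FALSE)
  }
  df
}

#' Read load cases from CSV
#'
#' Expects the columns `label, force_N, precondition_force_N,
#' peak_stress_MPa, precondition_stress_MPa` (units encoded in the names to
#' prevent unit drift). Parse failures name the offending row and column.
#'
#' @param path CSV file path.
#' @return A list of [load_case()] objects, in file order.
#' @examples
#' cases <- read_load_cases(fatiguekit_example("load_cases_elastic.csv"))
#' length(cases)
#' @export
read_load_cases <- function(path) {
  cols <- c("label", "force_N", "precondition_force_N", "peak_stress_MPa",
            "precondition_stress_MPa")
  df <- read_checked_csv(path, cols, cols[-1],
                         c("force_N", "precondition_force_N"))
  lapply(seq_len(nrow(df)), function(i) {
    load_case(df$label[i], df$force_N[i], df$precondition_force_N[i],
              df$peak_stress_MPa[i], df$precondition_stress_MPa[i])
  })
}

#' Write load cases to CSV
#'
#' @param cases List of [load_case()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_load_cases <- function(cases, path) {
  if (inherits(cases, "load_case")) cases <- list(cases)
  df <- do.call(rbind, lapply(cases, function(cs) data.frame(
    label = cs$label, force_N = cs$force,
    precondition_force_N = cs$precondition_force,
    peak_stress_MPa = cs$peak_stress,
    precondition_stress_MPa = cs$precondition_stress
  )))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fatigue observations from CSV
#'
#' Expects columns `label, force_N, life_cycles, censored` (0/1) and
#' optionally `note`.
#'
#' @param path CSV file path.
#' @return A [fatigue_observations()] data.frame.
#' @export
read_observations <- function(path) {
  df <- read_checked_csv(path, c("label", "force_N", "life_cycles", "censored"),
                         c("force_N", "life_cycles", "censored"),
                         c("force_N", "life_cycles"))
  if (any(!df$censored %in% c(0, 1)))
    stop(sprintf("parse error in %s: 'censored' must be 0 or 1.", path),
         call. = FALSE)
  fatigue_observations(df$force_N, df$life_cycles, df$censored == 1,
                       label = df$label,
                       note = if (is.null(df$note)) "" else df$note)
}

#' Write fatigue observations to CSV
#'
#' @param observations A [fatigue_observations()] data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_observations <- function(observations, path) {
  df <- data.frame(label = observations$label,
                   force_N = observations$force,
                   life_cycles = observations$life,
                   censored = as.integer(observations$censored),
                   note = observations$note)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a staircase campaign record to CSV
#'
#' Columns: `specimen, force_N_reported, force_N_exact, outcome,
#' life_cycles`.
#'
#' @param record A [run_campaign()] record.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_campaign_record <- function(record, path) {
  if (!inherits(record, "campaign_record"))
    stop("`record` must be a campaign_record object.", call. = FALSE)
  sp <- record$specimens
  df <- data.frame(specimen = sp$specimen,
                   force_N_reported = sp$force_reported,
                   force_N_exact = sp$force_exact,
                   outcome = sp$outcome, life_cycles = sp$life)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a material record from JSON or YAML
#'
#' Expects keys `ultimate_strength_MPa`, `yield_strength_MPa`,
#' `elastic_modulus_GPa`, `elongation`, `poisson_ratio`. The modulus is
#' converted from GPa to MPa at this boundary; everything downstream is in
#' MPa.
#'
#' @param path `.json`, `.yaml` or `.yml` file path.
#' @return A [material_spec()].
#' @examples
#' read_material(fatiguekit_example("material_ti64_eli.json"))
#' @export
read_material <- function(path) {
  rec <- read_structured(path)
  need <- c("ultimate_strength_MPa", "yield_strength_MPa",
            "elastic_modulus_GPa", "elongation", "poisson_ratio")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    stop(sprintf("material record %s is missing key(s): %s.", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  material_spec(rec$ultimate_strength_MPa, rec$yield_strength_MPa,
                rec$elastic_modulus_GPa * 1e3, rec$elongation,
                rec$poisson_ratio)
}

read_structured <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop(sprintf("unsupported config format '.%s' (use JSON or YAML).", ext),
            call. = FALSE)
}

#' Read and validate a pipeline configuration
#'
#' A configuration is a YAML or JSON document with blocks:
#' \describe{
#'   \item{material}{path to a material record (see [read_material()]) or
#'     the record inlined.}
#'   \item{sn_curve}{`Cf` (fabrication factor) and `Nc1` (endurance life).}
#'   \item{prediction}{`N_max` (cap), `corrections` (subset of goodman,
#'     gerber), `extrapolate_low_cycle`.}
#'   \item{fit}{`runout_policy` (`as_failure` or `exclude`),
#'     `min_failures`.}
#'   \item{load_cases}{path to a load-case CSV.}
#'   \item{observations}{optional path to an experimental observations CSV.}
#' }
#' Relative paths are resolved against the configuration file's directory.
#' Unknown top-level keys are rejected, and every block is validated by the
#' constructor that owns it before any computation runs.
#'
#' @param path Configuration file path.
#' @return An object of class `"analysis_config"`.
#' @examples
#' cfg <- read_analysis_config(fatiguekit_example("plate_config.yaml"))
#' @export
read_analysis_config <- function(path) {
  raw <- read_structured(path)
  allowed <- c("material", "sn_curve", "prediction", "fit", "load_cases",
               "observations")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s.",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (key in c("material", "sn_curve", "load_cases"))
    if (is.null(raw[[key]]))
      stop(sprintf("configuration is missing required block '%s'.", key),
           call. = FALSE)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  material <- if (is.character(raw$material)) {
    read_material(resolve(raw$material))
  } else {
    do.call(material_spec, list(
      ultimate_strength = raw$material$ultimate_strength_MPa,
      yield_strength = raw$material$yield_strength_MPa,
      elastic_modulus = raw$material$elastic_modulus_GPa * 1e3,
      elongation = raw$material$elongation,
      poisson_ratio = raw$material$poisson_ratio
    ))
  }
  sn <- raw$sn_curve
  curve <- build_sn_curve(material,
                          Cf = if (is.null(sn$Cf)) 1 else sn$Cf,
                          Nc1 = if (is.null(sn$Nc1)) 1e6 else sn$Nc1)
  pred <- raw$prediction
  N_max <- if (is.null(pred$N_max)) 1e5 else pred$N_max
  corrections <- if (is.null(pred$corrections)) c("goodman", "gerber")
                 else match.arg(pred$corrections, c("goodman", "gerber"),
                                several.ok = TRUE)
  extrapolate <- isTRUE(pred$extrapolate_low_cycle)
  fit <- raw$fit
  runout_policy <- if (is.null(fit$runout_policy)) "as_failure"
                   else match.arg(fit$runout_policy,
                                  c("as_failure", "exclude"))
  min_failures <- if (is.null(fit$min_failures)) 3 else fit$min_failures
  structure(
    list(
      material = material, curve = curve, N_max = N_max,
      corrections = corrections, extrapolate_low_cycle = extrapolate,
      runout_policy = runout_policy, min_failures = min_failures,
      load_cases_path = resolve(raw$load_cases),
      observations_path = if (is.null(raw$observations)) NULL
                          else resolve(raw$observations),
      source_path = normalizePath(path)
    ),
    class = "analysis_config"
  )
}

#' Run the full stress-life pipeline from a configuration
#'
#' Orchestrates the end-to-end analysis: read the load cases, predict the
#' capped fatigue life of every case under each configured mean-stress
#' correction, fit Basquin force-life curves to the usable predictions
#' (low-cycle and infeasible cases are excluded; capped lives are treated
#' as runouts under the configured policy), optionally fit the experimental
#' observations, and read off the fatigue limits at `N_max`. Deterministic:
#' the same configuration always yields the same bundle.
#'
#' @param config An [read_analysis_config()] object, or a path to one.
#' @return An object of class `"report_bundle"`: list with `predictions`
#'   (one data.frame per correction), `fits`, `fatigue_limits` (N, per
#'   correction plus `experimental` when observations are configured),
#'   `observations` (or `NULL`) and `provenance` (config hash, package
#'   version).
#' @examples
#' bundle <- run_pipeline(fatiguekit_example("plate_config.yaml"))
#' bundle$fatigue_limits
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (!inherits(config, "analysis_config"))
    stop("`config` must be an analysis_config object or a path.", call. = FALSE)
  cases <- read_load_cases(config$load_cases_path)

  predictions <- list()
  fits <- list()
  limits <- list()
  for (corr in config$corrections) {
    tab <- predict_life_table(cases, config$curve, corr, config$N_max,
                              config$extrapolate_low_cycle)
    predictions[[corr]] <- tab
    usable <- tab[tab$status %in% c("finite", "endurance") &
                    is.finite(tab$reported_life), , drop = FALSE]
    # Predicted lives are model output, not censored measurements: capped
    # values enter the fit at the cap, mirroring the published treatment.
    fit <- tryCatch(
      fit_basquin(
        data.frame(force = usable$force_N, life = usable$reported_life,
                   censored = FALSE),
        runout_policy = "as_failure",
        min_failures = config$min_failures
      ),
      error = function(e) NULL
    )
    fits[[corr]] <- fit
    limits[[corr]] <- if (is.null(fit)) NA_real_
                      else fatigue_limit(fit, config$N_max)
  }

  observations <- NULL
  if (!is.null(config$observations_path)) {
    observations <- read_observations(config$observations_path)
    fit <- fit_basquin(observations, runout_policy = config$runout_policy,
                       min_failures = config$min_failures)
    fits$experimental <- fit
    limits$experimental <- fatigue_limit(fit, config$N_max)
  }

  structure(
    list(
      predictions = predictions,
      fits = fits,
      fatigue_limits = limits,
      observations = observations,
      provenance = list(
        config_hash = unname(tools::md5sum(config$source_path)),
        package_version = as.character(utils::packageVersion("fatiguekit")),
        N_max = config$N_max,
        corrections = config$corrections,
        runout_policy = config$runout_policy
      )
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Fatigue analysis report bundle\n")
  for (corr in names(x$predictions)) {
    cat(sprintf("\n%s predictions:\n", corr))
    print(x$predictions[[corr]][, c("label", "force_N", "sigma_w_MPa",
                                    "status", "reported_life")],
          row.names = FALSE)
  }
  cat("\nFatigue limits at N_max:\n")
  for (nm in names(x$fatigue_limits))
    cat(sprintf("  %-12s %.2f N\n", nm, x$fatigue_limits[[nm]]))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits one prediction CSV per correction plus a JSON summary
#' (fit parameters, fatigue limits, provenance).
#'
#' @param bundle A [run_pipeline()] bundle.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "report_bundle"))
    stop("`bundle` must be a report_bundle object.", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (corr in names(bundle$predictions))
    utils::write.csv(bundle$predictions[[corr]],
                     file.path(dir, sprintf("predictions_%s.csv", corr)),
                     row.names = FALSE, quote = FALSE)
  fit_summaries <- lapply(bundle$fits, function(f) {
    if (is.null(f)) return(NULL)
    list(coefficient = f$coefficient, exponent = f$exponent,
         p_value = f$slope_p_value, r_squared = f$r_squared,
         n_used = f$n_used, runout_policy = f$runout_policy)
  })
  jsonlite::write_json(
    list(fits = fit_summaries, fatigue_limits_N = bundle$fatigue_limits,
         provenance = bundle$provenance),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
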