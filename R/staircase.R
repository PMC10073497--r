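#' Configuration of a modified staircase fatigue campaign
#'
#' Parameters of the modified up-and-down protocol: the campaign starts at
#' `start_fraction` of the mean static failure force; after a failure the
#' next force is the current force times a multiplier chosen by how early
#' the failure occurred (life as a fraction of `N_max`, banded by
#' `band_thresholds`); after a runout the next force bisects (arithmetic
#' mean) between the current force and the lowest failing force observed so
#' far. The campaign stops once `stop_survivals` specimens have survived
#' `N_max` cycles. Forces are carried at full precision internally and only
#' rounded to `report_rounding` for reporting.
#'
#' This banded next-force rule is a reconstruction of a flowchart-defined
#' protocol (the rule is not published as a formula); every piece of it is
#' configurable.
#'
#' @param N_max Target (cap) cycle count, default 1e5.
#' @param start_fraction Fraction of mean static strength for the first
#'   specimen, default 0.5.
#' @param band_thresholds Two increasing life fractions in (0, 1) splitting
#'   failures into early / intermediate / late bands, default `c(0.1, 0.5)`.
#' @param band_multipliers Three non-decreasing factors in (0, 1) applied to
#'   the current force after a failure in each band, default
#'   `c(0.5, 0.7, 0.8)`.
#' @param stop_survivals Number of runouts that completes the campaign,
#'   default 3.
#' @param max_specimens Specimen budget before the campaign is declared
#'   exhausted, default 25.
#' @param report_rounding Force reporting resolution, N, default 0.1.
#' @param runout_increase Factor applied after a runout when no failure has
#'   been observed yet (nothing to bisect toward), default 1.25.
#' @param preconditioning_fraction Preconditioning force as a fraction of
#'   the initial force; metadata only, never used in computations.
#' @return An object of class `"campaign_config"`.
#' @export
campaign_config <- function(N_max = 1e5, start_fraction = 0.5,
                            band_thresholds = c(0.1, 0.5),
                            band_multipliers = c(0.5, 0.7, 0.8),
                            stop_survivals = 3, max_specimens = 25,
                            report_rounding = 0.1, runout_increase = 1.25,
                            preconditioning_fraction = 0.1) {
  stop_if_not_number(N_max, "N_max")
  stop_if_not_number(start_fraction, "start_fraction")
  stop_if_not_number(stop_survivals, "stop_survivals")
  stop_if_not_number(max_specimens, "max_specimens")
  stop_if_not_number(report_rounding, "report_rounding")
  stop_if_not_number(runout_increase, "runout_increase")
  if (N_max <= 0) stop("`N_max` must be positive.", call. = FALSE)
  if (start_fraction <= 0 || start_fraction >= 1)
    stop("`start_fraction` must lie in (0, 1).", call. = FALSE)
  if (length(band_thresholds) != 2 || any(band_thresholds <= 0) ||
      any(band_thresholds >= 1) || diff(band_thresholds) <= 0)
    stop("`band_thresholds` must be two increasing fractions in (0, 1).",
         call. = FALSE)
  if (length(band_multipliers) != 3 || any(band_multipliers <= 0) ||
      any(band_multipliers >= 1) || any(diff(band_multipliers) < 0))
    stop("`band_multipliers` must be three non-decreasing factors in (0, 1).",
         call. = FALSE)
  if (stop_survivals < 1) stop("`stop_survivals` must be >= 1.", call. = FALSE)
  if (max_specimens < 1) stop("`max_specimens` must be >= 1.", call. = FALSE)
  if (report_rounding <= 0)
    stop("`report_rounding` must be positive.", call. = FALSE)
  if (runout_increase <= 1)
    stop("`runout_increase` must exceed 1.", call. = FALSE)
  structure(
    list(N_max = N_max, start_fraction = start_fraction,
         band_thresholds = band_thresholds,
         band_multipliers = band_multipliers,
         stop_survivals = as.integer(stop_survivals),
         max_specimens = as.integer(max_specimens),
         report_rounding = report_rounding,
         runout_increase = runout_increase,
         preconditioning_fraction = preconditioning_fraction),
    class = "campaign_config"
  )
}

#' Round a force to the reporting resolution (half away from zero)
#'
#' Base R `round()` rounds half to even; force reports use the conventional
#' half-away-from-zero rule so e.g. 127.25 N reports as 127.3 N at 0.1 N
#' resolution.
#'
#' @param force Force(s), N.
#' @param config A [campaign_config()] (supplies the resolution).
#' @return Rounded force(s), N.
#' @export
report_force <- function(force, config) {
  res <- config$report_rounding
  sign(force) * floor(abs(force) / res + 0.5) * res
}

#' First force of a staircase campaign
#'
#' `start_fraction` times the mean static failure force, carried at full
#' precision (the reported value is rounded separately).
#'
#' @param static_forces Static failure forces, N (non-empty).
#' @param config A [campaign_config()].
#' @return Full-precision force, N.
#' @examples
#' cfg <- campaign_config()
#' initial_force(c(210.5, 299.6, 262.0, 236.6, 263.9), cfg)  # 127.26
#' @export
initial_force <- function(static_forces, config) {
  if (!is.numeric(static_forces) || length(static_forces) < 1 ||
      any(!is.finite(static_forces)))
    stop("insufficient data: need at least one static failure force.",
         call. = FALSE)
  config$start_fraction * mean(static_forces)
}

#' Next target force of the staircase protocol
#'
#' After a failure, the current force is multiplied by the band multiplier
#' selected by the failure life as a fraction of `N_max`; after a runout,
#' the next force is the arithmetic mean of the current force and the lowest
#' failing force observed so far (bisection toward the failure boundary).
#' A runout with no prior failure has nothing to bisect toward, so the
#' force is increased by the configured `runout_increase` factor.
#'
#' @param current_force Current full-precision force, N.
#' @param outcome `"failure"` or `"runout"`.
#' @param life Observed life in cycles (used only for failures).
#' @param history Data.frame of prior specimens with columns `force_exact`
#'   and `outcome` (may be empty); the current specimen must be included
#'   when it failed, or not — only *prior and current* failures matter for
#'   bisection, so pass the history *including the current specimen*.
#' @param config A [campaign_config()].
#' @return Full-precision next force, N.
#' @export
next_force <- function(current_force, outcome, life, history, config) {
  stop_if_not_number(current_force, "current_force")
  outcome <- match.arg(outcome, c("failure", "runout"))
  if (outcome == "failure") {
    stop_if_not_number(life, "life")
    band <- findInterval(life / config$N_max, config$band_thresholds) + 1
    return(current_force * config$band_multipliers[band])
  }
  failed <- history$force_exact[history$outcome == "failure"]
  if (!length(failed)) return(current_force * config$runout_increase)
  (current_force + min(failed)) / 2
}

#' Run a staircase campaign against a life oracle
#'
#' Drives the modified staircase protocol: starts at
#' [initial_force()], queries the oracle for each specimen's life at the
#' current full-precision force, and steps with [next_force()] until
#' `stop_survivals` runouts have occurred (`status = "completed"`) or the
#' specimen budget is exhausted (`status = "exhausted"`). Deterministic
#' for a deterministic oracle.
#'
#' @param life_oracle Function of one argument (force, N) returning a list
#'   with `life` (cycles) and `outcome` (`"failure"` or `"runout"`).
#'   Runout lives must equal `N_max`. See [replay_oracle()] and
#'   [population_oracle()].
#' @param static_forces Static failure forces, N (set the initial force).
#' @param config A [campaign_config()].
#' @param label_prefix Specimen label prefix, default `"E"`.
#' @return An object of class `"campaign_record"`: list with `specimens`
#'   (data.frame: `specimen`, `force_exact`, `force_reported`, `outcome`,
#'   `life`), `status`, `config`.
#' @examples
#' lives <- c(1230, 23262, 78567, 1e5, 1e5, 1e5)
#' rec <- run_campaign(replay_oracle(lives), c(210.5, 299.6, 262.0, 236.6, 263.9),
#'                     campaign_config())
#' rec$specimens$force_reported  # 127.3 63.6 44.5 35.6 40.1 42.3
#' @export
run_campaign <- function(life_oracle, static_forces, config,
                         label_prefix = "E") {
  if (!is.function(life_oracle))
    stop("`life_oracle` must be a function of force.", call. = FALSE)
  if (!inherits(config, "campaign_config"))
    stop("`config` must be a campaign_config object.", call. = FALSE)
  force <- initial_force(static_forces, config)
  history <- data.frame(specimen = character(), force_exact = numeric(),
                        force_reported = numeric(), outcome = character(),
                        life = numeric(), stringsAsFactors = FALSE)
  survivals <- 0L
  status <- "exhausted"
  for (i in seq_len(config$max_specimens)) {
    res <- life_oracle(force)
    if (!is.list(res) || is.null(res$life) || is.null(res$outcome))
      stop("life oracle must return list(life=, outcome=).", call. = FALSE)
    if (res$outcome == "runout" && res$life != config$N_max)
      stop("oracle violation: runout life must equal N_max.", call. = FALSE)
    history <- rbind(history, data.frame(
      specimen = sprintf("%s%02d", label_prefix, i),
      force_exact = force, force_reported = report_force(force, config),
      outcome = res$outcome, life = res$life, stringsAsFactors = FALSE
    ))
    if (res$outcome == "runout") {
      survivals <- survivals + 1L
      if (survivals >= config$stop_survivals) {
        status <- "completed"
        break
      }
    }
    force <- next_force(force, res$outcome, res$life, history, config)
  }
  structure(list(specimens = history, status = status, config = config),
            class = "campaign_record")
}

#' @export
print.campaign_record <- function(x, ...) {
  cat(sprintf("Staircase campaign (%s, %d specimens)\n",
              x$status, nrow(x$specimens)))
  print(x$specimens, row.names = FALSE)
  invisible(x)
}

#' Oracle replaying a recorded life sequence
#'
#' Returns the recorded lives in order regardless of the queried force;
#' used to replay a physical campaign through the staircase engine (the
#' engine then reconstructs the force sequence from the protocol).
#'
#' @param lives Recorded lives in test order, cycles.
#' @param N_max Cap; lives at or above it are runouts (default 1e5).
#' @return A life-oracle function for [run_campaign()].
#' @export
replay_oracle <- function(lives, N_max = 1e5) {
  if (!is.numeric(lives) || !length(lives) || any(!is.finite(lives)) ||
      any(lives <= 0))
    stop("`lives` must be positive and finite.", call. = FALSE)
  i <- 0L
  function(force) {
    i <<- i + 1L
    if (i > length(lives))
      stop("replay exhausted: more specimens requested than recorded lives.",
           call. = FALSE)
    life <- lives[i]
    if (life >= N_max) list(life = N_max, outcome = "runout")
    else list(life = life, outcome = "failure")
  }
}

#' Sample-size sufficiency test of a staircase campaign
#'
#' A campaign is deemed sufficient when a Basquin force-life regression on
#' its points (runouts kept at the cap) has a slope significantly different
#' from zero: the returned value is the two-sided t-test p-value of the
#' log-log slope, to be compared against the 0.05 threshold.
#'
#' @param record A [run_campaign()] record (needs at least 3 points).
#' @return Slope p-value in `[0, 1]`.
#' @export
sufficiency_test <- function(record) {
  if (!inherits(record, "campaign_record"))
    stop("`record` must be a campaign_record object.", call. = FALSE)
  if (nrow(record$specimens) < 3)
    stop("insufficient data: need at least 3 specimens.", call. = FALSE)
  fit <- fit_basquin(record, runout_policy = "as_failure", min_failures = 1)
  fit$slope_p_value
}
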