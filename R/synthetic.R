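#' Virtual specimen population for protocol validation
#'
#' Generative model of a fatigue-test specimen population with the
#' statistical structure the analysis pipeline assumes: static strength is
#' normal (truncated at zero), the median force-life behaviour follows a
#' true Basquin law `force = A * life^beta`, individual lives scatter
#' lognormally around the median (normal in log-life, the standard fatigue
#' scatter model), and any life reaching `N_max` is censored as a runout.
#'
#' The defaults describe a small titanium plate population: static strength
#' 254.5 +/- 29.8 N, and a true force-life curve passing through a fatigue
#' limit of about 40.9 N at 1e5 cycles with exponent -0.25
#' (`A = 727.7`, `beta = -0.25`), with log-life scatter 0.2.
#'
#' @param coefficient True Basquin coefficient `A`: force at 1 cycle, N.
#' @param exponent True Basquin exponent `beta`, negative.
#' @param life_scatter Standard deviation of natural-log life, >= 0.
#' @param static_mean Mean static failure force, N.
#' @param static_sd Standard deviation of static failure force, N, >= 0.
#' @param N_max Runout censoring cap, cycles.
#' @return An object of class `"virtual_population"`.
#' @export
virtual_population <- function(coefficient = 727.7, exponent = -0.25,
                               life_scatter = 0.2, static_mean = 254.5,
                               static_sd = 29.8, N_max = 1e5) {
  stop_if_not_number(coefficient, "coefficient")
  stop_if_not_number(exponent, "exponent")
  stop_if_not_number(life_scatter, "life_scatter")
  stop_if_not_number(static_mean, "static_mean")
  stop_if_not_number(static_sd, "static_sd")
  stop_if_not_number(N_max, "N_max")
  if (coefficient <= 0) stop("`coefficient` must be positive.", call. = FALSE)
  if (exponent >= 0) stop("`exponent` must be negative.", call. = FALSE)
  if (life_scatter < 0) stop("`life_scatter` must be >= 0.", call. = FALSE)
  if (static_mean <= 0) stop("`static_mean` must be positive.", call. = FALSE)
  if (static_sd < 0) stop("`static_sd` must be >= 0.", call. = FALSE)
  if (N_max <= 0) stop("`N_max` must be positive.", call. = FALSE)
  structure(
    list(coefficient = coefficient, exponent = exponent,
         life_scatter = life_scatter, static_mean = static_mean,
         static_sd = static_sd, N_max = N_max),
    class = "virtual_population"
  )
}

#' True fatigue limit of a virtual population
#'
#' The force on the population's true Basquin curve at `N_max` (default:
#' the population's own cap) — the ground truth that simulated campaigns
#' try to recover.
#'
#' @param pop A [virtual_population()].
#' @param N_max Cycle count; defaults to the population cap.
#' @return Force in N.
#' @export
true_fatigue_limit <- function(pop, N_max = pop$N_max) {
  if (!inherits(pop, "virtual_population"))
    stop("`pop` must be a virtual_population object.", call. = FALSE)
  pop$coefficient * N_max^pop$exponent
}

#' Draw static failure forces from a virtual population
#'
#' Normal draws truncated at zero (negative draws are rejected and
#' redrawn; negligible mass at realistic parameters). Reproducible under a
#' fixed seed.
#'
#' @param pop A [virtual_population()].
#' @param n Number of specimens, >= 1.
#' @param seed Integer seed.
#' @return Vector of `n` forces, N.
#' @export
sample_static_strengths <- function(pop, n, seed) {
  if (!inherits(pop, "virtual_population"))
    stop("`pop` must be a virtual_population object.", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be >= 1.", call. = FALSE)
  n <- as.integer(n)
  if (pop$static_sd == 0) return(rep(pop$static_mean, n))
  set.seed(as.integer(seed))
  out <- stats::rnorm(n, pop$static_mean, pop$static_sd)
  while (any(out <= 0))
    out[out <= 0] <- stats::rnorm(sum(out <= 0), pop$static_mean, pop$static_sd)
  out
}

#' Simulate one specimen's fatigue life at a force
#'
#' The median life inverts the true Basquin law, `(force / A)^(1 / beta)`,
#' and is multiplied by `exp(N(0, life_scatter))`; lives reaching `N_max`
#' are censored as runouts at exactly `N_max`.
#'
#' @param pop A [virtual_population()].
#' @param force Applied cyclic force, N, positive.
#' @param seed Optional integer seed for this specimen's draw; omit to use
#'   the current RNG stream.
#' @return List with `life` (cycles) and `outcome` (`"failure"` or
#'   `"runout"`).
#' @export
specimen_life <- function(pop, force, seed = NULL) {
  if (!inherits(pop, "virtual_population"))
    stop("`pop` must be a virtual_population object.", call. = FALSE)
  stop_if_not_number(force, "force")
  if (force <= 0) stop("`force` must be positive (N).", call. = FALSE)
  life <- (force / pop$coefficient)^(1 / pop$exponent)
  if (pop$life_scatter > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    life <- life * exp(stats::rnorm(1, 0, pop$life_scatter))
  }
  # knife-edge tolerance: a force exactly on the curve at the cap must
  # censor even after the power-law round trip loses a few ulps
  if (life >= pop$N_max * (1 - 1e-12)) list(life = pop$N_max, outcome = "runout")
  else list(life = life, outcome = "failure")
}

#' Life oracle over a virtual population with hierarchical seeding
#'
#' Builds a [run_campaign()] oracle whose i-th query uses the i-th of a
#' pre-spawned block of specimen seeds derived from the master seed, so
#' specimen draws are independent of how many specimens precede them.
#'
#' @param pop A [virtual_population()].
#' @param seed Master integer seed.
#' @param max_specimens Size of the pre-spawned seed block.
#' @return A life-oracle function.
#' @export
population_oracle <- function(pop, seed, max_specimens = 1000) {
  if (!inherits(pop, "virtual_population"))
    stop("`pop` must be a virtual_population object.", call. = FALSE)
  seeds <- spawn_seeds(seed, max_specimens)
  i <- 0L
  function(force) {
    i <<- i + 1L
    if (i > length(seeds))
      stop("population oracle seed block exhausted.", call. = FALSE)
    specimen_life(pop, force, seed = seeds[i])
  }
}

# Derive a block of child seeds from a master seed (kept below 2^31).
spawn_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full staircase campaign on a virtual population
#'
#' Samples a static-strength series, then runs the staircase engine against
#' the population's life oracle. Master-seed reproducible: the static draws
#' and every specimen's life use seeds derived from `seed`.
#'
#' @param pop A [virtual_population()].
#' @param config A [campaign_config()] (its `N_max` should match the
#'   population's; the population cap governs censoring).
#' @param seed Master integer seed.
#' @param n_static Number of static specimens drawn to set the initial
#'   force (default 6).
#' @return A [run_campaign()] record, with the static forces attached as
#'   attribute `"static_forces"`.
#' @export
generate_campaign_dataset <- function(pop, config, seed, n_static = 6) {
  if (!inherits(config, "campaign_config"))
    stop("`config` must be a campaign_config object.", call. = FALSE)
  seeds <- spawn_seeds(seed, 2L)
  statics <- sample_static_strengths(pop, n_static, seed = seeds[1])
  oracle <- population_oracle(pop, seed = seeds[2],
                              max_specimens = config$max_specimens)
  rec <- run_campaign(oracle, statics, config)
  attr(rec, "static_forces") <- statics
  rec
}

#' Replicated recovery experiment: how well does the protocol find the limit?
#'
#' Repeats simulate-campaign / fit-Basquin / read-limit `n_replicates`
#' times and summarizes how the estimated fatigue limit compares with the
#' population's true limit. Runouts are excluded from the fit by default:
#' with failures lying on (or scattered around) the true line, excluding
#' censored points recovers the line without the downward bias that
#' cap-valued runouts introduce. Replicates whose campaign yields too few
#' failures to fit are reported as `NA` and skipped in the summary.
#'
#' @param pop A [virtual_population()].
#' @param config A [campaign_config()].
#' @param n_replicates Number of simulated campaigns, >= 1.
#' @param seed Master integer seed.
#' @param runout_policy Passed to [fit_basquin()]; default `"exclude"`.
#' @param n_static Static specimens per replicate (default 6).
#' @return An object of class `"recovery_experiment"`: list with
#'   `replicates` (data.frame: `replicate`, `n_specimens`, `n_failures`,
#'   `status`, `estimate`), `true_limit` (N), and `summary` (list: `bias`,
#'   `median_estimate`, `spread` (SD), `frac_within_5pct`, `n_valid`).
#' @export
recovery_experiment <- function(pop, config, n_replicates, seed,
                                runout_policy = "exclude", n_static = 6) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      n_replicates < 1)
    stop("`n_replicates` must be >= 1.", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  rep_seeds <- spawn_seeds(seed, n_replicates)
  truth <- true_fatigue_limit(pop)
  rows <- lapply(seq_len(n_replicates), function(r) {
    rec <- generate_campaign_dataset(pop, config, seed = rep_seeds[r],
                                     n_static = n_static)
    est <- tryCatch(
      fatigue_limit(fit_basquin(rec, runout_policy = runout_policy),
                    N_max = config$N_max),
      error = function(e) NA_real_
    )
    data.frame(replicate = r, n_specimens = nrow(rec$specimens),
               n_failures = sum(rec$specimens$outcome == "failure"),
               status = rec$status, estimate = est)
  })
  reps <- do.call(rbind, rows)
  est <- reps$estimate[is.finite(reps$estimate)]
  structure(
    list(
      replicates = reps,
      true_limit = truth,
      summary = list(
        bias = mean(est) - truth,
        median_estimate = stats::median(est),
        spread = if (length(est) > 1) stats::sd(est) else 0,
        frac_within_5pct = mean(abs(est - truth) / truth <= 0.05),
        n_valid = length(est)
      )
    ),
    class = "recovery_experiment"
  )
}

#' @export
print.recovery_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery experiment: %d valid replicates, true limit %.2f N\n",
              s$n_valid, x$true_limit))
  cat(sprintf("  median estimate %.2f N, bias %+.2f N, spread %.2f N\n",
              s$median_estimate, s$bias, s$spread))
  cat(sprintf("  fraction within 5%% of truth: %.2f\n", s$frac_within_5pct))
  invisible(x)
}
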