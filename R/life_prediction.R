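#' One load case: applied force and the resulting peak stresses
#'
#' A load case pairs a target cyclic force with the peak stress it induces
#' at the critical location, plus the stress at the preconditioning (lower
#' dwell) force; the two stresses define the stress cycle the part sees.
#'
#' @param label Identifier (e.g. `"E03"`).
#' @param force Target cyclic force, N.
#' @param precondition_force Preconditioning force, N (the cycle's low end).
#' @param peak_stress Peak stress at the target force, MPa.
#' @param precondition_stress Peak stress at the preconditioning force, MPa.
#' @return An object of class `"load_case"`.
#' @export
load_case <- function(label, force, precondition_force, peak_stress,
                      precondition_stress) {
  stop_if_not_number(force, "force")
  stop_if_not_number(precondition_force, "precondition_force")
  stop_if_not_number(peak_stress, "peak_stress")
  stop_if_not_number(precondition_stress, "precondition_stress")
  if (force <= 0 || precondition_force <= 0)
    stop("forces must be positive (N).", call. = FALSE)
  if (force >= precondition_force && peak_stress < precondition_stress)
    stop("peak stress at the target force must be at least the ",
         "preconditioning stress when the target force is larger.",
         call. = FALSE)
  structure(
    list(
      label = as.character(label),
      force = as.numeric(force),
      precondition_force = as.numeric(precondition_force),
      peak_stress = as.numeric(peak_stress),
      precondition_stress = as.numeric(precondition_stress)
    ),
    class = "load_case"
  )
}

#' Mean and population standard deviation of static failure forces
#'
#' Summarizes a static-strength test series. The standard deviation uses the
#' population convention (denominator n, not n - 1); with the sample
#' convention the summary would not reproduce the conventional reporting of
#' small static series this package targets.
#'
#' @param forces Static failure forces, N; at least two values.
#' @return A list with `mean` and `sd` (N) and `n`.
#' @examples
#' static_strength_summary(c(210.5, 299.6, 262.0, 236.6, 263.9))
#' @export
static_strength_summary <- function(forces) {
  if (!is.numeric(forces) || length(forces) < 2 || any(!is.finite(forces)))
    stop("need at least two finite static failure forces.", call. = FALSE)
  m <- mean(forces)
  list(mean = m, sd = sqrt(mean((forces - m)^2)), n = length(forces))
}

#' Capped fatigue-life prediction for one load case
#'
#' Runs the full stress-life chain for a load case: build the stress cycle
#' from the case's two peak stresses, map it to an equivalent fully reversed
#' amplitude with the chosen mean-stress correction, invert the S-N curve,
#' and cap the reported life at the campaign target `N_max` (survival past
#' `N_max` is operationally indistinguishable from infinite life, so
#' endurance outcomes also report `N_max`). Infeasible mean stress
#' (`sigma_m >= sigma_u`) and low-cycle amplitudes (above the curve's
#' validity window) are propagated as flags, never as errors.
#'
#' @param case A [load_case()].
#' @param curve An [build_sn_curve()]; its `sigma_u` drives the correction.
#' @param correction `"goodman"` or `"gerber"`.
#' @param N_max Campaign cap in cycles (default 1e5).
#' @param extrapolate_low_cycle If `TRUE`, low-cycle cases report the
#'   extrapolated Basquin life (still capped); default `FALSE`.
#' @return An object of class `"life_prediction"`: list with `label`,
#'   `correction`, `sigma_w` (MPa, `NA` if infeasible), `status` (one of
#'   `"finite"`, `"endurance"`, `"low_cycle"`, `"infeasible"`), `raw_life`
#'   (cycles; `Inf` for endurance, `NA` when flagged), `reported_life`
#'   (cycles, at most `N_max`; `NA` when flagged) and `N_max`.
#' @examples
#' curve <- build_sn_curve(material_spec(860, 795, 110000))
#' case <- load_case("E03", 44.5, 15, 658.6, 220.1)
#' predict_life(case, curve, "gerber")  # capped at 100000
#' @export
predict_life <- function(case, curve, correction = c("goodman", "gerber"),
                         N_max = 1e5, extrapolate_low_cycle = FALSE) {
  if (!inherits(case, "load_case"))
    stop("`case` must be a load_case object.", call. = FALSE)
  if (!inherits(curve, "sn_curve"))
    stop("`curve` must be an sn_curve object.", call. = FALSE)
  correction <- match.arg(correction)
  stop_if_not_number(N_max, "N_max")
  if (N_max <= 0) stop("`N_max` must be positive.", call. = FALSE)

  cycle <- make_cycle(case$peak_stress, case$precondition_stress)
  sigma_w <- switch(correction,
    goodman = goodman_equivalent(cycle, curve$sigma_u),
    gerber = gerber_equivalent(cycle, curve$sigma_u)
  )
  if (is.na(sigma_w)) {
    status <- "infeasible"
    raw <- NA_real_
    reported <- NA_real_
  } else {
    outcome <- life_at_stress(curve, sigma_w,
                              extrapolate = extrapolate_low_cycle)
    status <- outcome$status
    raw <- outcome$life
    reported <- if (status == "endurance") {
      N_max
    } else if (status == "low_cycle" && is.na(raw)) {
      NA_real_
    } else {
      min(raw, N_max)
    }
  }
  structure(
    list(label = case$label, correction = correction, sigma_w = sigma_w,
         status = status, raw_life = raw, reported_life = reported,
         N_max = N_max),
    class = "life_prediction"
  )
}

#' @export
print.life_prediction <- function(x, ...) {
  cat(sprintf("Life prediction [%s, %s]: ", x$label, x$correction))
  if (x$status == "infeasible") {
    cat("infeasible mean stress (no finite equivalent amplitude)\n")
  } else if (x$status == "low_cycle" && is.na(x$reported_life)) {
    cat(sprintf("low-cycle regime (sigma_w = %.1f MPa, outside validity)\n",
                x$sigma_w))
  } else {
    cat(sprintf("%.0f cycles (sigma_w = %.1f MPa, %s)\n",
                x$reported_life, x$sigma_w, x$status))
  }
  invisible(x)
}

#' Predictions for a list of load cases, as a table
#'
#' Applies [predict_life()] to each case and binds the results, preserving
#' input order.
#'
#' @param cases List of [load_case()] objects.
#' @inheritParams predict_life
#' @return A data.frame with columns `label`, `correction`, `force_N`,
#'   `sigma_max_MPa`, `sigma_min_MPa`, `sigma_a_MPa`, `sigma_m_MPa`,
#'   `sigma_w_MPa`, `status`, `raw_life`, `reported_life`.
#' @export
predict_life_table <- function(cases, curve,
                               correction = c("goodman", "gerber"),
                               N_max = 1e5, extrapolate_low_cycle = FALSE) {
  correction <- match.arg(correction)
  if (inherits(cases, "load_case")) cases <- list(cases)
  if (!length(cases) || !all(vapply(cases, inherits, logical(1), "load_case")))
    stop("`cases` must be a list of load_case objects.", call. = FALSE)
  rows <- lapply(cases, function(cs) {
    p <- predict_life(cs, curve, correction, N_max, extrapolate_low_cycle)
    cyc <- make_cycle(cs$peak_stress, cs$precondition_stress)
    data.frame(
      label = cs$label, correction = correction, force_N = cs$force,
      sigma_max_MPa = cyc$sigma_max, sigma_min_MPa = cyc$sigma_min,
      sigma_a_MPa = cyc$sigma_a, sigma_m_MPa = cyc$sigma_m,
      sigma_w_MPa = p$sigma_w, status = p$status,
      raw_life = p$raw_life, reported_life = p$reported_life
    )
  })
  do.call(rbind, rows)
}

#' Fatigue observations table
#'
#' Validated container for (force, life, censored) fatigue observations.
#' A censored observation is a runout: the specimen survived to the
#' campaign cap without failing, so its life equals the cap and is a lower
#' bound, not a failure time.
#'
#' @param force Applied cyclic forces, N.
#' @param life Cycles to failure, or the cap for runouts; positive.
#' @param censored Logical (or 0/1): `TRUE` for runouts.
#' @param label Optional specimen labels.
#' @param note Optional free-text notes (e.g. failure location).
#' @return A data.frame of class `"fatigue_observations"` with columns
#'   `label`, `force`, `life`, `censored`, `note`.
#' @export
fatigue_observations <- function(force, life, censored = FALSE,
                                 label = NULL, note = "") {
  if (!is.numeric(force) || !is.numeric(life) || length(force) != length(life))
    stop("`force` and `life` must be numeric vectors of equal length.",
         call. = FALSE)
  n <- length(force)
  censored <- rep_len(as.logical(censored), n)
  note <- rep_len(as.character(note), n)
  if (is.null(label)) label <- sprintf("obs%02d", seq_len(n))
  if (any(!is.finite(force)) || any(force <= 0))
    stop("forces must be positive and finite.", call. = FALSE)
  if (any(!is.finite(life)) || any(life <= 0))
    stop("lives must be positive and finite.", call. = FALSE)
  structure(
    data.frame(label = as.character(label), force = force, life = life,
               censored = censored, note = note),
    class = c("fatigue_observations", "data.frame")
  )
}

#' Basquin force-life regression with a runout policy
#'
#' Fits the log-log linear Basquin law `force = A * life^beta` by ordinary
#' least squares of `log10(force)` on `log10(life)`. Runouts (censored
#' observations) are handled by policy: `"as_failure"` keeps them at their
#' recorded life (the campaign cap) — the convention that reproduces
#' limit estimates from short staircase campaigns where most survivors sit
#' at the cap — while `"exclude"` drops them, which is unbiased when the
#' failures alone trace the force-life line. No maximum-likelihood censored
#' regression is attempted.
#'
#' @param observations A [fatigue_observations()] data.frame (or any
#'   data.frame with columns `force`, `life`, `censored`), or a
#'   [run_campaign()] record.
#' @param runout_policy `"as_failure"` (default) or `"exclude"`.
#' @param min_failures Minimum number of uncensored observations required
#'   (default 3).
#' @return An object of class `"basquin_fit"`: list with `coefficient`
#'   (force at 1 cycle, N), `exponent` (log-log slope, negative for valid
#'   fatigue data), `slope_p_value` (two-sided t-test of zero slope),
#'   `r_squared`, `n_used`, `runout_policy` and the underlying `lm` fit.
#' @examples
#' obs <- fatigue_observations(c(127.3, 63.6, 44.5), c(1230, 23262, 78567))
#' fit_basquin(obs)
#' @export
fit_basquin <- function(observations, runout_policy = c("as_failure", "exclude"),
                        min_failures = 3) {
  runout_policy <- match.arg(runout_policy)
  obs <- as_observation_frame(observations)
  n_fail <- sum(!obs$censored)
  if (n_fail < min_failures)
    stop(sprintf("insufficient data: %d uncensored observations, need %d.",
                 n_fail, min_failures), call. = FALSE)
  if (runout_policy == "exclude") obs <- obs[!obs$censored, , drop = FALSE]
  if (stats::var(log10(obs$life)) == 0)
    stop("degenerate fit: no variance in life.", call. = FALSE)
  dat <- data.frame(lf = log10(obs$force), ll = log10(obs$life))
  fit <- stats::lm(lf ~ ll, data = dat)
  # suppress the "essentially perfect fit" note for noiseless data
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(dat) > 2) sm$coefficients["ll", "Pr(>|t|)"] else NA_real_
  structure(
    list(
      coefficient = 10^unname(stats::coef(fit)[1]),
      exponent = unname(stats::coef(fit)[2]),
      slope_p_value = unname(p),
      r_squared = sm$r.squared,
      n_used = nrow(dat),
      runout_policy = runout_policy,
      lm = fit
    ),
    class = "basquin_fit"
  )
}

#' @export
print.basquin_fit <- function(x, ...) {
  cat("Basquin force-life fit (log-log OLS)\n")
  cat(sprintf("  force = %.4g * life^(%.5f)\n", x$coefficient, x$exponent))
  cat(sprintf("  slope p-value = %.4g, R^2 = %.4f, n = %d (runouts: %s)\n",
              x$slope_p_value, x$r_squared, x$n_used, x$runout_policy))
  invisible(x)
}

#' Fatigue limit: the fitted force at the campaign cap
#'
#' Evaluates a Basquin force-life fit at `N_max`, giving the force the part
#' is expected to sustain for `N_max` cycles without failure.
#'
#' @param fit A [fit_basquin()] object.
#' @param N_max Cycle count at which the limit is read off (default 1e5).
#' @return Force in N.
#' @export
fatigue_limit <- function(fit, N_max = 1e5) {
  if (!inherits(fit, "basquin_fit"))
    stop("`fit` must be a basquin_fit object.", call. = FALSE)
  stop_if_not_number(N_max, "N_max")
  if (N_max <= 0) stop("`N_max` must be positive.", call. = FALSE)
  fit$coefficient * N_max^fit$exponent
}

# Coerce campaign records / bare data.frames to the observation layout.
as_observation_frame <- function(x) {
  if (inherits(x, "campaign_record")) {
    return(data.frame(force = x$specimens$force_exact,
                      life = x$specimens$life,
                      censored = x$specimens$outcome == "runout"))
  }
  if (!is.data.frame(x) || !all(c("force", "life") %in% names(x)))
    stop("`observations` must have columns force, life (and optionally ",
         "censored).", call. = FALSE)
  if (is.null(x$censored)) x$censored <- FALSE
  if (any(!is.finite(x$force)) || any(x$force <= 0) ||
      any(!is.finite(x$life)) || any(x$life <= 0))
    stop("forces and lives must be positive and finite.", call. = FALSE)
  data.frame(force = x$force, life = x$life,
             censored = as.logical(x$censored))
}
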