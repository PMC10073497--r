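#' Constant-amplitude stress cycle from its two extrema
#'
#' Characterizes one load cycle by its peak stresses: amplitude
#' `sigma_a = (sigma_max - sigma_min) / 2` and mean
#' `sigma_m = (sigma_max + sigma_min) / 2`.
#'
#' @param sigma_max Maximum stress of the cycle, MPa.
#' @param sigma_min Minimum stress of the cycle, MPa; at most `sigma_max`.
#' @return An object of class `"stress_cycle"`: list with `sigma_max`,
#'   `sigma_min`, `sigma_a`, `sigma_m` (MPa).
#' @examples
#' make_cycle(526.2, 220.1)
#' @export
make_cycle <- function(sigma_max, sigma_min) {
  stop_if_not_number(sigma_max, "sigma_max")
  stop_if_not_number(sigma_min, "sigma_min")
  if (sigma_max < sigma_min)
    stop("invalid cycle: `sigma_max` is below `sigma_min`.", call. = FALSE)
  structure(
    list(
      sigma_max = as.numeric(sigma_max),
      sigma_min = as.numeric(sigma_min),
      sigma_a = (sigma_max - sigma_min) / 2,
      sigma_m = (sigma_max + sigma_min) / 2
    ),
    class = "stress_cycle"
  )
}

#' @export
print.stress_cycle <- function(x, ...) {
  cat(sprintf(
    "Stress cycle: max %.2f / min %.2f MPa (amplitude %.2f, mean %.2f)\n",
    x$sigma_max, x$sigma_min, x$sigma_a, x$sigma_m
  ))
  invisible(x)
}

#' Goodman mean-stress correction
#'
#' Maps a cycle with non-zero mean stress to the equivalent fully reversed
#' amplitude usable with a zero-mean S-N curve, via the linear Goodman
#' relation `sigma_w = sigma_a / (1 - sigma_m / sigma_u)`. Goodman is the
#' conservative choice: for tensile mean stress it yields a larger
#' equivalent amplitude (hence shorter predicted life) than Gerber.
#'
#' A mean stress at or above the ultimate strength has no finite equivalent
#' amplitude; `NA` is returned so callers can report the case as infeasible
#' rather than fail. A compressive (negative) mean stress is outside the
#' relation's intended regime and triggers a warning.
#'
#' @param cycle A [make_cycle()] object.
#' @param sigma_u Ultimate tensile strength, MPa.
#' @return Equivalent fully reversed amplitude in MPa, or `NA_real_` when
#'   `sigma_m >= sigma_u` (infeasible mean stress).
#' @examples
#' goodman_equivalent(make_cycle(526.2, 220.1), 860)  # about 270.4
#' @export
goodman_equivalent <- function(cycle, sigma_u) {
  check_correction_args(cycle, sigma_u)
  if (cycle$sigma_m >= sigma_u) return(NA_real_)
  if (cycle$sigma_m < 0)
    warning("negative mean stress: the Goodman relation is intended for ",
            "tensile mean stress.", call. = FALSE)
  cycle$sigma_a / (1 - cycle$sigma_m / sigma_u)
}

#' Gerber mean-stress correction
#'
#' Quadratic counterpart of [goodman_equivalent()]:
#' `sigma_w = sigma_a / (1 - (sigma_m / sigma_u)^2)`. For tensile mean
#' stress below the ultimate strength, Gerber's equivalent amplitude is
#' always below Goodman's, so Gerber predicts longer lives. The squared
#' term makes negative mean stress admissible as long as its magnitude
#' stays below `sigma_u`.
#'
#' @inheritParams goodman_equivalent
#' @return Equivalent fully reversed amplitude in MPa, or `NA_real_` when
#'   `|sigma_m| >= sigma_u` (infeasible mean stress).
#' @examples
#' gerber_equivalent(make_cycle(658.6, 220.1), 860)  # about 296.7
#' @export
gerber_equivalent <- function(cycle, sigma_u) {
  check_correction_args(cycle, sigma_u)
  if (abs(cycle$sigma_m) >= sigma_u) return(NA_real_)
  cycle$sigma_a / (1 - (cycle$sigma_m / sigma_u)^2)
}

check_correction_args <- function(cycle, sigma_u) {
  if (!inherits(cycle, "stress_cycle"))
    stop("`cycle` must be a stress_cycle object.", call. = FALSE)
  stop_if_not_number(sigma_u, "sigma_u")
  if (sigma_u <= 0)
    stop("`sigma_u` must be positive (MPa).", call. = FALSE)
  invisible(TRUE)
}
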