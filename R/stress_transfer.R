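#' Force-to-peak-stress transfer model
#'
#' A piecewise-linear map from applied force to peak stress at the critical
#' location, calibrated on (force, stress) knots — typically the output of a
#' static structural analysis at the tested force levels — or reduced to a
#' single proportionality coefficient. It is a geometry-free stand-in for a
#' full structural model: exact at the knots, linear between them, extended
#' linearly beyond the end knots using the edge slopes.
#'
#' @param forces Strictly increasing applied forces, N (knot abscissae).
#'   Omit when using `coefficient`.
#' @param stresses Positive peak stresses, MPa, one per force.
#' @param coefficient Single stress-per-force coefficient, MPa/N; mutually
#'   exclusive with knots.
#' @return An object of class `"stress_transfer"`.
#' @examples
#' st <- stress_transfer_model(c(63.6, 127.3), c(940, 1824.5))
#' stress_from_force(st, 95.45)
#' @export
stress_transfer_model <- function(forces = NULL, stresses = NULL,
                                  coefficient = NULL) {
  if (!is.null(coefficient)) {
    if (!is.null(forces) || !is.null(stresses))
      stop("supply either knots or a coefficient, not both.", call. = FALSE)
    stop_if_not_number(coefficient, "coefficient")
    if (coefficient <= 0)
      stop("`coefficient` must be positive (MPa/N).", call. = FALSE)
    return(structure(list(coefficient = as.numeric(coefficient), knots = NULL),
                     class = "stress_transfer"))
  }
  if (is.null(forces) || is.null(stresses))
    stop("empty transfer model: supply knots or a coefficient.", call. = FALSE)
  if (!is.numeric(forces) || !is.numeric(stresses) ||
      length(forces) != length(stresses) || length(forces) < 1)
    stop("`forces` and `stresses` must be numeric vectors of equal length.",
         call. = FALSE)
  if (any(!is.finite(forces)) || any(!is.finite(stresses)))
    stop("knots must be finite.", call. = FALSE)
  if (any(forces <= 0))
    stop("knot forces must be positive.", call. = FALSE)
  if (any(stresses <= 0))
    stop("knot stresses must be positive.", call. = FALSE)
  ord <- order(forces)
  forces <- forces[ord]
  stresses <- stresses[ord]
  if (any(diff(forces) <= 0))
    stop("knot forces must be strictly increasing (no duplicates).",
         call. = FALSE)
  structure(
    list(coefficient = NULL,
         knots = data.frame(force_N = forces, peak_stress_MPa = stresses)),
    class = "stress_transfer"
  )
}

#' Peak stress at an applied force
#'
#' @param model A [stress_transfer_model()].
#' @param F Applied force, N, positive; may be a vector.
#' @return Peak stress(es) in MPa.
#' @export
stress_from_force <- function(model, F) {
  if (!inherits(model, "stress_transfer"))
    stop("`model` must be a stress_transfer object.", call. = FALSE)
  if (!is.numeric(F) || length(F) < 1 || any(!is.finite(F)) || any(F <= 0))
    stop("`F` must be positive and finite.", call. = FALSE)
  if (!is.null(model$coefficient)) return(model$coefficient * F)
  x <- model$knots$force_N
  y <- model$knots$peak_stress_MPa
  n <- length(x)
  if (n == 1) return(y * F / x)  # single knot: proportional through origin
  vapply(F, function(f) {
    i <- findInterval(f, x, all.inside = TRUE)  # edge-slope extension
    y[i] + (y[i + 1] - y[i]) * (f - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}
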