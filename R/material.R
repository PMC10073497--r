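#' Static material properties guaranteed by a material standard
#'
#' Bundles the minimum static tensile properties that a material standard
#' (e.g. ASTM F3001-14 for additively manufactured Ti6Al4V ELI) guarantees.
#' These minima are the only material inputs needed to synthesize a
#' stress-life curve with [build_sn_curve()] and a strain-life law with
#' [build_strain_life()].
#'
#' @param ultimate_strength Ultimate tensile strength \eqn{\sigma_u}, MPa.
#' @param yield_strength 0.2\%-offset yield strength \eqn{\sigma_y}, MPa.
#'   Must be positive and below `ultimate_strength`.
#' @param elastic_modulus Elastic modulus \eqn{E}, MPa (110 GPa is entered
#'   as `110000`; see [read_material()] for the GPa-keyed file format).
#' @param elongation Elongation at break as a dimensionless fraction in
#'   (0, 1), e.g. `0.10` for 10\%.
#' @param poisson_ratio Poisson's ratio, dimensionless, in (0, 0.5).
#'
#' @return An object of class `"material_spec"`: a list with fields
#'   `ultimate_strength`, `yield_strength`, `elastic_modulus`,
#'   `elongation`, `poisson_ratio` (all MPa or dimensionless).
#'
#' @examples
#' ti64 <- material_spec(860, 795, 110000, elongation = 0.10)
#' ti64
#' @export
material_spec <- function(ultimate_strength, yield_strength, elastic_modulus,
                          elongation = 0.10, poisson_ratio = 0.34) {
  stop_if_not_number(ultimate_strength, "ultimate_strength")
  stop_if_not_number(yield_strength, "yield_strength")
  stop_if_not_number(elastic_modulus, "elastic_modulus")
  stop_if_not_number(elongation, "elongation")
  stop_if_not_number(poisson_ratio, "poisson_ratio")
  if (ultimate_strength <= 0)
    stop("`ultimate_strength` must be positive (MPa).", call. = FALSE)
  if (yield_strength <= 0 || yield_strength >= ultimate_strength)
    stop("`yield_strength` must satisfy 0 < yield < ultimate.", call. = FALSE)
  if (elastic_modulus <= 0)
    stop("`elastic_modulus` must be positive (MPa).", call. = FALSE)
  if (elongation <= 0 || elongation >= 1)
    stop("`elongation` must be a fraction in (0, 1).", call. = FALSE)
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("`poisson_ratio` must lie in (0, 0.5).", call. = FALSE)
  structure(
    list(
      ultimate_strength = as.numeric(ultimate_strength),
      yield_strength = as.numeric(yield_strength),
      elastic_modulus = as.numeric(elastic_modulus),
      elongation = as.numeric(elongation),
      poisson_ratio = as.numeric(poisson_ratio)
    ),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat("Material specification (standard minima)\n")
  cat(sprintf("  ultimate strength : %8.1f MPa\n", x$ultimate_strength))
  cat(sprintf("  yield strength    : %8.1f MPa\n", x$yield_strength))
  cat(sprintf("  elastic modulus   : %8.0f MPa\n", x$elastic_modulus))
  cat(sprintf("  elongation        : %8.2f\n", x$elongation))
  cat(sprintf("  Poisson ratio     : %8.2f\n", x$poisson_ratio))
  invisible(x)
}

#' Synthesize a Basquin stress-life (S-N) curve from standard minima
#'
#' Builds the high-cycle stress-life law for a material from its ultimate
#' tensile strength, following the standard two-anchor construction: the
#' low-cycle anchor is `S1 = 0.8 * sigma_u` at N = 1000 cycles (a stress
#' close to yield, below which the stress-life approach is not valid) and
#' the endurance anchor is `S2 = 0.307 * Cf * sigma_u` at `Nc1` cycles
#' (default 1e6), beyond which life is treated as infinite. The fabrication
#' factor `Cf` in (0, 1] knocks down the endurance stress for as-built
#' surface roughness, stress concentration, and process defects.
#'
#' The Basquin exponent is the log-log slope between the two anchors,
#' `b = (log10(S2) - log10(S1)) / (log10(Nc1) - 3)`, and the coefficient is
#' chosen so the power law `sigma_a(N) = sigma_f_prime * N^b` passes exactly
#' through both anchors: `sigma_f_prime = S1 * 1000^(-b)`. All life
#' computations therefore run on the two-anchor log-log line in cycles N,
#' which keeps results independent of any cycles-versus-reversals
#' convention.
#'
#' @param material A [material_spec()].
#' @param Cf Fabrication knock-down factor, in (0, 1]. Default 1 (standard
#'   material, no knock-down).
#' @param Nc1 Endurance life in cycles (default 1e6); must exceed 1000.
#'
#' @return An object of class `"sn_curve"`: list with fields `S1`, `S2`
#'   (MPa), `Nc1`, `b`, `sigma_f_prime` (MPa), `Cf`, `low_cycle_bound`
#'   (1000 cycles) and `sigma_u` (carried for mean-stress corrections).
#'
#' @examples
#' curve <- build_sn_curve(material_spec(860, 795, 110000), Cf = 1)
#' curve$S1   # 688
#' curve$S2   # 264.02
#' stress_at_life(curve, c(1e3, 1e6))
#' @export
build_sn_curve <- function(material, Cf = 1, Nc1 = 1e6) {
  if (!inherits(material, "material_spec"))
    stop("`material` must be a material_spec object.", call. = FALSE)
  stop_if_not_number(Cf, "Cf")
  stop_if_not_number(Nc1, "Nc1")
  if (Cf <= 0 || Cf > 1)
    stop("`Cf` must lie in (0, 1].", call. = FALSE)
  if (Nc1 <= 1e3)
    stop("`Nc1` must exceed 1000 cycles.", call. = FALSE)
  su <- material$ultimate_strength
  S1 <- 0.8 * su
  S2 <- 0.307 * Cf * su
  b <- (log10(S2) - log10(S1)) / (log10(Nc1) - 3)
  sigma_f_prime <- S1 * 1e3^(-b)
  structure(
    list(
      S1 = S1, S2 = S2, Nc1 = Nc1, b = b,
      sigma_f_prime = sigma_f_prime, Cf = Cf,
      low_cycle_bound = 1e3, sigma_u = su
    ),
    class = "sn_curve"
  )
}

#' @export
print.sn_curve <- function(x, ...) {
  cat("Basquin stress-life curve\n")
  cat(sprintf("  S1 (at 1e3 cycles)     : %9.2f MPa\n", x$S1))
  cat(sprintf("  S2 (at %.3g cycles)   : %9.2f MPa\n", x$Nc1, x$S2))
  cat(sprintf("  exponent b             : %9.5f\n", x$b))
  cat(sprintf("  coefficient sigma_f'   : %9.2f MPa\n", x$sigma_f_prime))
  cat(sprintf("  fabrication factor Cf  : %9.3f\n", x$Cf))
  invisible(x)
}

#' Stress amplitude sustained for a given fatigue life
#'
#' Evaluates the Basquin power law `sigma_a = sigma_f_prime * N^b`, i.e. the
#' log-log line through the curve's two anchors, at life `N`. The law is
#' strictly decreasing in N; evaluation is permitted outside the
#' (1000, Nc1) validity window (it simply extends the line).
#'
#' @param curve An [build_sn_curve()] object.
#' @param N Fatigue life in cycles; positive, may be a vector.
#' @return Stress amplitude(s) in MPa.
#' @examples
#' curve <- build_sn_curve(material_spec(860, 795, 110000))
#' stress_at_life(curve, 10^4.5)  # geometric mean of S1 and S2
#' @export
stress_at_life <- function(curve, N) {
  if (!inherits(curve, "sn_curve"))
    stop("`curve` must be an sn_curve object.", call. = FALSE)
  if (!is.numeric(N) || length(N) < 1 || any(!is.finite(N)) || any(N <= 0))
    stop("`N` must be positive and finite.", call. = FALSE)
  curve$sigma_f_prime * N^curve$b
}

#' Fatigue life at a fully reversed stress amplitude
#'
#' Inverts the Basquin line. Amplitudes inside `[S2, S1]` return a finite
#' life; amplitudes below the endurance stress `S2` are flagged
#' `"endurance"` (infinite life; tabulated as the campaign cap downstream);
#' amplitudes above `S1` fall in the low-cycle regime where the stress-life
#' approach is invalid and are flagged `"low_cycle"` (with the extrapolated
#' Basquin life only if `extrapolate = TRUE`).
#'
#' @param curve An [build_sn_curve()] object.
#' @param sigma_w Fully reversed (zero-mean) stress amplitude, MPa, positive
#'   scalar. Apply [goodman_equivalent()] or [gerber_equivalent()] first for
#'   cycles with non-zero mean stress.
#' @param extrapolate If `TRUE`, a low-cycle amplitude also reports the
#'   extrapolated Basquin life. Default `FALSE` (validity window enforced).
#'
#' @return An object of class `"life_outcome"`: list with `status` (one of
#'   `"finite"`, `"endurance"`, `"low_cycle"`) and `life` (cycles; `Inf`
#'   for endurance, `NA` for low-cycle unless extrapolating).
#' @examples
#' curve <- build_sn_curve(material_spec(860, 795, 110000))
#' life_at_stress(curve, 270.4)
#' life_at_stress(curve, 200)   # endurance
#' @export
life_at_stress <- function(curve, sigma_w, extrapolate = FALSE) {
  if (!inherits(curve, "sn_curve"))
    stop("`curve` must be an sn_curve object.", call. = FALSE)
  stop_if_not_number(sigma_w, "sigma_w")
  if (sigma_w <= 0)
    stop("`sigma_w` must be a positive stress amplitude (MPa).", call. = FALSE)
  invert <- function(s) (s / curve$sigma_f_prime)^(1 / curve$b)
  if (sigma_w < curve$S2) {
    out <- list(status = "endurance", life = Inf)
  } else if (sigma_w > curve$S1) {
    out <- list(
      status = "low_cycle",
      life = if (extrapolate) invert(sigma_w) else NA_real_
    )
  } else {
    out <- list(status = "finite", life = invert(sigma_w))
  }
  structure(out, class = "life_outcome")
}

#' @export
print.life_outcome <- function(x, ...) {
  lab <- switch(x$status,
    finite = sprintf("%.0f cycles", x$life),
    endurance = "endurance (infinite life)",
    low_cycle = if (is.na(x$life)) "low-cycle regime (outside validity)"
                else sprintf("low-cycle regime (extrapolated %.0f cycles)", x$life)
  )
  cat("Life outcome:", lab, "\n")
  invisible(x)
}

#' Tabulate an S-N curve at log-uniform life points
#'
#' @param curve An [build_sn_curve()] object.
#' @param n Number of points, log-uniform between 1000 cycles and `Nc1`.
#' @return A data.frame with columns `N` and `stress_amplitude_MPa`,
#'   suitable for CSV export with [utils::write.csv()].
#' @export
sn_curve_table <- function(curve, n = 50) {
  if (!inherits(curve, "sn_curve"))
    stop("`curve` must be an sn_curve object.", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("`n` must be at least 2.", call. = FALSE)
  N <- 10^seq(3, log10(curve$Nc1), length.out = as.integer(n))
  data.frame(N = N, stress_amplitude_MPa = stress_at_life(curve, N))
}

# shared scalar-argument validator
stop_if_not_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number.", name), call. = FALSE)
  invisible(TRUE)
}
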