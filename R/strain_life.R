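#' Strain-life (Coffin-Manson / Basquin) parameters from standard minima
#'
#' Builds the strain-life parameter set used to locate the elastic/plastic
#' transition of a material. The fatigue strength coefficient follows the
#' standard estimate `sigma_f_prime = 1.67 * sigma_u`; the remaining
#' parameters default to the values tabulated for titanium alloys:
#' fatigue ductility coefficient 0.35, fatigue ductility exponent -0.69,
#' fatigue strength exponent -0.095.
#'
#' @param material A [material_spec()].
#' @param eps_f_prime Fatigue ductility coefficient (dimensionless strain),
#'   positive. Default 0.35.
#' @param c Fatigue ductility exponent, negative and below `b` (the plastic
#'   branch is steeper). Default -0.69.
#' @param b Fatigue strength exponent, negative. Default -0.095.
#'
#' @return An object of class `"strain_life_params"`: list with
#'   `sigma_f_prime` (MPa), `b`, `eps_f_prime`, `c`.
#' @examples
#' sl <- build_strain_life(material_spec(860, 795, 110000))
#' sl$sigma_f_prime  # 1436.2
#' @export
build_strain_life <- function(material, eps_f_prime = 0.35, c = -0.69,
                              b = -0.095) {
  if (!inherits(material, "material_spec"))
    stop("`material` must be a material_spec object.", call. = FALSE)
  stop_if_not_number(eps_f_prime, "eps_f_prime")
  stop_if_not_number(c, "c")
  stop_if_not_number(b, "b")
  if (b >= 0) stop("`b` must be negative.", call. = FALSE)
  if (c >= 0) stop("`c` must be negative.", call. = FALSE)
  if (c >= b)
    stop("`c` must be below `b` (plastic branch steeper).", call. = FALSE)
  if (eps_f_prime <= 0) stop("`eps_f_prime` must be positive.", call. = FALSE)
  structure(
    list(
      sigma_f_prime = 1.67 * material$ultimate_strength,
      b = as.numeric(b),
      eps_f_prime = as.numeric(eps_f_prime),
      c = as.numeric(c)
    ),
    class = "strain_life_params"
  )
}

#' Elastic, plastic and total strain amplitudes at a reversal count
#'
#' Evaluates the strain-life decomposition: the elastic branch is the strain
#' form of Basquin's law, `(sigma_f_prime / E) * (2N)^b`; the plastic branch
#' is the Coffin-Manson law, `eps_f_prime * (2N)^c`; the total strain
#' amplitude is their sum.
#'
#' @param params A [build_strain_life()] object.
#' @param E Elastic modulus, MPa.
#' @param reversals Reversal count 2N, at least 1; may be a vector.
#' @return A data.frame with columns `reversals`, `elastic`, `plastic`,
#'   `total` (strain amplitudes, dimensionless).
#' @export
strain_amplitudes <- function(params, E, reversals) {
  if (!inherits(params, "strain_life_params"))
    stop("`params` must be a strain_life_params object.", call. = FALSE)
  stop_if_not_number(E, "E")
  if (E <= 0) stop("`E` must be positive (MPa).", call. = FALSE)
  if (!is.numeric(reversals) || any(!is.finite(reversals)) || any(reversals < 1))
    stop("`reversals` must be >= 1.", call. = FALSE)
  elastic <- (params$sigma_f_prime / E) * reversals^params$b
  plastic <- params$eps_f_prime * reversals^params$c
  data.frame(
    reversals = reversals,
    elastic = elastic,
    plastic = plastic,
    total = elastic + plastic
  )
}

#' Transition fatigue life separating plastic- and elastic-dominated regimes
#'
#' Solves for the reversal count 2Nt at which the elastic and plastic strain
#' amplitudes are equal: `2Nt = (eps_f_prime * E / sigma_f_prime)^(1/(b-c))`.
#' Below 2Nt the deformation is plastic-dominated (strain-life territory);
#' above it a stress-life treatment is valid.
#'
#' @param params A [build_strain_life()] object.
#' @param E Elastic modulus, MPa.
#' @return Transition reversal count 2Nt (numeric scalar).
#' @examples
#' sl <- build_strain_life(material_spec(860, 795, 110000))
#' transition_life(sl, 110000)  # about 251.5 reversals
#' @export
transition_life <- function(params, E) {
  if (!inherits(params, "strain_life_params"))
    stop("`params` must be a strain_life_params object.", call. = FALSE)
  stop_if_not_number(E, "E")
  if (E <= 0) stop("`E` must be positive (MPa).", call. = FALSE)
  if (params$b == params$c)
    stop("degenerate strain-life model: b equals c, no transition exists.",
         call. = FALSE)
  (params$eps_f_prime * E / params$sigma_f_prime)^(1 / (params$b - params$c))
}
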