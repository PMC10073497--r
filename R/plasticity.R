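#' Bilinear hardening plasticity model
#'
#' Describes a material by an elastic slope `E` up to the yield stress and a
#' linear hardening slope `H` beyond it. By default `H` is fitted so the
#' bilinear law reaches the ultimate strength at the elongation limit:
#' `H = (sigma_u - sigma_y) / (elongation - sigma_y / E)`.
#'
#' @param material A [material_spec()]; supplies `E`, the ultimate strength
#'   and the elongation for the default hardening modulus.
#' @param yield_strength Yield stress, MPa. Defaults to the material's
#'   yield; passed explicitly when a different (e.g. measured) yield is
#'   preferred for the plastic branch.
#' @param hardening_modulus Hardening slope `H`, MPa, in (0, E). Default
#'   fitted from the material record as above.
#' @return An object of class `"plasticity_model"`: list with `E`,
#'   `yield_strength`, `hardening_modulus` (MPa).
#' @examples
#' plasticity_model(material_spec(860, 795, 110000))
#' @export
plasticity_model <- function(material, yield_strength = material$yield_strength,
                             hardening_modulus = NULL) {
  if (!inherits(material, "material_spec"))
    stop("`material` must be a material_spec object.", call. = FALSE)
  stop_if_not_number(yield_strength, "yield_strength")
  E <- material$elastic_modulus
  if (yield_strength <= 0 || yield_strength >= material$ultimate_strength)
    stop("`yield_strength` must satisfy 0 < yield < ultimate.", call. = FALSE)
  if (is.null(hardening_modulus)) {
    hardening_modulus <- (material$ultimate_strength - yield_strength) /
      (material$elongation - yield_strength / E)
  }
  stop_if_not_number(hardening_modulus, "hardening_modulus")
  if (hardening_modulus <= 0 || hardening_modulus >= E)
    stop("`hardening_modulus` must lie in (0, E).", call. = FALSE)
  structure(
    list(
      E = E,
      yield_strength = as.numeric(yield_strength),
      hardening_modulus = as.numeric(hardening_modulus)
    ),
    class = "plasticity_model"
  )
}

#' Neuber correction of an over-yield linear-elastic stress
#'
#' A linear-elastic analysis can report fictitious peak stresses above
#' yield; the real material deforms plastically and redistributes the
#' stress. This correction applies Neuber's rule on the bilinear hardening
#' law: the corrected stress `s` satisfies
#' `s * eps(s) = sigma_elastic^2 / E`, where `eps(s)` is the bilinear
#' strain at `s`. The equation is solved by bisection on `(yield,
#' sigma_elastic)` to the requested stress tolerance; the solution is
#' strictly between the yield stress and the elastic input and is monotone
#' non-decreasing in the input.
#'
#' Stresses at or below yield are returned unchanged. The correction is a
#' map from fictitious elastic stresses to stresses on the material law;
#' its output is tagged as already lying on that law, so re-applying the
#' correction to its own output is a no-op (idempotence).
#'
#' @param sigma_elastic Linear-elastic peak stress, MPa, non-negative
#'   scalar.
#' @param model A [plasticity_model()].
#' @param tol Bisection tolerance on the corrected stress, MPa.
#' @return Corrected stress in MPa (with an attribute marking it as on the
#'   elasto-plastic law).
#' @examples
#' m <- plasticity_model(material_spec(860, 795, 110000))
#' plastic_correction(526.2, m)   # below yield: unchanged
#' plastic_correction(1824.5, m)  # mapped into (795, 1824.5)
#' @export
plastic_correction <- function(sigma_elastic, model, tol = 1e-8) {
  if (!inherits(model, "plasticity_model"))
    stop("`model` must be a plasticity_model object.", call. = FALSE)
  stop_if_not_number(sigma_elastic, "sigma_elastic")
  if (sigma_elastic < 0)
    stop("`sigma_elastic` must be non-negative (MPa).", call. = FALSE)
  if (isTRUE(attr(sigma_elastic, "on_material_law")))
    return(sigma_elastic)
  E <- model$E
  sy <- model$yield_strength
  H <- model$hardening_modulus
  if (sigma_elastic <= sy) {
    out <- as.numeric(sigma_elastic)
  } else {
    # bilinear strain at stress s (s > sy)
    strain_at <- function(s) sy / E + (s - sy) / H
    target <- sigma_elastic^2 / E  # Neuber product of the elastic solution
    lo <- sy
    hi <- as.numeric(sigma_elastic)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (mid * strain_at(mid) < target) lo <- mid else hi <- mid
    }
    out <- (lo + hi) / 2
  }
  attr(out, "on_material_law") <- TRUE
  out
}
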