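#' Analytic hydrogen-bridge model potentials
#'
#' Constructs one of three analytic potentials for the proton coordinate `x`
#' (measured from the midpoint of a collinear D-H...A bridge) and, for the
#' coupled bridge, the donor-acceptor distance `R`:
#'
#' * `"harmonic"`: \eqn{V = k x^2 / 2}, a free (non-bonded) X-H stretch;
#' * `"double_well"`: \eqn{V = V_0 ((x/a_0)^2 - 1)^2}, a symmetric quartic
#'   double well with minima at \eqn{x = \pm a_0} and barrier \eqn{V_0};
#' * `"coupled_bridge"`: the double well with well separation
#'   \eqn{a(R) = a_0 + c_a (R - R_0)} and barrier
#'   \eqn{V_0(R) = V_0 + c_V (R - R_0)} tracking the donor-acceptor
#'   distance, plus a restraint \eqn{k_R (R - R_0)^2 / 2}; a shorter bridge
#'   thus brings the wells together and lowers the transfer barrier, the
#'   geometric correlation that drives proton sharing in real hydrogen bonds.
#'
#' Defaults put the classical barrier at 3.1 kcal/mol, wells 0.35 A either
#' side of the bridge midpoint and an O...O-like equilibrium distance of
#' 2.6 A. Deuterium is modelled by `mass_H = 2.014`.
#'
#' @param kind one of `"harmonic"`, `"double_well"`, `"coupled_bridge"`.
#' @param mass_H proton (or deuteron) mass, amu.
#' @param mass_heavy donor/acceptor heavy-atom mass, amu.
#' @param k_harm harmonic force constant, kcal mol^-1 A^-2. The default
#'   corresponds to a 3400 cm^-1 stretch for a 1.008 amu proton.
#' @param V0 barrier height at the reference geometry, kcal/mol.
#' @param a0 half well separation, A.
#' @param R0 equilibrium donor-acceptor distance, A (must exceed `2 * a0`).
#' @param k_R donor-acceptor restraint constant, kcal mol^-1 A^-2.
#' @param c_a,c_V linear coupling of the well separation (A/A) and barrier
#'   (kcal mol^-1 A^-1) to `R - R0`.
#' @return an object of class `model_potential`.
#' @examples
#' m <- model_potential("double_well", V0 = 3.1, a0 = 0.35)
#' evaluate_potential(m, x = c(-0.35, 0, 0.35))$energy
#' @export
model_potential <- function(kind = c("harmonic", "double_well", "coupled_bridge"),
                            mass_H = 1.008, mass_heavy = 15.999,
                            k_harm = NULL, V0 = 3.1, a0 = 0.35, R0 = 2.6,
                            k_R = 60, c_a = 0.5, c_V = 3) {
  kind <- match.arg(kind)
  if (is.null(k_harm)) {
    omega <- 2 * pi * C_CMFS * 3400            # fs^-1
    k_harm <- 1.008 * MASSFAC * omega^2
  }
  stopifnot(mass_H > 0, mass_heavy > 0, k_harm > 0, V0 >= 0, a0 > 0, k_R >= 0)
  if (kind != "harmonic" && R0 <= 2 * a0)
    stop("R0 must exceed 2 * a0 so the wells lie between donor and acceptor")
  structure(list(kind = kind, mass_H = mass_H, mass_heavy = mass_heavy,
                 k_harm = k_harm, V0 = V0, a0 = a0, R0 = R0,
                 k_R = k_R, c_a = c_a, c_V = c_V),
            class = "model_potential")
}

kind_id <- function(model) {
  match(model$kind, c("harmonic", "double_well", "coupled_bridge")) - 1L
}

#' Evaluate a model potential
#'
#' Returns the energy and the exact analytic forces (negative gradients) at
#' the supplied bridge coordinates.
#'
#' @param model a [model_potential()].
#' @param x proton coordinate(s) relative to the bridge midpoint, A.
#' @param R donor-acceptor distance(s), A; recycled against `x`. Defaults to
#'   the model's `R0`.
#' @return list with numeric vectors `energy` (kcal/mol), `fx` and `fR`
#'   (kcal mol^-1 A^-1).
#' @export
evaluate_potential <- function(model, x, R = model$R0) {
  stopifnot(inherits(model, "model_potential"))
  if (any(R <= 0)) stop("R must be positive")
  if (model$kind == "coupled_bridge") {
    dR <- R - model$R0
    if (any(model$a0 + model$c_a * dR <= 0) || any(model$V0 + model$c_V * dR < 0))
      stop("R outside the potential domain: a(R) <= 0 or V0(R) < 0")
  }
  cpp_potential(kind_id(model), unclass(model), as.numeric(x), as.numeric(R))
}

#' @export
print.model_potential <- function(x, ...) {
  cat("<model_potential>", x$kind, "\n")
  cat(sprintf("  mass_H %.3f amu, mass_heavy %.3f amu\n", x$mass_H, x$mass_heavy))
  if (x$kind == "harmonic") {
    cat(sprintf("  k_harm %.1f kcal/mol/A^2\n", x$k_harm))
  } else {
    cat(sprintf("  V0 %.2f kcal/mol, a0 %.2f A, R0 %.2f A\n", x$V0, x$a0, x$R0))
    if (x$kind == "coupled_bridge")
      cat(sprintf("  k_R %.1f, c_a %.2f, c_V %.2f\n", x$k_R, x$c_a, x$c_V))
  }
  invisible(x)
}
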