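#' Solver settings for the solid-liquid equilibrium
#'
#' @param tol Convergence tolerance on the equilibrium residual
#'   `|ln(x * gamma) - RHS|` (dimensionless).
#' @param max_iter Maximum number of successive-substitution iterations.
#' @param damping Damping factor in (0, 1].
#' @return An object of class `sle_settings`. The universal gas constant
#'   used throughout is R = 8.314 J/(mol K).
#' @export
sle_settings <- function(tol = 1e-8, max_iter = 500L, damping = 0.5) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), damping = damping,
                 R_gas = R_GAS),
            class = "sle_settings")
}

# ln x_ideal(T): right-hand side of the equilibrium relation.
sle_rhs <- function(props, T) {
  (props$dH_fus / R_GAS) * (1 / props$T_m - 1 / T) +
    (props$dCp / R_GAS) * (props$T_m / T - 1 - log(props$T_m / T))
}

#' Ideal solubility of a solid solute
#'
#' The activity-coefficient-free (gamma = 1) limit of the solid-liquid
#' equilibrium relation:
#' \deqn{x = \exp\!\Big[\frac{\Delta H_{fus}}{R}\Big(\frac{1}{T_m} -
#'   \frac{1}{T}\Big) + \frac{\Delta C_p}{R}\Big(\frac{T_m}{T} - 1 -
#'   \ln\frac{T_m}{T}\Big)\Big].}
#' At the melting point the expression equals 1 exactly, and it is
#' strictly increasing in T below it.
#'
#' @param props [melting_props()] of the solute.
#' @param T Temperature(s) in K, each in (0, T_m].
#' @return Mole-fraction solubility, one value per temperature.
#' @examples
#' ideal_solubility(fructose_melting(), 308.15)
#' @export
ideal_solubility <- function(props, T) {
  stopifnot(inherits(props, "glysol_melting"))
  if (any(T <= 0)) abort("temperatures must be positive.")
  if (any(T > props$T_m)) {
    abort(sprintf("T = %g K exceeds the melting temperature %g K: no solid phase.",
                  max(T), props$T_m))
  }
  exp(sle_rhs(props, T))
}

#' Solve the solid-liquid equilibrium for solubility
#'
#' Finds the mole fraction x satisfying
#' \eqn{\ln[x\,\gamma_{solute}(x, T)] = \ln x_{ideal}(T)}
#' for a binary solute/solvent mixture under a configured activity model,
#' by damped successive substitution
#' \eqn{x \leftarrow (1 - d)\,x + d\, x_{ideal}/\gamma_{solute}(x)},
#' starting from the ideal solubility (clamped to at most 0.99) and
#' iterating until the equilibrium residual drops below `settings$tol`.
#' The iterate is clamped to (0, 1).
#'
#' @param config A [model_config()].
#' @param props [melting_props()] of the solute.
#' @param solute,solvent [component()] objects (solute first).
#' @param T Temperature, K; must not exceed the melting temperature.
#' @param settings An [sle_settings()].
#' @return Mole-fraction solubility (single number).
#' @examples
#' cfg <- gen_mock_model("ideal")
#' s <- component("fructose", 180.16, c(U = 1))
#' g <- component("glycerol", 92.09, c(U = 1))
#' solve_solubility(cfg, fructose_melting(), s, g, 308.15)
#' @export
solve_solubility <- function(config, props, solute, solvent, T,
                             settings = sle_settings()) {
  stopifnot(inherits(settings, "sle_settings"))
  if (T > props$T_m) {
    abort(sprintf("T = %g K exceeds the melting temperature %g K: no solid phase.",
                  T, props$T_m))
  }
  rhs <- sle_rhs(props, T)
  x_id <- exp(rhs)
  x <- min(x_id, 0.99)
  gamma_solute <- function(x) {
    st <- mixture_state(list(solute, solvent), c(x, 1 - x), T)
    activity_coefficients(st, config)$gamma[1]
  }
  resid <- Inf
  for (it in seq_len(settings$max_iter)) {
    g <- gamma_solute(x)
    resid <- abs(log(x * g) - rhs)
    if (resid <= settings$tol) return(x)
    x_new <- x_id / g
    x <- (1 - settings$damping) * x + settings$damping * x_new
    x <- min(max(x, 1e-12), 1 - 1e-12)
  }
  abort(sprintf("SLE solve did not converge at T = %g K (last residual %.3e).", T, resid))
}

#' Composition-basis conversions
#'
#' `mass_to_mole_fraction()` converts a solute mass fraction w to the mole
#' fraction \eqn{x = (w/M_s) / (w/M_s + (1-w)/M_v)};
#' `mole_to_mass_fraction()` is its exact algebraic inverse.
#' `to_g_per_100g()` expresses a mass fraction as grams of solute per
#' 100 g of *solution* (simply `100 * w`); `to_g_per_100g_solvent()` is
#' the per-100-g-of-solvent alternative `100 * w / (1 - w)`, kept separate
#' to avoid silent basis confusion.
#'
#' @param w Mass fraction(s) in `[0, 1]`.
#' @param x Mole fraction(s) in `[0, 1]`.
#' @param M_solute,M_solvent Molar masses, g/mol.
#' @return Numeric vector of converted compositions.
#' @examples
#' mass_to_mole_fraction(0.2270, 180.16, 92.09)
#' to_g_per_100g(0.226973)
#' @export
mass_to_mole_fraction <- function(w, M_solute, M_solvent) {
  if (any(w < 0 | w > 1)) abort("mass fractions must lie in [0, 1].")
  stopifnot(M_solute > 0, M_solvent > 0)
  (w / M_solute) / (w / M_solute + (1 - w) / M_solvent)
}

#' @rdname mass_to_mole_fraction
#' @export
mole_to_mass_fraction <- function(x, M_solute, M_solvent) {
  if (any(x < 0 | x > 1)) abort("mole fractions must lie in [0, 1].")
  stopifnot(M_solute > 0, M_solvent > 0)
  (x * M_solute) / (x * M_solute + (1 - x) * M_solvent)
}

#' @rdname mass_to_mole_fraction
#' @export
to_g_per_100g <- function(w) {
  if (any(w < 0 | w > 1)) abort("mass fractions must lie in [0, 1].")
  100 * w
}

#' @rdname mass_to_mole_fraction
#' @export
to_g_per_100g_solvent <- function(w) {
  if (any(w < 0 | w >= 1)) abort("mass fractions must lie in [0, 1).")
  100 * w / (1 - w)
}

#' Solubility curve over a temperature grid
#'
#' Solves the solid-liquid equilibrium at each temperature and returns a
#' tidy curve. Per-point failures are reported with their temperature.
#'
#' @inheritParams solve_solubility
#' @param T Numeric vector of temperatures, each at most the melting
#'   temperature.
#' @param basis `"mole_fraction"` or `"mass_fraction"` for the output
#'   composition column.
#' @return A tibble with columns `T_K` and `x` (in the requested basis),
#'   with the basis recorded in the `basis` attribute.
#' @export
solubility_curve <- function(config, props, solute, solvent, T,
                             basis = c("mole_fraction", "mass_fraction"),
                             settings = sle_settings()) {
  basis <- match.arg(basis)
  x <- vapply(T, function(Ti) {
    tryCatch(solve_solubility(config, props, solute, solvent, Ti, settings),
             error = function(e) {
               abort(sprintf("at T = %g K: %s", Ti, conditionMessage(e)))
             })
  }, numeric(1))
  if (basis == "mass_fraction") {
    x <- mole_to_mass_fraction(x, solute$molar_mass, solvent$molar_mass)
  }
  out <- tibble::tibble(T_K = as.numeric(T), x = x)
  attr(out, "basis") <- basis
  out
}
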