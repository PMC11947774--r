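#' Define a mixture component
#'
#' A component is an identity (name), a molar mass, and optionally its
#' decomposition into functional subgroups. Group counts may be supplied
#' directly as a named numeric vector (one decomposition used for every
#' model), or as a named list keyed by model-variant name when different
#' activity models decompose the molecule differently. When a component
#' carries no counts at all, the [model_config()] used to evaluate it must
#' declare the decomposition in its `components` block.
#'
#' @param name Component name (single string).
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param group_counts Either `NULL`, a named numeric vector of non-negative
#'   subgroup counts, or a named list of such vectors keyed by model name.
#' @return An object of class `glysol_component`.
#' @examples
#' component("glycerol", 92.09, c(CH2 = 2, CH = 1, OH = 3))
#' @export
component <- function(name, molar_mass, group_counts = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0) {
    abort("`molar_mass` must be a single positive number (g/mol).")
  }
  if (!is.null(group_counts)) {
    check_counts <- function(v, label) {
      if (!is.numeric(v) || is.null(names(v)) || any(!nzchar(names(v)))) {
        abort(sprintf("group counts %s must be a named numeric vector.", label))
      }
      if (any(v < 0) || any(v != round(v))) {
        abort(sprintf("group counts %s must be non-negative integers.", label))
      }
      if (sum(v) <= 0) {
        abort(sprintf("group counts %s must contain at least one nonzero entry.", label))
      }
    }
    if (is.list(group_counts)) {
      if (is.null(names(group_counts))) {
        abort("a list of group counts must be keyed by model name.")
      }
      for (nm in names(group_counts)) check_counts(group_counts[[nm]], sprintf("for variant '%s'", nm))
    } else {
      check_counts(group_counts, sprintf("of component '%s'", name))
    }
  }
  structure(
    list(name = name, molar_mass = molar_mass, group_counts = group_counts),
    class = "glysol_component"
  )
}

#' @export
print.glysol_component <- function(x, ...) {
  cat(sprintf("<component> %s (M = %.2f g/mol)\n", x$name, x$molar_mass))
  invisible(x)
}

#' Melting properties of a solid solute
#'
#' The three constants entering the solid-liquid equilibrium relation:
#' the enthalpy of fusion at the normal melting temperature, the melting
#' temperature itself, and a temperature-independent heat-capacity
#' difference between the subcooled liquid and the solid.
#'
#' @param dH_fus Enthalpy of fusion, J/mol; positive.
#' @param T_m Normal melting temperature, K; positive.
#' @param dCp Heat-capacity difference, J/(mol K); non-negative (0 selects
#'   the simplified two-term form of the equilibrium relation).
#' @return An object of class `glysol_melting`.
#' @examples
#' melting_props(26030, 376.15, 232)
#' @export
melting_props <- function(dH_fus, T_m, dCp = 0) {
  if (!is.numeric(dH_fus) || length(dH_fus) != 1L || dH_fus <= 0) {
    abort("`dH_fus` must be a single positive number (J/mol).")
  }
  if (!is.numeric(T_m) || length(T_m) != 1L || T_m <= 0) {
    abort("`T_m` must be a single positive number (K).")
  }
  if (!is.numeric(dCp) || length(dCp) != 1L || dCp < 0) {
    abort("`dCp` must be a single non-negative number (J/(mol K)).")
  }
  structure(list(dH_fus = dH_fus, T_m = T_m, dCp = dCp), class = "glysol_melting")
}

#' @export
print.glysol_melting <- function(x, ...) {
  cat(sprintf(
    "<melting props> dH_fus = %g J/mol, T_m = %g K, dCp = %g J/(mol K)\n",
    x$dH_fus, x$T_m, x$dCp
  ))
  invisible(x)
}

#' Bundled fructose and glycerol fixtures
#'
#' Compiled-in experimental constants for the fructose-glycerol system:
#' the isothermal solubility dataset (five temperatures, 308.15-351.15 K,
#' mass-fraction basis, with replicate scatter sigma), fructose melting
#' properties (dH_fus = 26030 J/mol, T_m = 376.15 K, dCp = 232 J/(mol K)),
#' and the two components with standard molar masses (fructose 180.16,
#' glycerol 92.09 g/mol). `fructose_solubility_308K_unrounded()` returns
#' the full-precision 308.15 K mass fraction (0.226973) from which the
#' rounded table entry 0.2270 derives.
#'
#' @return `fructose_solubility()`: a solubility dataset tibble with columns
#'   `T_K`, `x_mass`, `sigma`. `fructose_melting()`: a [melting_props()]
#'   object. `fructose_component()`, `glycerol_component()`: components.
#'   `fructose_glycerol_fixtures()`: all of the above in a named list.
#' @examples
#' fructose_solubility()
#' fructose_melting()
#' @export
fructose_solubility <- function() {
  as_solubility_dataset(
    tibble::tibble(
      T_K = c(308.15, 318.15, 328.15, 338.15, 351.15),
      x_mass = c(0.2270, 0.2942, 0.3440, 0.4089, 0.4734),
      sigma = c(0.0036, 0.0030, 0.0038, 0.0043, 0.0099)
    ),
    basis_note = "mass fraction of fructose in fructose + glycerol"
  )
}

#' @rdname fructose_solubility
#' @export
fructose_solubility_308K_unrounded <- function() 0.226973

#' @rdname fructose_solubility
#' @export
fructose_melting <- function() melting_props(dH_fus = 26030, T_m = 376.15, dCp = 232)

#' @rdname fructose_solubility
#' @export
fructose_component <- function() component("fructose", 180.16)

#' @rdname fructose_solubility
#' @export
glycerol_component <- function() component("glycerol", 92.09)

#' @rdname fructose_solubility
#' @export
fructose_glycerol_fixtures <- function() {
  list(
    fructose = fructose_component(),
    glycerol = glycerol_component(),
    melting = fructose_melting(),
    dataset = fructose_solubility()
  )
}
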