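#' Activity coefficients under a configured model variant
#'
#' Evaluates the three contributions to \eqn{\ln\gamma_i} (combinatorial,
#' residual, association) for every component of a mixture state and
#' returns them in a tidy breakdown, one row per component, with the total
#' \eqn{\ln\gamma_i} and \eqn{\gamma_i = \exp(\ln\gamma_i)}. Configs
#' without an association block get an identically-zero association
#' column. A config carrying a `constant_lngamma` field (a named vector by
#' component name, used by the mock-model generator) short-circuits the
#' group-contribution machinery and returns those constants.
#'
#' @param state A [mixture_state()].
#' @param config A [model_config()].
#' @return A tibble of class `gamma_breakdown` with columns `component`,
#'   `x`, `ln_gamma_C`, `ln_gamma_R`, `ln_gamma_assoc`, `ln_gamma_total`,
#'   `gamma`, plus attributes `r`, `q` (molecular volume/area sums) and
#'   `T`.
#' @examples
#' cfg <- gen_mock_model("ideal")
#' a <- component("a", 100, c(U = 1)); b <- component("b", 50, c(U = 1))
#' activity_coefficients(mixture_state(list(a, b), c(0.3, 0.7), 320), cfg)
#' @export
activity_coefficients <- function(state, config) {
  stopifnot(inherits(state, "mixture_state"), inherits(config, "model_config"))
  nm <- purrr::map_chr(state$components, "name")
  if (!is.null(config$constant_lngamma)) {
    lng <- unname(vapply(nm, function(n) {
      v <- config$constant_lngamma[n]
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)))
    out <- tibble::tibble(component = nm, x = state$x,
                          ln_gamma_C = lng, ln_gamma_R = 0, ln_gamma_assoc = 0,
                          ln_gamma_total = lng, gamma = exp(lng))
    class(out) <- c("gamma_breakdown", class(out))
    attr(out, "T") <- state$T
    return(out)
  }
  nu <- count_matrix(state, config)
  sg <- config$subgroups
  rq <- t(apply(nu, 1L, function(cn) component_rq(cn[cn > 0], sg)))
  lnC <- combinatorial_lngamma(state, config)
  lnR <- residual_lngamma(state, config)
  lnA <- association_lngamma(state, config)
  lnT <- lnC + lnR + lnA
  out <- tibble::tibble(component = nm, x = state$x,
                        ln_gamma_C = lnC, ln_gamma_R = lnR,
                        ln_gamma_assoc = lnA, ln_gamma_total = lnT,
                        gamma = exp(lnT))
  class(out) <- c("gamma_breakdown", class(out))
  attr(out, "r") <- setNames(rq[, "r"], nm)
  attr(out, "q") <- setNames(rq[, "q"], nm)
  attr(out, "T") <- state$T
  out
}

#' Gibbs-Duhem residual of a binary mixture
#'
#' Diagnostic for thermodynamic consistency of a configured model: at
#' fixed temperature the Gibbs-Duhem relation requires
#' \eqn{x_1\, d\ln\gamma_1/dx_1 + x_2\, d\ln\gamma_2/dx_1 = 0}. The
#' derivatives are taken by central finite differences with step `h`.
#'
#' @param config A [model_config()].
#' @param components List of exactly two [component()] objects.
#' @param x1 Interior mole fraction(s) of component 1.
#' @param T Temperature, K.
#' @param h Finite-difference step.
#' @return Numeric vector of residuals, one per `x1`.
#' @export
gibbs_duhem_residual <- function(config, components, x1, T, h = 1e-5) {
  stopifnot(length(components) == 2L)
  lng <- function(x) {
    st <- mixture_state(components, c(x, 1 - x), T)
    activity_coefficients(st, config)$ln_gamma_total
  }
  vapply(x1, function(z) {
    up <- lng(z + h); dn <- lng(z - h)
    d <- (up - dn) / (2 * h)
    z * d[1] + (1 - z) * d[2]
  }, numeric(1))
}
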