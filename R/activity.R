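#' Define a mixture state
#'
#' A mixture state is the argument of every activity-coefficient
#' evaluation: the component list, their mole fractions, and the
#' temperature. Mole fractions must be non-negative and sum to one
#' (a zero mole fraction is allowed and yields the infinite-dilution
#' limit of that component).
#'
#' @param components List of [component()] objects.
#' @param x Numeric vector of mole fractions, same length as `components`.
#' @param T Temperature in Kelvin.
#' @return An object of class `mixture_state`.
#' @export
mixture_state <- function(components, x, T) {
  if (inherits(components, "glysol_component")) components <- list(components)
  if (!all(vapply(components, inherits, logical(1), "glysol_component"))) {
    abort("`components` must be a list of component() objects.")
  }
  if (length(x) != length(components)) {
    abort("`x` must have one mole fraction per component.")
  }
  if (any(x < 0)) abort("mole fractions must be non-negative.")
  if (abs(sum(x) - 1) > 1e-8) {
    abort(sprintf("mole fractions must sum to 1 (got %.12f).", sum(x)))
  }
  if (!is.numeric(T) || length(T) != 1L || T <= 0) abort("`T` must be a single positive Kelvin temperature.")
  structure(list(components = components, x = as.numeric(x), T = T),
            class = "mixture_state")
}

# r_i, q_i from a resolved count vector and the subgroup table.
component_rq <- function(counts, subgroups) {
  idx <- match(names(counts), subgroups$id)
  c(r = sum(counts * subgroups$R[idx]), q = sum(counts * subgroups$Q[idx]))
}

# Count matrix (components x subgroups actually used) for a state/config.
count_matrix <- function(state, config) {
  counts <- purrr::map(state$components, resolve_group_counts, config = config)
  subs <- unique(unlist(purrr::map(counts, names)))
  nu <- matrix(0, length(counts), length(subs),
               dimnames = list(purrr::map_chr(state$components, "name"), subs))
  for (i in seq_along(counts)) nu[i, names(counts[[i]])] <- counts[[i]]
  nu
}

#' Combinatorial contribution to ln gamma
#'
#' Entropic size/shape contribution for every component of a mixture,
#' in either the Staverman-Guggenheim form (coordination number z = 10)
#' used by classical UNIFAC,
#' \deqn{\ln\gamma_i^C = \ln(\Phi_i/x_i) + (z/2)\,q_i \ln(\theta_i/\Phi_i)
#'   + l_i - (\Phi_i/x_i)\sum_j x_j l_j,}
#' with \eqn{l_i = (z/2)(r_i - q_i) - (r_i - 1)}, or the Larsen-modified
#' form \eqn{\ln\gamma_i^C = \ln(\omega_i/x_i) + 1 - \omega_i/x_i} with
#' volume fractions built on \eqn{r_i^{2/3}}. Ratios such as
#' \eqn{\Phi_i/x_i} are evaluated analytically, so components at zero mole
#' fraction get their finite infinite-dilution value.
#'
#' @param state A [mixture_state()].
#' @param config A [model_config()] (supplies the decomposition and R/Q).
#' @param flavor Overrides the config's combinatorial flavor if given.
#' @return Numeric vector of \eqn{\ln\gamma_i^C}, one entry per component.
#' @export
combinatorial_lngamma <- function(state, config, flavor = NULL) {
  flavor <- flavor %||% config$combinatorial
  flavor <- match.arg(flavor, c("staverman_guggenheim", "larsen_modified"))
  nu <- count_matrix(state, config)
  sg <- config$subgroups
  rq <- t(apply(nu, 1L, function(cn) component_rq(cn[cn > 0], sg)))
  r <- rq[, "r"]; q <- rq[, "q"]
  x <- state$x
  if (flavor == "staverman_guggenheim") {
    phi_over_x <- r / sum(x * r)             # Phi_i / x_i
    theta_over_x <- q / sum(x * q)           # theta_i / x_i
    l <- (Z_COORD / 2) * (r - q) - (r - 1)
    unname(log(phi_over_x) + (Z_COORD / 2) * q * log(theta_over_x / phi_over_x) +
             l - phi_over_x * sum(x * l))
  } else {
    w_over_x <- r^(2 / 3) / sum(x * r^(2 / 3))  # omega_i / x_i
    unname(log(w_over_x) + 1 - w_over_x)
  }
}

# Group activity coefficients ln Gamma_k for subgroup mole fractions Xk.
group_lngamma <- function(Xk, sg, psi_main) {
  theta <- sg$Q * Xk / sum(sg$Q * Xk)
  P <- psi_main[sg$main, sg$main, drop = FALSE]  # P[m, k] = psi(main_m -> main_k)
  S1 <- as.numeric(crossprod(P, theta))          # sum_m theta_m psi_mk
  D <- as.numeric(crossprod(P, theta))           # same sums, denominator per column m
  S2 <- as.numeric(P %*% (theta / D))            # sum_m psi_km theta_m / D_m
  sg$Q * (1 - log(S1) - S2)
}

#' Residual (solution-of-groups) contribution to ln gamma
#'
#' \deqn{\ln\gamma_i^R = \sum_k \nu_k^{(i)} [\ln\Gamma_k - \ln\Gamma_k^{(i)}],}
#' where \eqn{\Gamma_k} is the group activity coefficient in the mixture
#' and \eqn{\Gamma_k^{(i)}} the same quantity in pure component i at the
#' same temperature, with
#' \eqn{\Psi_{mn} = \exp(-a_{mn}(T)/T)} and
#' \eqn{a_{mn}(T) = a^0_{mn} + a^1_{mn}(T - T_0)}. A group pair missing
#' from the interaction table is an error naming the pair.
#'
#' @inheritParams combinatorial_lngamma
#' @return Numeric vector of \eqn{\ln\gamma_i^R} per component.
#' @export
residual_lngamma <- function(state, config) {
  nu <- count_matrix(state, config)
  sg <- config$subgroups[match(colnames(nu), config$subgroups$id), , drop = FALSE]
  mains <- unique(sg$main)
  a <- interaction_matrix(config, mains, state$T)
  psi_main <- exp(-a / state$T)
  Xmix <- as.numeric(state$x %*% nu)
  Xmix <- Xmix / sum(Xmix)
  ln_mix <- group_lngamma(Xmix, sg, psi_main)
  vapply(seq_len(nrow(nu)), function(i) {
    Xi <- nu[i, ] / sum(nu[i, ])
    sum(nu[i, ] * (ln_mix - group_lngamma(Xi, sg, psi_main)))
  }, numeric(1))
}
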