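# Site bookkeeping: each associating subgroup g contributes a donor site
# class (g:D) and an acceptor class (g:A). Cross strengths use the
# arithmetic mean of eps/k and the geometric mean of kappa; only
# donor-acceptor pairs bond.
site_table <- function(assoc) {
  rows <- list()
  for (i in seq_len(nrow(assoc))) {
    g <- assoc[i, ]
    if (g$donors > 0) rows[[length(rows) + 1L]] <-
        tibble::tibble(site = paste0(g$subgroup, ":D"), subgroup = g$subgroup,
                       type = "D", mult = g$donors,
                       eps_over_k = g$eps_over_k, kappa = g$kappa)
    if (g$acceptors > 0) rows[[length(rows) + 1L]] <-
        tibble::tibble(site = paste0(g$subgroup, ":A"), subgroup = g$subgroup,
                       type = "A", mult = g$acceptors,
                       eps_over_k = g$eps_over_k, kappa = g$kappa)
  }
  dplyr::bind_rows(rows)
}

# Association strength matrix Delta_kl(T) between site classes.
delta_matrix <- function(sites, T) {
  n <- nrow(sites)
  D <- matrix(0, n, n, dimnames = list(sites$site, sites$site))
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (sites$type[k] == sites$type[l]) next
      kap <- sqrt(sites$kappa[k] * sites$kappa[l])
      eps <- (sites$eps_over_k[k] + sites$eps_over_k[l]) / 2
      D[k, l] <- kap * (expm1(eps / T))
    }
  }
  D
}

# Site mole densities (moles of each site class per mole of mixture)
# for composition x and count matrix nu (components x subgroups).
site_densities <- function(sites, nu, x) {
  vapply(seq_len(nrow(sites)), function(s) {
    g <- sites$subgroup[s]
    ng <- if (g %in% colnames(nu)) as.numeric(x %*% nu[, g]) else 0
    sites$mult[s] * ng
  }, numeric(1))
}

# Damped successive substitution for the mass-action system
# X_k = 1 / (1 + sum_l rho_l X_l Delta_kl); start X = 1.
solve_site_system <- function(rho, Delta, tol = 1e-10, max_iter = 1000L, damping = 0.5) {
  X <- rep(1, length(rho))
  for (it in seq_len(max_iter)) {
    Xnew <- 1 / (1 + as.numeric(Delta %*% (rho * X)))
    res <- max(abs(Xnew - X))
    X <- (1 - damping) * X + damping * Xnew
    if (res <= tol) return(X)
  }
  abort(sprintf("site-fraction solve did not converge in %d iterations (residual %.3e).",
                max_iter, res))
}

#' Solve the Wertheim non-bonded site fractions
#'
#' For each associating site class k, the fraction of sites not engaged in
#' a hydrogen bond, X_k in (0, 1], solves the mass-action system
#' \deqn{X_k = 1 / (1 + \sum_l \rho_l X_l \Delta_{kl}(T)),}
#' with site densities \eqn{\rho_l} on a mole-fraction basis (moles of
#' site l per mole of mixture) and association strength
#' \eqn{\Delta_{kl} = \kappa_{kl}[\exp(\epsilon_{kl}/kT) - 1]}. Donor and
#' acceptor classes of each associating subgroup only bond across types;
#' cross parameters combine as the arithmetic mean of \eqn{\epsilon/k} and
#' the geometric mean of \eqn{\kappa}. The system is solved by damped
#' successive substitution (damping 0.5, tolerance 1e-10 on the update,
#' at most 1000 iterations, start X = 1).
#'
#' @param state A [mixture_state()] whose components carry group counts
#'   (directly or via `config`).
#' @param assoc Association table (columns `subgroup`, `donors`,
#'   `acceptors`, `eps_over_k`, `kappa`).
#' @param config Optional [model_config()] used to resolve group counts.
#' @return Named numeric vector of non-bonded fractions, one per site
#'   class (names like `"OH:D"`, `"OH:A"`).
#' @export
solve_site_fractions <- function(state, assoc, config = NULL) {
  assoc <- tibble::as_tibble(assoc)
  if (!"donors" %in% names(assoc)) assoc$donors <- 1
  if (!"acceptors" %in% names(assoc)) assoc$acceptors <- 1
  sites <- site_table(assoc)
  if (is.null(sites) || nrow(sites) == 0) return(setNames(numeric(0), character(0)))
  nu <- if (!is.null(config)) {
    count_matrix(state, config)
  } else {
    counts <- purrr::map(state$components, function(cp) {
      if (!is.numeric(cp$group_counts)) {
        abort(sprintf("component '%s' carries no plain group-count vector; pass `config`.", cp$name))
      }
      cp$group_counts
    })
    subs <- unique(unlist(purrr::map(counts, names)))
    m <- matrix(0, length(counts), length(subs),
                dimnames = list(purrr::map_chr(state$components, "name"), subs))
    for (i in seq_along(counts)) m[i, names(counts[[i]])] <- counts[[i]]
    m
  }
  rho <- site_densities(sites, nu, state$x)
  Delta <- delta_matrix(sites, state$T)
  setNames(solve_site_system(rho, Delta), sites$site)
}

# Association chemical potential mu_i/RT for one composition:
# sum_l nu_li ln X_l + (1/2) sum_l rho_l (1 - X_l), the exact derivative
# of the Wertheim free energy on the mole-fraction site-density basis
# (evaluated with X at its mass-action stationary point).
assoc_mu <- function(nu_sites_i, rho, X) {
  sum(nu_sites_i * log(X)) + 0.5 * sum(rho * (1 - X))
}

#' Association contribution to ln gamma
#'
#' Wertheim-type hydrogen-bonding contribution. Writing \eqn{\mu_i^{assoc}/RT
#' = \sum_l \nu_{li} \ln X_l + \tfrac12 \sum_l \rho_l (1 - X_l)} (with
#' \eqn{\nu_{li}} the number of sites of class l on molecule i and
#' \eqn{\rho_l} the mixture site density), the activity-coefficient
#' contribution is the difference between the mixture and the pure-component
#' value, \eqn{\ln\gamma_i^{assoc} = \mu_i^{assoc}(x, T) -
#' \mu_i^{assoc}(\text{pure } i, T)}. This form derives from a single
#' Helmholtz-type generating function, so it vanishes identically for pure
#' components and satisfies the Gibbs-Duhem relation by construction.
#' Returns zeros when the config has no association block or no component
#' carries associating groups, and reduces to zero strength when
#' `kappa = 0`.
#'
#' @inheritParams combinatorial_lngamma
#' @return Numeric vector of \eqn{\ln\gamma_i^{assoc}} per component.
#' @export
association_lngamma <- function(state, config) {
  n <- length(state$components)
  if (is.null(config$association)) return(numeric(n))
  sites <- site_table(config$association)
  if (is.null(sites) || nrow(sites) == 0) return(numeric(n))
  nu <- count_matrix(state, config)
  # sites per molecule: nu_sites[i, l]
  nu_sites <- vapply(seq_len(nrow(sites)), function(s) {
    g <- sites$subgroup[s]
    ng <- if (g %in% colnames(nu)) nu[, g] else rep(0, n)
    sites$mult[s] * ng
  }, numeric(n))
  nu_sites <- matrix(nu_sites, nrow = n)
  if (all(nu_sites == 0)) return(numeric(n))
  Delta <- delta_matrix(sites, state$T)
  rho_mix <- as.numeric(state$x %*% nu_sites)
  X_mix <- solve_site_system(rho_mix, Delta)
  vapply(seq_len(n), function(i) {
    mu_mix <- assoc_mu(nu_sites[i, ], rho_mix, X_mix)
    rho_i <- nu_sites[i, ]
    if (all(rho_i == 0)) return(mu_mix)  # pure reference of an inert component is zero
    X_i <- solve_site_system(rho_i, Delta)
    mu_mix - assoc_mu(rho_i, rho_i, X_i)
  }, numeric(1))
}
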