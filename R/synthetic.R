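#' Measurement-noise specification
#'
#' Multiplicative lognormal noise emulating replicate scatter of
#' isothermal solubility measurements (the bundled experimental dataset
#' shows sigma/x of roughly 1-2%). The seed is mandatory: every
#' stochastic generator call is reproducible.
#'
#' @param rel_sd Relative standard deviation of the multiplicative noise
#'   (non-negative).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(rel_sd, seed) {
  stopifnot(is.numeric(rel_sd), length(rel_sd) == 1L, rel_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(rel_sd = rel_sd, seed = as.integer(seed)), class = "noise_spec")
}

apply_mult_noise <- function(x_true, noise, max_retry = 100L) {
  if (noise$rel_sd == 0) return(x_true)
  withr::with_seed(noise$seed, {
    x <- x_true * exp(rnorm(length(x_true), 0, noise$rel_sd))
    bad <- which(x <= 0 | x >= 1)
    tries <- 0L
    while (length(bad) > 0 && tries < max_retry) {
      x[bad] <- x_true[bad] * exp(rnorm(length(bad), 0, noise$rel_sd))
      bad <- which(x <= 0 | x >= 1)
      tries <- tries + 1L
    }
    if (length(bad) > 0) {
      abort("noise pushed solubilities outside (0, 1) after bounded retries.")
    }
    x
  })
}

#' Generate a synthetic Nyvlt-shaped solubility dataset
#'
#' Evaluates a Nyvlt correlation on a temperature grid and perturbs each
#' point with seeded multiplicative lognormal noise, standing in for
#' replicate isothermal measurements. The default grid mirrors the
#' experimental span 308.15-351.15 K.
#'
#' @param params A [nyvlt_params()] truth.
#' @param T_list Temperature grid, K.
#' @param noise A [noise_spec()].
#' @return A solubility dataset tibble (`T_K`, `x_mass`).
#' @examples
#' truth <- nyvlt_params(-38, 1000, 14, c(308.15, 351.15))
#' gen_nyvlt_dataset(truth, seq(310, 350, 10), noise_spec(0.015, 1))
#' @export
gen_nyvlt_dataset <- function(params,
                              T_list = seq(308.15, 351.15, length.out = 10),
                              noise = noise_spec(0, 1)) {
  stopifnot(inherits(params, "nyvlt_params"), inherits(noise, "noise_spec"))
  x_true <- suppressWarnings(predict_nyvlt(params, T_list))
  if (any(x_true <= 0 | x_true >= 1)) {
    abort("the Nyvlt truth leaves (0, 1) on this temperature grid.")
  }
  as_solubility_dataset(
    tibble::tibble(T_K = as.numeric(T_list), x_mass = apply_mult_noise(x_true, noise)),
    basis_note = sprintf("synthetic Nyvlt data (rel_sd = %g, seed = %d)",
                         noise$rel_sd, noise$seed)
  )
}

#' Generate mock activity-model configurations
#'
#' Three kinds of small, fully-controlled configs for testing:
#' * `"ideal"`: both components decompose into the same single subgroup,
#'   so every contribution vanishes analytically and gamma = 1 at any
#'   state.
#' * `"constant_gamma"`: the ideal config plus a `constant_lngamma`
#'   override pinning the solute's activity coefficient at `c_gamma`
#'   independent of composition (an engineered testing device honored by
#'   [activity_coefficients()]).
#' * `"random_small"`: two main groups with seeded small random R/Q,
#'   interaction energies and counts (optionally a weak association
#'   block), small enough that all model invariants (pure-component
#'   limits, Gibbs-Duhem consistency, continuity) hold comfortably.
#'
#' Mock configs name their components `"solute"` and `"solvent"`, and
#' also accept any component that carries its own counts.
#'
#' @param kind One of `"ideal"`, `"constant_gamma"`, `"random_small"`.
#' @param seed Integer seed (used by `"random_small"`).
#' @param c_gamma Constant solute activity coefficient for
#'   `"constant_gamma"`.
#' @param with_association Add a weak association block to
#'   `"random_small"`.
#' @return A [model_config()].
#' @examples
#' gen_mock_model("constant_gamma", c_gamma = 2)
#' @export
gen_mock_model <- function(kind = c("ideal", "constant_gamma", "random_small"),
                           seed = 1L, c_gamma = 2, with_association = FALSE) {
  kind <- match.arg(kind)
  if (kind %in% c("ideal", "constant_gamma")) {
    cfg <- model_config(
      name = if (kind == "ideal") "ideal" else sprintf("constant_gamma(%g)", c_gamma),
      combinatorial = "staverman_guggenheim",
      subgroups = tibble::tibble(id = "U", main = "U", R = 1, Q = 1),
      interactions = tibble::tibble(from = "U", to = "U", a0 = 0, a1 = 0),
      components = list(solute = c(U = 1), solvent = c(U = 1), fructose = c(U = 1),
                        glycerol = c(U = 1)),
      provenance = "synthetic mock configuration for testing"
    )
    if (kind == "constant_gamma") {
      cfg$constant_lngamma <- c(solute = log(c_gamma), fructose = log(c_gamma))
    }
    return(cfg)
  }
  withr::with_seed(seed, {
    R1 <- stats::runif(2, 0.5, 1.5); Q1 <- stats::runif(2, 0.5, 1.5)
    a12 <- stats::runif(1, -80, 80); a21 <- stats::runif(1, -80, 80)
    s1 <- stats::runif(1, -0.2, 0.2); s2 <- stats::runif(1, -0.2, 0.2)
    cnt_solute <- c(G1 = sample(1:3, 1), G2 = sample(0:2, 1))
    cnt_solvent <- c(G1 = sample(0:2, 1), G2 = sample(1:3, 1))
    if (cnt_solute[["G2"]] == 0 && cnt_solvent[["G1"]] == 0) cnt_solute[["G2"]] <- 1
    assoc <- if (with_association) {
      tibble::tibble(subgroup = "G2", donors = 1, acceptors = 1,
                     eps_over_k = stats::runif(1, 200, 800),
                     kappa = stats::runif(1, 0.001, 0.01))
    } else NULL
    model_config(
      name = sprintf("random_small(seed=%d)", seed),
      combinatorial = "staverman_guggenheim",
      subgroups = tibble::tibble(id = c("G1", "G2"), main = c("G1", "G2"),
                                 R = R1, Q = Q1),
      interactions = tibble::tibble(from = c("G1", "G2"), to = c("G2", "G1"),
                                    a0 = c(a12, a21), a1 = c(s1, s2)),
      association = assoc,
      components = list(solute = cnt_solute[cnt_solute > 0],
                        solvent = cnt_solvent[cnt_solvent > 0]),
      provenance = "synthetic seeded random configuration for testing"
    )
  })
}

#' Generate a synthetic SLE solubility dataset
#'
#' Solves the solid-liquid equilibrium under a given config at each
#' temperature, converts to mass fraction, and applies seeded
#' multiplicative noise. Used for end-to-end pipeline tests: on noiseless
#' data the generating config scores RMSD 0 in [run_model_comparison()],
#' and under noise its RMSD sits near the noise level.
#'
#' @param config A [model_config()].
#' @param props [melting_props()] of the solute.
#' @param solute,solvent [component()] objects.
#' @param T_list Temperature grid, K.
#' @param noise A [noise_spec()].
#' @param settings An [sle_settings()].
#' @return A solubility dataset tibble (`T_K`, `x_mass`).
#' @export
gen_sle_dataset <- function(config, props, solute, solvent,
                            T_list = seq(308.15, 351.15, length.out = 5),
                            noise = noise_spec(0, 1),
                            settings = sle_settings()) {
  stopifnot(inherits(noise, "noise_spec"))
  curve <- solubility_curve(config, props, solute, solvent, T_list,
                            basis = "mass_fraction", settings = settings)
  as_solubility_dataset(
    tibble::tibble(T_K = curve$T_K, x_mass = apply_mult_noise(curve$x, noise)),
    basis_note = sprintf("synthetic SLE data from model '%s' (rel_sd = %g, seed = %d)",
                         config$name, noise$rel_sd, noise$seed)
  )
}
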