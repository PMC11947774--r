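# Shared fixtures built in code.

# Two-subgroup config with all interactions zero: residual vanishes but the
# combinatorial does not (different R/Q per component).
zero_interaction_config <- function() {
  model_config(
    name = "zero_interaction",
    combinatorial = "staverman_guggenheim",
    subgroups = tibble::tibble(id = c("S1", "S2"), main = c("S1", "S2"),
                               R = c(0.8, 1.6), Q = c(0.7, 1.4)),
    interactions = tibble::tibble(from = c("S1", "S2"), to = c("S2", "S1"),
                                  a0 = 0, a1 = 0),
    components = list(alpha = c(S1 = 2), beta = c(S2 = 1))
  )
}

comp_alpha <- function() component("alpha", 100, c(S1 = 2))
comp_beta <- function() component("beta", 60, c(S2 = 1))

# Mock solute/solvent that every gen_mock_model() config can decompose.
mock_solute <- function() component("solute", 180.16)
mock_solvent <- function() component("solvent", 92.09)

# Classic validation mixture for the combined combinatorial + residual
# check: acetone (1 CH3 + 1 CH3CO) in n-pentane (2 CH3 + 3 CH2) at 307 K,
# x1 = 0.047. Frozen expected values were hand-evaluated independently of
# the engine (direct arithmetic on the published subgroup parameters):
#   ln_gamma_C = (-0.0527172613, -0.0001017694)
#   ln_gamma_R = ( 1.6605607660,  0.0053481940)
#   gamma      = ( 4.9920340,     1.0052600)
acetone_pentane <- function() {
  list(
    acetone = component("acetone", 58.08, c(CH3 = 1, CH3CO = 1)),
    pentane = component("n-pentane", 72.15, c(CH3 = 2, CH2 = 3)),
    T = 307, x = c(0.047, 0.953),
    ln_C = c(-0.0527172613, -0.0001017694),
    ln_R = c(1.6605607660, 0.0053481940),
    gamma = c(4.9920340, 1.0052600)
  )
}

# Single self-associating hydroxyl-like site pair for closed-form checks.
simple_assoc <- function(eps = 1500, kappa = 0.01) {
  tibble::tibble(subgroup = "OH", donors = 1, acceptors = 1,
                 eps_over_k = eps, kappa = kappa)
}

table3_temperatures <- function() c(308.15, 318.15, 328.15, 338.15, 351.15)
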