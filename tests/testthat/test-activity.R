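test_that("pure-component activity coefficients are exactly 1 for every bundled variant", {
  fx <- fructose_glycerol_fixtures()
  for (cfg in bundled_model_configs()) {
    for (pure_first in c(TRUE, FALSE)) {
      x <- if (pure_first) c(1, 0) else c(0, 1)
      st <- mixture_state(list(fx$fructose, fx$glycerol), x, 320)
      g <- activity_coefficients(st, cfg)
      i <- if (pure_first) 1 else 2
      expect_lt(abs(g$ln_gamma_total[i]), 1e-12)
    }
  }
})

test_that("components with identical size and shape have zero combinatorial term", {
  cfg <- model_config(
    name = "twin", subgroups = tibble::tibble(id = "U", main = "U", R = 1.3, Q = 0.9),
    interactions = tibble::tibble(from = "U", to = "U", a0 = 0),
    components = list(p = c(U = 2), q = c(U = 2))
  )
  comps <- list(component("p", 10), component("q", 10))
  for (flavor in c("staverman_guggenheim", "larsen_modified")) {
    st <- mixture_state(comps, c(0.3, 0.7), 350)
    expect_equal(combinatorial_lngamma(st, cfg, flavor = flavor), c(0, 0),
                 tolerance = 1e-14)
  }
})

test_that("the engine reproduces the independently evaluated classic mixture", {
  ap <- acetone_pentane()
  cfg <- bundled_model_configs("UNIFAC")
  st <- mixture_state(list(ap$acetone, ap$pentane), ap$x, ap$T)
  g <- activity_coefficients(st, cfg)
  expect_equal(g$ln_gamma_C, ap$ln_C, tolerance = 1e-8)
  expect_equal(g$ln_gamma_R, ap$ln_R, tolerance = 1e-8)
  expect_equal(g$gamma, ap$gamma, tolerance = 1e-6)
})

test_that("residual term vanishes for zero interactions and for pure components", {
  cfg <- zero_interaction_config()
  st <- mixture_state(list(comp_alpha(), comp_beta()), c(0.4, 0.6), 330)
  expect_equal(residual_lngamma(st, cfg), c(0, 0), tolerance = 1e-14)
  # pure component under a non-trivial interaction table
  cfgU <- bundled_model_configs("UNIFAC")
  fx <- fructose_glycerol_fixtures()
  stp <- mixture_state(list(fx$fructose, fx$glycerol), c(1, 0), 320)
  expect_identical(residual_lngamma(stp, cfgU)[1], 0)
  # and with zero interaction + zero association the total is the combinatorial alone
  tot <- activity_coefficients(st, cfg)
  expect_equal(tot$ln_gamma_total, tot$ln_gamma_C)
})

test_that("a missing interaction pair is reported by name", {
  cfg <- model_config(
    name = "gappy",
    subgroups = tibble::tibble(id = c("A1", "B1"), main = c("A", "B"),
                               R = c(1, 1.2), Q = c(1, 1.1)),
    interactions = tibble::tibble(from = "A", to = "B", a0 = 50),  # B->A missing
    components = list(u = c(A1 = 1), v = c(B1 = 1))
  )
  st <- mixture_state(list(component("u", 10), component("v", 10)), c(0.5, 0.5), 300)
  expect_error(residual_lngamma(st, cfg), "missing interaction pair \\(B, A\\)")
})

test_that("site fractions obey limits, symmetry and the quadratic closed form", {
  a <- component("hb", 50, c(OH = 1))
  b <- component("inert", 50, c(CH2 = 1))
  st <- mixture_state(list(a, b), c(0.4, 0.6), 320)
  # kappa = 0 switches association off entirely
  X0 <- solve_site_fractions(st, simple_assoc(kappa = 0))
  expect_equal(unname(X0), c(1, 1))
  # one self-associating site pair: quadratic closed form
  X <- solve_site_fractions(st, simple_assoc(eps = 1500, kappa = 0.01))
  rho <- 0.4
  Delta <- 0.01 * expm1(1500 / 320)
  Xc <- (-1 + sqrt(1 + 4 * rho * Delta)) / (2 * rho * Delta)
  expect_equal(unname(X), c(Xc, Xc), tolerance = 1e-9)
  # two site types with identical parameters and densities solve identically
  two <- tibble::tibble(subgroup = c("OH", "OH2"), donors = 1, acceptors = 1,
                        eps_over_k = 1200, kappa = 0.02)
  c2 <- component("hb2", 50, c(OH = 1, OH2 = 1))
  st2 <- mixture_state(list(c2, b), c(0.5, 0.5), 320)
  X2 <- solve_site_fractions(st2, two)
  expect_equal(unname(X2[c("OH:D", "OH:A")]), unname(X2[c("OH2:D", "OH2:A")]))
})

test_that("association term obeys its limits and matches direct substitution", {
  assoc <- simple_assoc(eps = 1500, kappa = 0.01)
  cfg <- model_config(
    name = "assoc_toy",
    subgroups = tibble::tibble(id = c("OH", "CH2"), main = c("OH", "CH2"),
                               R = c(1, 0.6744), Q = c(1.2, 0.54)),
    interactions = tibble::tibble(from = c("OH", "CH2"), to = c("CH2", "OH"), a0 = 0),
    association = assoc,
    components = list(hb = c(OH = 1, CH2 = 1), inert = c(CH2 = 2))
  )
  hb <- component("hb", 50, c(OH = 1, CH2 = 1))
  inert <- component("inert", 50, c(CH2 = 2))
  # mixture with no associating groups present -> zero vector
  st0 <- mixture_state(list(inert, inert), c(0.5, 0.5), 320)
  expect_equal(association_lngamma(st0, cfg), c(0, 0))
  # pure associating component -> exactly zero
  stp <- mixture_state(list(hb, inert), c(1, 0), 320)
  expect_equal(association_lngamma(stp, cfg)[1], 0)
  # direct substitution of the solved site fractions into the formula:
  # mu_i/RT = sum_l nu_li ln X_l + 0.5 * sum_l rho_l (1 - X_l)
  x1 <- 0.35
  st <- mixture_state(list(hb, inert), c(x1, 1 - x1), 320)
  X_mix <- solve_site_fractions(st, assoc, config = cfg)
  rho_mix <- rep(x1, 2)  # one donor + one acceptor site per hb molecule
  stp1 <- mixture_state(list(hb, inert), c(1, 0), 320)
  X_pure <- solve_site_fractions(stp1, assoc, config = cfg)
  mu_mix_hb <- sum(1 * log(X_mix)) + 0.5 * sum(rho_mix * (1 - X_mix))
  mu_pure_hb <- sum(1 * log(X_pure)) + 0.5 * sum(1 * (1 - X_pure))
  mu_mix_inert <- 0.5 * sum(rho_mix * (1 - X_mix))
  expected <- c(mu_mix_hb - mu_pure_hb, mu_mix_inert)
  expect_equal(association_lngamma(st, cfg), expected, tolerance = 1e-9)
})

test_that("a variant without association equals the same config with kappa = 0", {
  cfg_on <- bundled_model_configs("A-UNIFAC")
  cfg_off <- cfg_on
  cfg_off$association$kappa <- 0
  cfg_none <- cfg_on
  cfg_none$association <- NULL
  fx <- fructose_glycerol_fixtures()
  st <- mixture_state(list(fx$fructose, fx$glycerol), c(0.25, 0.75), 330)
  g_off <- activity_coefficients(st, cfg_off)
  g_none <- activity_coefficients(st, cfg_none)
  expect_equal(g_off$ln_gamma_assoc, c(0, 0))
  expect_equal(g_off$ln_gamma_total, g_none$ln_gamma_total, tolerance = 1e-12)
})

test_that("Gibbs-Duhem consistency holds for seeded random configs", {
  for (seed in 1:5) {
    cfg <- gen_mock_model("random_small", seed = seed,
                          with_association = seed %% 2 == 0)
    res <- gibbs_duhem_residual(cfg, list(mock_solute(), mock_solvent()),
                                x1 = c(0.2, 0.5, 0.8), T = 320)
    expect_lt(max(abs(res)), 1e-6)
  }
})

test_that("reordering components permutes all outputs identically", {
  cfg <- bundled_model_configs("A-UNIFAC")
  fx <- fructose_glycerol_fixtures()
  st12 <- mixture_state(list(fx$fructose, fx$glycerol), c(0.3, 0.7), 325)
  st21 <- mixture_state(list(fx$glycerol, fx$fructose), c(0.7, 0.3), 325)
  g12 <- activity_coefficients(st12, cfg)
  g21 <- activity_coefficients(st21, cfg)
  for (col in c("ln_gamma_C", "ln_gamma_R", "ln_gamma_assoc", "ln_gamma_total")) {
    expect_equal(g12[[col]], rev(g21[[col]]), tolerance = 1e-13)
  }
})

test_that("activity coefficients stay finite as a mole fraction vanishes", {
  fx <- fructose_glycerol_fixtures()
  for (cfg in bundled_model_configs()) {
    st <- mixture_state(list(fx$fructose, fx$glycerol), c(1e-12, 1 - 1e-12), 320)
    g <- activity_coefficients(st, cfg)
    expect_true(all(is.finite(g$ln_gamma_total)))
    # and the dilute value is continuous with a nearby small composition
    st2 <- mixture_state(list(fx$fructose, fx$glycerol), c(1e-6, 1 - 1e-6), 320)
    g2 <- activity_coefficients(st2, cfg)
    expect_equal(g$ln_gamma_total[1], g2$ln_gamma_total[1], tolerance = 1e-3)
  }
})

test_that("mixture states reject invalid compositions", {
  fx <- fructose_glycerol_fixtures()
  comps <- list(fx$fructose, fx$glycerol)
  expect_error(mixture_state(comps, c(-0.1, 1.1), 300), "non-negative")
  expect_error(mixture_state(comps, c(0.6, 0.6), 300), "sum to 1")
  expect_error(mixture_state(comps, c(0.5, 0.5), -3), "positive")
})
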