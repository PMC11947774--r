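test_that("bundled fixtures carry the experimental values to all printed digits", {
  d <- fructose_solubility()
  expect_s3_class(d, "solubility_dataset")
  expect_equal(d$T_K, c(308.15, 318.15, 328.15, 338.15, 351.15))
  expect_equal(d$x_mass, c(0.2270, 0.2942, 0.3440, 0.4089, 0.4734))
  expect_equal(d$sigma, c(0.0036, 0.0030, 0.0038, 0.0043, 0.0099))
  expect_equal(d$x_mass[d$T_K == 308.15], 0.2270)
  expect_equal(d$sigma[d$T_K == 351.15], 0.0099)

  m <- fructose_melting()
  expect_equal(m$dH_fus, 26030)
  expect_equal(m$T_m, 376.15)
  expect_equal(m$dCp, 232)

  expect_equal(fructose_component()$molar_mass, 180.16)
  expect_equal(glycerol_component()$molar_mass, 92.09)

  fx <- fructose_glycerol_fixtures()
  expect_named(fx, c("fructose", "glycerol", "melting", "dataset"))
})

test_that("the shipped solubility CSV parses to the same dataset", {
  path <- system.file("extdata", "table3.csv", package = "glysol")
  d <- read_solubility_table(path)
  ref <- fructose_solubility()
  expect_equal(d$T_K, ref$T_K)
  expect_equal(d$x_mass, ref$x_mass)
  expect_equal(d$sigma, ref$sigma)
})

test_that("solubility tables round-trip through CSV", {
  d <- as_solubility_dataset(
    tibble::tibble(T_K = c(300.123456789, 310.5), x_mass = c(0.21234567891234, 0.25),
                   sigma = c(0.001, 0.002)),
    basis_note = "round-trip check"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_solubility_table(d, path)
  back <- read_solubility_table(path)
  expect_equal(back$T_K, d$T_K)
  expect_equal(back$x_mass, d$x_mass)
  expect_equal(back$sigma, d$sigma)
})

test_that("malformed solubility inputs fail with row-level messages", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("T_K,x_mass", path)
  expect_error(read_solubility_table(path), "no records")

  writeLines(c("T_K,x_mass", "308.15,1.2"), path)
  expect_error(read_solubility_table(path), "row 1.*\\(0, 1\\)")

  writeLines(c("T_K,x_mass", "308.15,0.2", "308.15,0.3"), path)
  expect_error(read_solubility_table(path), "duplicate temperature")

  writeLines(c("T_K,x_mass", "308.15,0.2", "oops,0.3"), path)
  expect_error(read_solubility_table(path), "row 2.*malformed numeric")

  expect_error(as_solubility_dataset(data.frame(T_K = numeric(), x_mass = numeric())),
               "no records")
  expect_error(as_solubility_dataset(data.frame(T_K = -1, x_mass = 0.5)), "positive")
})

test_that("a minimal model config with a zero self-interaction is valid", {
  cfg <- model_config(
    name = "minimal", combinatorial = "staverman_guggenheim",
    subgroups = tibble::tibble(id = "U", main = "U", R = 1, Q = 1),
    interactions = tibble::tibble(from = "U", to = "U", a0 = 0)
  )
  expect_s3_class(cfg, "model_config")
  expect_equal(cfg$interactions$a1, 0)
})

test_that("config validation rejects dangling cross-references", {
  sg <- tibble::tibble(id = c("A1", "B1"), main = c("A", "B"), R = 1, Q = 1)
  expect_error(
    model_config("bad", subgroups = sg,
                 interactions = tibble::tibble(from = "A", to = "Z", a0 = 5)),
    "undeclared main group"
  )
  expect_error(
    model_config("bad", subgroups = sg,
                 association = tibble::tibble(subgroup = "OH", eps_over_k = 1, kappa = 0.1)),
    "absent from subgroup table"
  )
  expect_error(
    model_config("bad", subgroups = sg,
                 components = list(c1 = c(Zz = 1))),
    "undeclared subgroup"
  )
  expect_error(
    model_config("bad", subgroups = sg,
                 interactions = tibble::tibble(from = "A", to = "A", a0 = 3)),
    "self interactions"
  )
})

test_that("model configs round-trip through YAML and JSON", {
  cfg <- model_config(
    name = "rt", combinatorial = "larsen_modified",
    subgroups = tibble::tibble(id = c("G1", "G2"), main = c("G1", "G2"),
                               R = c(0.9011, 1.4457), Q = c(0.848, 1.18)),
    interactions = tibble::tibble(from = c("G1", "G2"), to = c("G2", "G1"),
                                  a0 = c(476.4, 26.76), a1 = c(0.12, -0.05)),
    association = tibble::tibble(subgroup = "G2", donors = 1, acceptors = 2,
                                 eps_over_k = 1800, kappa = 0.005),
    components = list(sugar = c(G1 = 2, G2 = 1)),
    T0 = 298.15, provenance = "round-trip test"
  )
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model_config(cfg, path)
    back <- read_model_config(path)
    expect_equal(back$name, cfg$name)
    expect_equal(back$combinatorial, cfg$combinatorial)
    expect_equal(back$T0, cfg$T0)
    expect_equal(as.data.frame(back$subgroups), as.data.frame(cfg$subgroups))
    expect_equal(as.data.frame(back$interactions), as.data.frame(cfg$interactions))
    expect_equal(as.data.frame(back$association), as.data.frame(cfg$association))
    expect_equal(back$components, cfg$components)
  }
})

test_that("bundled variant configs load and expose their structure", {
  cfgs <- bundled_model_configs()
  expect_setequal(names(cfgs),
                  c("UNIFAC", "A-UNIFAC", "Bio-UNIFAC", "mS-UNIFAC", "P&M-UNIFAC"))
  au <- bundled_model_configs("A-UNIFAC")
  expect_true(all(c("OHring", "OHgly") %in% au$association$subgroup))
  expect_equal(au$combinatorial, "staverman_guggenheim")
  expect_equal(bundled_model_configs("Bio-UNIFAC")$combinatorial, "larsen_modified")
  expect_error(bundled_model_configs("nope"), "no bundled config")
})

test_that("glycerol r and q derive from the configured subgroup decomposition", {
  cfg <- bundled_model_configs("UNIFAC")
  fx <- fructose_glycerol_fixtures()
  st <- mixture_state(list(fx$fructose, fx$glycerol), c(0.2, 0.8), 320)
  g <- activity_coefficients(st, cfg)
  # 2 CH2 + 1 CH + 3 OH
  expect_equal(unname(attr(g, "r")["glycerol"]), 2 * 0.6744 + 0.4469 + 3 * 1.0)
  expect_equal(unname(attr(g, "q")["glycerol"]), 2 * 0.540 + 0.228 + 3 * 1.2)
})
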