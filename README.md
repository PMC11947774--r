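# glysol

Solid–liquid equilibrium modeling of sugar solubility in non-aqueous
solvents, built around the fructose–glycerol system. Fructose dissolved
in glycerol is a candidate entrainer for extractive distillation of the
ethanol–water azeotrope; designing that process requires knowing how
much fructose glycerol holds as a function of temperature, and whether
predictive activity-coefficient models can reproduce it.

`glysol` provides, for thermodynamicists and process engineers:

* a **UNIFAC-family activity-coefficient engine**: Staverman–Guggenheim
  or Larsen-modified combinatorial, solution-of-groups residual with
  linearly temperature-dependent interaction energies, and an optional
  Wertheim association term for hydrogen-bonding hydroxyl sites
  (`activity_coefficients()`, `solve_site_fractions()`);
* a **solid–liquid equilibrium solver**,
  ln(x·γ) = (ΔH_fus/R)(1/T_m − 1/T) + (ΔC_p/R)(T_m/T − 1 − ln(T_m/T)),
  solved for x by damped successive substitution
  (`solve_solubility()`, `ideal_solubility()`, `solubility_curve()`);
* a **Nývlt correlation fitter** for log₁₀x = A + B/T + C·log₁₀T with
  closed-form and x-scale objectives and tidy accessors
  (`fit_nyvlt()`, `predict_nyvlt()`, `rmsd_percent()`);
* a **comparison pipeline** scoring configured model variants against a
  solubility dataset on both composition bases
  (`run_model_comparison()`, `build_unit_view()`, `export_figure_data()`);
* a **synthetic-data generator** for ground-truth testing
  (`gen_nyvlt_dataset()`, `gen_mock_model()`, `gen_sle_dataset()`).

The experimental fructose-in-glycerol dataset (five isothermal points,
308.15–351.15 K, mass fractions with replicate scatter) and fructose
melting constants (ΔH_fus = 26030 J/mol, T_m = 376.15 K, C_P^S = 232
J/(mol K)) ship as compiled-in fixtures. Model parameters live in YAML
config files under `inst/extdata/models/` with per-file provenance; the
plain UNIFAC file carries the classical published parameters, while the
A-UNIFAC / Bio-UNIFAC / mS-UNIFAC / P&M-UNIFAC files are labelled
structural reconstructions (see the methods vignette).

## Worked example

```r
library(glysol)

d <- fructose_solubility()
fit <- fit_nyvlt(d, objective = "x")
fit
#> Nyvlt solubility fit (x objective, n = 5)
#> <nyvlt_params> log10(x) = 84.9455 + -4807.72/T + -28.1198*log10(T)  [308.15, 351.15] K
#>   RMSD(rel) 1.167%   RMSD(abs) 0.359%   AARD 0.954%
```

The fitted correlation reproduces the data to an average relative
deviation of 0.95% inside its 308.15–351.15 K window (it warns if asked
to extrapolate). Comparing the activity-model variants, with the
simplified (ΔC_p = 0) equilibrium relation on the mole-fraction basis:

```r
fx <- fructose_glycerol_fixtures()
melt0 <- melting_props(26030, 376.15, 0)
rep <- run_model_comparison(d, bundled_model_configs(), melt0,
                            fx$fructose, fx$glycerol)
dplyr::select(tidy(rep), model, status, aard_mole_percent, rmsd_mole_percent)
#> # A tibble: 5 × 4
#>   model      status aard_mole_percent rmsd_mole_percent
#>   <chr>      <chr>              <dbl>             <dbl>
#> 1 A-UNIFAC   ok                  23.7              30.3
#> 2 Bio-UNIFAC ok                  40.5              45.5
#> 3 mS-UNIFAC  ok                  50.1              52.9
#> 4 P&M-UNIFAC ok                  40.9              45.9
#> 5 UNIFAC     ok                  45.4              49.2
```

Every variant deviates substantially from the measurements — the
experimental solubility is well below what near-ideal group-contribution
predictions give, with the association-corrected A-UNIFAC closest —
which is why the empirical Nývlt fit, not a predictive model, is the
practical correlation for this system. The unit view expresses the data
in g of fructose per 100 g of solution:

```r
build_unit_view(d)
#> # A tibble: 5 × 3
#>     T_K x_mass g_per_100g
#>   <dbl>  <dbl>      <dbl>
#> 1  308.  0.227       22.7
#> ...
```

`autoplot()` methods draw the fitted Nývlt curve over the data and the
per-model prediction curves.

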