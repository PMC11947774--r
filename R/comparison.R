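#' Compare activity-model variants against a solubility dataset
#'
#' Runs each configured model over the experimental temperatures: solves
#' the solid-liquid equilibrium at every temperature, converts predictions
#' between composition bases, and scores each model against the data with
#' relative and absolute RMSD and AARD, on both the mole- and
#' mass-fraction bases. A model that fails (missing parameters,
#' non-convergence) is marked failed with its error message; the others
#' complete. Identical inputs always produce identical reports — there is
#' no randomness anywhere in the pipeline.
#'
#' @param data A solubility dataset (mass-fraction basis, columns `T_K`,
#'   `x_mass`).
#' @param configs A list of [model_config()] objects (or a single one).
#' @param props [melting_props()] of the solute.
#' @param solute,solvent [component()] objects.
#' @param settings An [sle_settings()].
#' @return An object of class `comparison_report`: a list with
#'   `predictions` (tibble: `model`, `T_K`, `x_exp_mass`, `x_exp_mole`,
#'   `x_calc_mole`, `x_calc_mass`) and `summary` (tibble: `model`,
#'   `status`, the deviation statistics, `n`, `error`), rows sorted by
#'   model name. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' rep <- run_model_comparison(fructose_solubility(), list(gen_mock_model("ideal")),
#'                             solute = component("fructose", 180.16, c(U = 1)),
#'                             solvent = component("glycerol", 92.09, c(U = 1)))
#' tidy(rep)
#' @export
run_model_comparison <- function(data, configs,
                                 props = fructose_melting(),
                                 solute = fructose_component(),
                                 solvent = glycerol_component(),
                                 settings = sle_settings()) {
  if (inherits(configs, "model_config")) configs <- list(configs)
  if (length(configs) == 0) abort("need at least one model config.")
  data <- as_solubility_dataset(data, basis_note = attr(data, "basis_note") %||% "mass fraction")
  x_exp_mole <- mass_to_mole_fraction(data$x_mass, solute$molar_mass, solvent$molar_mass)
  nm <- purrr::map_chr(configs, "name")
  if (anyDuplicated(nm)) abort("model names must be unique within a comparison.")
  per_model <- purrr::map(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    res <- tryCatch({
      xc <- vapply(data$T_K, function(Ti) {
        solve_solubility(cfg, props, solute, solvent, Ti, settings)
      }, numeric(1))
      list(ok = TRUE, x_calc_mole = xc, error = NA_character_)
    }, error = function(e) list(ok = FALSE, x_calc_mole = rep(NA_real_, nrow(data)),
                                error = conditionMessage(e)))
    pred <- tibble::tibble(
      model = nm[i], T_K = data$T_K,
      x_exp_mass = data$x_mass, x_exp_mole = x_exp_mole,
      x_calc_mole = res$x_calc_mole,
      x_calc_mass = if (res$ok) {
        mole_to_mass_fraction(pmin(pmax(res$x_calc_mole, 0), 1),
                              solute$molar_mass, solvent$molar_mass)
      } else NA_real_
    )
    summ <- tibble::tibble(
      model = nm[i],
      status = if (res$ok) "ok" else "failed",
      rmsd_mole_percent = if (res$ok) rmsd_percent(pred$x_calc_mole, pred$x_exp_mole, "relative") else NA_real_,
      rmsd_mass_percent = if (res$ok) rmsd_percent(pred$x_calc_mass, pred$x_exp_mass, "relative") else NA_real_,
      aard_mole_percent = if (res$ok) rmsd_percent(pred$x_calc_mole, pred$x_exp_mole, "aard") else NA_real_,
      aard_mass_percent = if (res$ok) rmsd_percent(pred$x_calc_mass, pred$x_exp_mass, "aard") else NA_real_,
      n = nrow(data), error = res$error
    )
    list(pred = pred, summ = summ)
  })
  ord <- order(nm)
  predictions <- dplyr::bind_rows(purrr::map(per_model[ord], "pred"))
  summary <- dplyr::bind_rows(purrr::map(per_model[ord], "summ"))
  structure(
    list(predictions = predictions, summary = summary,
         basis = "mole_fraction",
         solute = solute$name, solvent = solvent$name),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Model comparison: %s in %s (%d models)\n",
              x$solute, x$solvent, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$summary

#' @export
glance.comparison_report <- function(x, ...) {
  ok <- x$summary[x$summary$status == "ok", ]
  best <- if (nrow(ok) > 0) ok$model[which.min(ok$rmsd_mole_percent)] else NA_character_
  tibble::tibble(
    n_models = nrow(x$summary), n_ok = nrow(ok),
    n_failed = nrow(x$summary) - nrow(ok),
    best_model = best,
    best_rmsd_mole_percent = if (nrow(ok) > 0) min(ok$rmsd_mole_percent) else NA_real_
  )
}

#' @export
autoplot.comparison_report <- function(object, ...) {
  pred <- object$predictions
  exp_pts <- dplyr::distinct(pred, .data$T_K, .data$x_exp_mole)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$T_K)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_calc_mole, color = .data$model)) +
    ggplot2::geom_point(data = exp_pts, ggplot2::aes(y = .data$x_exp_mole), size = 2) +
    ggplot2::labs(x = "T (K)", y = "solubility (mole fraction)",
                  title = "Experimental data vs model predictions", color = "model") +
    ggplot2::theme_minimal()
}

#' Tabulate a solubility dataset in g per 100 g of solution
#'
#' @param data A solubility dataset (mass-fraction basis).
#' @return A tibble with columns `T_K`, `x_mass`, `g_per_100g`. An empty
#'   input data frame yields an empty table.
#' @examples
#' build_unit_view(fructose_solubility())
#' @export
build_unit_view <- function(data) {
  if (is.data.frame(data) && nrow(data) == 0) {
    return(tibble::tibble(T_K = numeric(), x_mass = numeric(), g_per_100g = numeric()))
  }
  data <- as_solubility_dataset(data, basis_note = attr(data, "basis_note") %||% "mass fraction")
  tibble::tibble(T_K = data$T_K, x_mass = data$x_mass,
                 g_per_100g = to_g_per_100g(data$x_mass))
}

#' Export plot-ready curve data
#'
#' Writes two CSV files: `fig_nyvlt.csv` holds the experimental
#' mass-fraction points and a dense Nyvlt curve spanning the fitted
#' temperature window; `fig_models.csv` holds the experimental
#' mole-fraction points and each model's predicted points from a
#' comparison report. Both are long-format tables with a `series` column.
#'
#' @param report A [run_model_comparison()] report.
#' @param fit A [fit_nyvlt()] fit (or its [nyvlt_params()]).
#' @param data The experimental solubility dataset.
#' @param dir Output directory (created if missing).
#' @param n_grid Number of points of the dense Nyvlt curve.
#' @return Named character vector of the two file paths, invisibly.
#' @export
export_figure_data <- function(report, fit, data, dir, n_grid = 100) {
  stopifnot(inherits(report, "comparison_report"))
  params <- if (inherits(fit, "nyvlt_fit")) fit$params else fit
  stopifnot(inherits(params, "nyvlt_params"))
  data <- as_solubility_dataset(data, basis_note = attr(data, "basis_note") %||% "mass fraction")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid_T <- seq(params$T_range[1], params$T_range[2], length.out = n_grid)
  fig1 <- dplyr::bind_rows(
    tibble::tibble(series = "experimental", T_K = data$T_K, x_mass = data$x_mass),
    tibble::tibble(series = "nyvlt", T_K = grid_T,
                   x_mass = predict_nyvlt(params, grid_T))
  )
  f1 <- file.path(dir, "fig_nyvlt.csv")
  readr::write_csv(fig1, f1)
  pred <- report$predictions
  fig2 <- dplyr::bind_rows(
    dplyr::distinct(
      tibble::tibble(series = "experimental", T_K = pred$T_K, x_mole = pred$x_exp_mole)),
    tibble::tibble(series = pred$model, T_K = pred$T_K, x_mole = pred$x_calc_mole)
  )
  f2 <- file.path(dir, "fig_models.csv")
  readr::write_csv(fig2, f2)
  invisible(c(fig_nyvlt = f1, fig_models = f2))
}
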