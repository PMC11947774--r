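#' Nyvlt correlation parameters
#'
#' Container for the three coefficients of the Nyvlt solubility
#' correlation \eqn{\log_{10} x = A + B/T + C \log_{10} T} together with
#' the temperature window on which they were fitted. Predictions outside
#' the window are allowed but warn, since the correlation is an empirical
#' fit with no extrapolation guarantee.
#'
#' @param A,B,C Coefficients (A, C dimensionless; B in K).
#' @param T_range Length-2 numeric, the validity window in K.
#' @return An object of class `nyvlt_params`.
#' @export
nyvlt_params <- function(A, B, C, T_range) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(T_range) == 2L, T_range[1] <= T_range[2], T_range[1] > 0)
  structure(list(A = A, B = B, C = C, T_range = as.numeric(T_range)),
            class = "nyvlt_params")
}

#' @export
print.nyvlt_params <- function(x, ...) {
  cat(sprintf("<nyvlt_params> log10(x) = %.6g + %.6g/T + %.6g*log10(T)  [%g, %g] K\n",
              x$A, x$B, x$C, x$T_range[1], x$T_range[2]))
  invisible(x)
}

#' Evaluate the Nyvlt correlation
#'
#' Returns \eqn{10^{A + B/T + C\log_{10} T}} (a mass fraction when fitted
#' to mass-fraction data). Temperatures outside the fitted window trigger
#' a warning but still return the extrapolated value.
#'
#' @param params A [nyvlt_params()].
#' @param T Temperature(s), K; must be positive.
#' @return Predicted solubility, one value per temperature.
#' @export
predict_nyvlt <- function(params, T) {
  stopifnot(inherits(params, "nyvlt_params"))
  if (any(T <= 0)) abort("temperatures must be positive.")
  out_of_range <- T < params$T_range[1] | T > params$T_range[2]
  if (any(out_of_range)) {
    warn(sprintf(
      "%d temperature(s) outside the fitted range [%g, %g] K; the correlation is not validated there.",
      sum(out_of_range), params$T_range[1], params$T_range[2]))
  }
  10^(params$A + params$B / T + params$C * log10(T))
}

#' Deviation statistics between calculated and experimental solubilities
#'
#' Three conventions, all in percent:
#' `relative` is the root-mean-square relative deviation
#' \eqn{100\sqrt{\mathrm{mean}[((x_c - x_e)/x_e)^2]}};
#' `absolute` is the root-mean-square deviation on the raw scale,
#' \eqn{100\sqrt{\mathrm{mean}[(x_c - x_e)^2]}};
#' `aard` is the average absolute relative deviation
#' \eqn{100\,\mathrm{mean}[|x_c - x_e|/x_e]}, the statistic most solubility
#' papers print under the name "RMSD".
#'
#' @param x_calc,x_exp Numeric vectors of equal length (at least 1).
#' @param mode One of `"relative"`, `"absolute"`, `"aard"`.
#' @return A single percentage.
#' @examples
#' rmsd_percent(0.22, 0.20, "relative") # 10
#' rmsd_percent(0.22, 0.20, "absolute") # 2
#' @export
rmsd_percent <- function(x_calc, x_exp, mode = c("relative", "absolute", "aard")) {
  mode <- match.arg(mode)
  if (length(x_calc) != length(x_exp)) abort("x_calc and x_exp must have equal length.")
  if (length(x_calc) < 1) abort("need at least one pair.")
  if (mode %in% c("relative", "aard") && any(x_exp <= 0)) {
    abort("relative deviations need strictly positive experimental values.")
  }
  switch(mode,
    relative = 100 * sqrt(mean(((x_calc - x_exp) / x_exp)^2)),
    absolute = 100 * sqrt(mean((x_calc - x_exp)^2)),
    aard = 100 * mean(abs(x_calc - x_exp) / x_exp)
  )
}

#' Fit the Nyvlt solubility correlation
#'
#' Fits \eqn{\log_{10} x = A + B/T + C \log_{10} T} to a solubility
#' dataset. The default objective (`"log10"`) is ordinary least squares in
#' \eqn{\log_{10} x}, which is linear in (A, B, C) and solved in closed
#' form. The alternative `"x"` objective minimizes squared residuals on
#' the solubility scale itself (started from the closed-form solution and
#' polished by quasi-Newton iterations); the two differ only at the level
#' of the residual weighting. The base-10 logarithm is a convention: any
#' other base only rescales the coefficients and leaves predictions
#' unchanged.
#'
#' @param data A solubility dataset (columns `T_K`, `x_mass`), at least
#'   three records at distinct temperatures.
#' @param objective `"log10"` (default) or `"x"`.
#' @return An object of class `nyvlt_fit`: a list with elements `params`
#'   ([nyvlt_params()]), `data`, `fitted`, `objective` and `diagnostics`
#'   (relative/absolute RMSD and AARD, percent). Supports [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @examples
#' fit <- fit_nyvlt(fructose_solubility())
#' glance(fit)
#' @export
fit_nyvlt <- function(data, objective = c("log10", "x")) {
  objective <- match.arg(objective)
  data <- as_solubility_dataset(data, basis_note = attr(data, "basis_note") %||% "mass fraction")
  if (nrow(data) < 3) abort("need at least 3 records to fit the three coefficients.")
  T <- data$T_K; x <- data$x_mass
  X <- cbind(1, 1 / T, log10(T))
  if (qr(X)$rank < 3) abort("rank-deficient design: temperatures do not identify A, B, C.")
  fit0 <- lm.fit(X, log10(x))
  beta <- unname(fit0$coefficients)
  se <- tryCatch({
    s2 <- sum(fit0$residuals^2) / max(fit0$df.residual, 1)
    sqrt(diag(s2 * chol2inv(qr.R(qr(X)))))
  }, error = function(e) rep(NA_real_, 3))
  if (objective == "x") {
    obj <- function(p) sum((10^(p[1] + p[2] / T + p[3] * log10(T)) - x)^2)
    sc <- pmax(abs(beta), c(1, 100, 1))
    o <- optim(beta, obj, method = "BFGS",
               control = list(parscale = sc, reltol = 1e-15, maxit = 500))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(parscale = sc, reltol = 1e-15, maxit = 2000))
    beta <- o$par
    se <- rep(NA_real_, 3)
  }
  params <- nyvlt_params(beta[1], beta[2], beta[3], range(T))
  fitted <- 10^(params$A + params$B / T + params$C * log10(T))
  diagnostics <- tibble::tibble(
    rmsd_relative_percent = rmsd_percent(fitted, x, "relative"),
    rmsd_absolute_percent = rmsd_percent(fitted, x, "absolute"),
    aard_percent = rmsd_percent(fitted, x, "aard")
  )
  structure(
    list(params = params, data = data, fitted = fitted, objective = objective,
         std_error = setNames(se, c("A", "B", "C")), diagnostics = diagnostics),
    class = "nyvlt_fit"
  )
}

#' @export
print.nyvlt_fit <- function(x, ...) {
  cat(sprintf("Nyvlt solubility fit (%s objective, n = %d)\n",
              x$objective, nrow(x$data)))
  print(x$params)
  cat(sprintf("  RMSD(rel) %.3f%%   RMSD(abs) %.3f%%   AARD %.3f%%\n",
              x$diagnostics$rmsd_relative_percent,
              x$diagnostics$rmsd_absolute_percent,
              x$diagnostics$aard_percent))
  invisible(x)
}

#' @export
tidy.nyvlt_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C"),
                 estimate = c(x$params$A, x$params$B, x$params$C),
                 std.error = unname(x$std_error))
}

#' @export
glance.nyvlt_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = nrow(x$data), objective = x$objective,
                   T_min = x$params$T_range[1], T_max = x$params$T_range[2]),
    x$diagnostics
  )
}

#' @export
predict.nyvlt_fit <- function(object, T = NULL, ...) {
  if (is.null(T)) return(object$fitted)
  predict_nyvlt(object$params, T)
}

#' @export
autoplot.nyvlt_fit <- function(object, n_grid = 100, ...) {
  grid <- tibble::tibble(
    T_K = seq(object$params$T_range[1], object$params$T_range[2], length.out = n_grid)
  )
  grid$x_mass <- predict_nyvlt(object$params, grid$T_K)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$T_K, y = .data$x_mass)) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "T (K)", y = "solubility (mass fraction)",
                  title = "Nyvlt correlation fit") +
    ggplot2::theme_minimal()
}
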