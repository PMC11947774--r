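#' Solubility datasets
#'
#' A solubility dataset is a tibble with a temperature column `T_K` (Kelvin)
#' and a composition column `x_mass` (mass fraction of solute, strictly
#' inside (0, 1)), optionally a per-record replicate scatter `sigma`, and a
#' free-text `basis_note` attribute recording the composition basis.
#' `as_solubility_dataset()` validates a plain data frame and stamps the
#' class; row order is preserved.
#'
#' @param data A data frame with columns `T_K`, `x_mass` and optionally
#'   `sigma`.
#' @param basis_note Free-text note on the composition basis.
#' @return A tibble of class `solubility_dataset`.
#' @examples
#' as_solubility_dataset(data.frame(T_K = c(300, 310), x_mass = c(0.2, 0.25)))
#' @export
as_solubility_dataset <- function(data, basis_note = "mass fraction") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(c("T_K", "x_mass"), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("no records: the dataset body is empty.")
  out <- tibble::as_tibble(data[intersect(c("T_K", "x_mass", "sigma"), names(data))])
  bad <- which(!is.finite(out$T_K) | out$T_K <= 0)
  if (length(bad) > 0) {
    abort(sprintf("row %d: temperature must be a positive number (got %s).", bad[1], out$T_K[bad[1]]))
  }
  bad <- which(!is.finite(out$x_mass) | out$x_mass <= 0 | out$x_mass >= 1)
  if (length(bad) > 0) {
    abort(sprintf("row %d: x_mass must lie strictly in (0, 1) (got %s).", bad[1], out$x_mass[bad[1]]))
  }
  dup <- which(duplicated(out$T_K))
  if (length(dup) > 0) {
    abort(sprintf("row %d: duplicate temperature %s K.", dup[1], out$T_K[dup[1]]))
  }
  if ("sigma" %in% names(out) && any(is.finite(out$sigma) & out$sigma < 0)) {
    abort("sigma must be non-negative.")
  }
  attr(out, "basis_note") <- basis_note
  class(out) <- unique(c("solubility_dataset", class(out)))
  out
}

#' Read and write solubility tables
#'
#' The on-disk dialect is plain CSV with a header, columns `T_K,x_mass`
#' and optionally `sigma`, dot decimal separator, UTF-8. Lines starting
#' with `#` are treated as comments (the writer records the basis note
#' that way).
#'
#' @param path Path to a CSV file.
#' @return `read_solubility_table()` returns a validated
#'   [as_solubility_dataset()] tibble; `write_solubility_table()` returns
#'   `path` invisibly.
#' @export
read_solubility_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) abort(sprintf("no records in '%s'.", path))
  missing_cols <- setdiff(c("T_K", "x_mass"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("'%s': missing required column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("row %d: malformed numeric value '%s' in column %s.",
                    bad[1], df[[col]][bad[1]], col))
    }
    v
  }
  out <- tibble::tibble(T_K = to_num("T_K"), x_mass = to_num("x_mass"))
  if ("sigma" %in% names(df)) out$sigma <- to_num("sigma")
  as_solubility_dataset(out, basis_note = sprintf("read from %s", basename(path)))
}

#' @rdname read_solubility_table
#' @param data A solubility dataset (or compatible data frame).
#' @export
write_solubility_table <- function(data, path) {
  data <- as_solubility_dataset(data, basis_note = attr(data, "basis_note") %||% "mass fraction")
  note <- attr(data, "basis_note")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(note)) writeLines(sprintf("# basis: %s", note), con)
  cols <- intersect(c("T_K", "x_mass", "sigma"), names(data))
  writeLines(paste(cols, collapse = ","), con)
  body <- apply(as.matrix(data[cols]), 1L, function(r) {
    paste(formatC(as.numeric(r), format = "g", digits = 15), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
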