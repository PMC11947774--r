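#' Assemble an activity-model configuration
#'
#' A model configuration bundles everything a UNIFAC-family variant needs:
#' the combinatorial flavor, the subgroup table (volume and area parameters
#' R_k, Q_k), the main-group interaction table with a linear temperature
#' dependence `a_mn(T) = a0_mn + a1_mn * (T - T0)`, an optional association
#' block (Wertheim hydrogen-bonding parameters per associating subgroup),
#' and group decompositions for named components. Variants with
#' temperature-independent interactions simply set `a1 = 0`.
#'
#' @param name Model name, e.g. `"UNIFAC"`, `"A-UNIFAC"`, or any custom tag.
#' @param combinatorial One of `"staverman_guggenheim"`, `"larsen_modified"`.
#' @param subgroups Data frame with columns `id`, `main`, `R`, `Q`.
#' @param interactions Data frame with columns `from`, `to`, `a0` and
#'   optionally `a1` (defaults to 0), in Kelvin (`a0`) and dimensionless
#'   (`a1`). Self pairs, when listed, must be zero; they are implied
#'   otherwise. A pair missing at evaluation time is an error, never a
#'   silent zero.
#' @param association Optional data frame with columns `subgroup`, `donors`,
#'   `acceptors`, `eps_over_k` (K) and `kappa` (dimensionless association
#'   volume). `kappa = 0` switches a site off.
#' @param components Named list of named count vectors: the group
#'   decomposition of each component this config knows about.
#' @param T0 Reference temperature (K) of the linear interaction
#'   temperature dependence.
#' @param provenance Free-text citation(s) for the parameter values.
#' @return An object of class `model_config`.
#' @examples
#' model_config(
#'   name = "toy", combinatorial = "staverman_guggenheim",
#'   subgroups = data.frame(id = "U", main = "U", R = 1, Q = 1),
#'   interactions = data.frame(from = "U", to = "U", a0 = 0)
#' )
#' @export
model_config <- function(name,
                         combinatorial = c("staverman_guggenheim", "larsen_modified"),
                         subgroups,
                         interactions = NULL,
                         association = NULL,
                         components = list(),
                         T0 = 298.15,
                         provenance = NULL) {
  combinatorial <- match.arg(combinatorial)
  subgroups <- tibble::as_tibble(subgroups)
  need <- setdiff(c("id", "main", "R", "Q"), names(subgroups))
  if (length(need) > 0) {
    abort(sprintf("subgroup table is missing column(s): %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(subgroups$id)) {
    abort(sprintf("duplicate subgroup id '%s'.", subgroups$id[duplicated(subgroups$id)][1]))
  }
  if (any(subgroups$R <= 0) || any(subgroups$Q <= 0)) {
    abort("all subgroup R and Q parameters must be positive.")
  }
  if (is.null(interactions)) {
    interactions <- tibble::tibble(from = character(), to = character(),
                                   a0 = numeric(), a1 = numeric())
  }
  interactions <- tibble::as_tibble(interactions)
  need <- setdiff(c("from", "to", "a0"), names(interactions))
  if (length(need) > 0) {
    abort(sprintf("interaction table is missing column(s): %s", paste(need, collapse = ", ")))
  }
  if (!"a1" %in% names(interactions)) interactions$a1 <- 0
  mains <- unique(subgroups$main)
  undeclared <- setdiff(unique(c(interactions$from, interactions$to)), mains)
  if (length(undeclared) > 0) {
    abort(sprintf("interaction table references undeclared main group(s): %s",
                  paste(undeclared, collapse = ", ")))
  }
  self <- interactions$from == interactions$to
  if (any(self & (interactions$a0 != 0 | interactions$a1 != 0))) {
    abort("self interactions a_mm must be zero.")
  }
  if (anyDuplicated(paste(interactions$from, interactions$to))) {
    abort("duplicate (from, to) pair in interaction table.")
  }
  if (!is.null(association)) {
    association <- tibble::as_tibble(association)
    need <- setdiff(c("subgroup", "eps_over_k", "kappa"), names(association))
    if (length(need) > 0) {
      abort(sprintf("association table is missing column(s): %s", paste(need, collapse = ", ")))
    }
    if (!"donors" %in% names(association)) association$donors <- 1
    if (!"acceptors" %in% names(association)) association$acceptors <- 1
    absent <- setdiff(association$subgroup, subgroups$id)
    if (length(absent) > 0) {
      abort(sprintf("associating subgroup(s) absent from subgroup table: %s",
                    paste(absent, collapse = ", ")))
    }
    if (any(association$kappa < 0) || any(association$eps_over_k < 0)) {
      abort("association parameters kappa and eps_over_k must be non-negative.")
    }
  }
  if (length(components) > 0) {
    if (is.null(names(components))) abort("`components` must be a named list.")
    for (nm in names(components)) {
      v <- components[[nm]]
      components[[nm]] <- v <- unlist(v)
      if (is.null(names(v)) || !is.numeric(v)) {
        abort(sprintf("group counts of component '%s' must be a named numeric vector.", nm))
      }
      unknown <- setdiff(names(v), subgroups$id)
      if (length(unknown) > 0) {
        abort(sprintf("component '%s' references undeclared subgroup(s): %s",
                      nm, paste(unknown, collapse = ", ")))
      }
      if (any(v < 0) || sum(v) <= 0) {
        abort(sprintf("component '%s': counts must be non-negative with at least one nonzero.", nm))
      }
    }
  }
  structure(
    list(name = name, combinatorial = combinatorial, subgroups = subgroups,
         interactions = interactions, association = association,
         components = components, T0 = T0, provenance = provenance),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s\n", x$name))
  cat(sprintf("  combinatorial: %s\n", x$combinatorial))
  cat(sprintf("  subgroups: %s\n", paste(x$subgroups$id, collapse = ", ")))
  cat(sprintf("  interaction pairs: %d (T0 = %g K)\n", nrow(x$interactions), x$T0))
  if (!is.null(x$association)) {
    cat(sprintf("  associating subgroups: %s\n", paste(x$association$subgroup, collapse = ", ")))
  }
  if (length(x$components) > 0) {
    cat(sprintf("  components: %s\n", paste(names(x$components), collapse = ", ")))
  }
  if (!is.null(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Read and write model configurations
#'
#' Configurations are stored as YAML (or JSON) with sections `name`,
#' `combinatorial`, `T0`, `subgroups`, `interactions`, `association`,
#' `components` (a `group_counts` map per component) and `provenance`.
#' Reading validates every cross-reference; writing then reading
#' round-trips field for field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return `read_model_config()` returns a [model_config()];
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_row_tbl <- function(lst) {
    if (is.null(lst) || length(lst) == 0) return(NULL)
    purrr::map_dfr(lst, function(row) tibble::as_tibble(row))
  }
  comps <- raw$components
  if (!is.null(comps) && !is.null(comps$group_counts)) comps <- comps$group_counts
  cfg <- model_config(
    name = raw$name %||% "custom",
    combinatorial = raw$combinatorial %||% "staverman_guggenheim",
    subgroups = as_row_tbl(raw$subgroups),
    interactions = as_row_tbl(raw$interactions),
    association = as_row_tbl(raw$association),
    components = purrr::map(comps %||% list(), unlist),
    T0 = raw$T0 %||% 298.15,
    provenance = raw$provenance
  )
  cfg
}

#' @rdname read_model_config
#' @param config A [model_config()].
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  tbl_to_rows <- function(tbl) {
    if (is.null(tbl)) return(NULL)
    purrr::pmap(tbl, function(...) list(...))
  }
  out <- list(
    name = config$name,
    combinatorial = config$combinatorial,
    T0 = config$T0,
    provenance = config$provenance,
    subgroups = tbl_to_rows(config$subgroups),
    interactions = tbl_to_rows(config$interactions),
    association = tbl_to_rows(config$association),
    components = list(group_counts = purrr::map(config$components, as.list))
  )
  out <- out[!vapply(out, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Bundled model-variant configurations
#'
#' Loads the parameter files shipped under `extdata/models`. The plain
#' `UNIFAC` file carries the classical published volume, area and
#' interaction parameters for the CH2/OH/ketone groups. The other variant
#' files (`A-UNIFAC`, `Bio-UNIFAC`, `mS-UNIFAC`, `P&M-UNIFAC`) are
#' *reconstructions*: the source publications' tables were not available
#' for verbatim transcription, so these files encode each variant's
#' structure (combinatorial flavor, group set, temperature dependence,
#' association scheme) with parameter values of representative magnitude,
#' as stated in each file's provenance string. Treat their numerical
#' predictions as illustrative, not as the original models.
#'
#' @param name Optional variant name; when given, returns that single
#'   config instead of the full named list.
#' @return A named list of [model_config()] objects, or a single config.
#' @export
bundled_model_configs <- function(name = NULL) {
  dir <- system.file("extdata", "models", package = "glysol")
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  cfgs <- purrr::map(files, read_model_config)
  names(cfgs) <- purrr::map_chr(cfgs, "name")
  cfgs <- cfgs[order(names(cfgs))]
  if (is.null(name)) return(cfgs)
  if (!name %in% names(cfgs)) {
    abort(sprintf("no bundled config named '%s' (have: %s).",
                  name, paste(names(cfgs), collapse = ", ")))
  }
  cfgs[[name]]
}

# Resolve the subgroup decomposition of `comp` under `config`:
# component-supplied counts win (variant-keyed list first, then plain
# vector), then the config's own components block.
resolve_group_counts <- function(comp, config) {
  gc <- comp$group_counts
  counts <- NULL
  if (is.list(gc) && !is.null(gc[[config$name]])) {
    counts <- gc[[config$name]]
  } else if (is.numeric(gc)) {
    counts <- gc
  } else if (!is.null(config$components[[comp$name]])) {
    counts <- config$components[[comp$name]]
  }
  if (is.null(counts)) {
    abort(sprintf("no group decomposition for component '%s' under model '%s'.",
                  comp$name, config$name))
  }
  unknown <- setdiff(names(counts), config$subgroups$id)
  if (length(unknown) > 0) {
    abort(sprintf("component '%s' uses subgroup(s) not in model '%s': %s",
                  comp$name, config$name, paste(unknown, collapse = ", ")))
  }
  counts[counts > 0]
}

# Directional interaction energies a_mn(T) for the given main groups,
# as a dense matrix. Missing off-diagonal pairs are an error.
interaction_matrix <- function(config, mains, T) {
  n <- length(mains)
  a <- matrix(0, n, n, dimnames = list(mains, mains))
  it <- config$interactions
  for (m in mains) {
    for (k in mains) {
      if (m == k) next
      hit <- which(it$from == m & it$to == k)
      if (length(hit) == 0) {
        abort(sprintf("model '%s': missing interaction pair (%s, %s).", config$name, m, k))
      }
      a[m, k] <- it$a0[hit] + it$a1[hit] * (T - config$T0)
    }
  }
  a
}
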