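#' Read a designed-experiment run table
#'
#' CSV schema (one row per run): `run_id`, `packaging` (VBP / NONE / PBP),
#' `rate` (decimal fraction), `response_days` (non-negative; may be empty
#' before measurement). Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return A design tibble with columns `run`, `packaging`, `rate`,
#'   `days`.
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      run_id = readr::col_integer(),
      packaging = readr::col_character(),
      rate = readr::col_double(),
      response_days = readr::col_double()
    )
  ))
  need <- c("run_id", "packaging", "rate", "response_days")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0(
      "design CSV is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed design rows (file line numbers): ",
      paste(unique(probs$row + 1L), collapse = ", ")
    ))
  }
  bad_pack <- which(!raw$packaging %in% packaging_levels)
  if (length(bad_pack)) {
    abort(sprintf(
      "unknown packaging token(s) %s at line(s) %s",
      paste(unique(raw$packaging[bad_pack]), collapse = ", "),
      paste(bad_pack + 1L, collapse = ", ")
    ))
  }
  bad_resp <- which(!is.na(raw$response_days) & raw$response_days < 0)
  if (length(bad_resp)) {
    abort(sprintf("negative response at line(s) %s",
                  paste(bad_resp + 1L, collapse = ", ")))
  }
  tibble(
    run = raw$run_id, packaging = raw$packaging,
    rate = raw$rate, days = raw$response_days
  )
}

#' @rdname read_design_csv
#' @param design a design tibble.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(
    tibble(
      run_id = design$run, packaging = design$packaging,
      rate = design$rate, response_days = design$days
    ),
    path
  )
  invisible(path)
}

#' Read a long-format TMC table
#'
#' Schema: `packaging`, `substrate_code`, `temperature`, `day`,
#' `log_cfu_g`.
#'
#' @param path CSV file path.
#' @return A TMC tibble.
#' @export
read_tmc_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      packaging = readr::col_character(),
      substrate_code = readr::col_character(),
      temperature = readr::col_character(),
      day = readr::col_integer(),
      log_cfu_g = readr::col_double()
    )
  )
  need <- c("packaging", "substrate_code", "temperature", "day", "log_cfu_g")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    abort(paste0(
      "TMC CSV is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  out
}

#' Write / read a fitted quadratic as JSON
#'
#' The JSON carries the response name, coding scheme, rate levels, the six
#' coefficients and the residual degrees of freedom — everything needed to
#' reload the surface and predict from it. Reading returns a `quad_model`;
#' a write/read round trip is the identity on the model.
#'
#' @param model a `quad_model` or `shelf_fit`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  model <- as_quad_model(model)
  jsonlite::write_json(
    list(
      response = model$response,
      coding = model$coding,
      rate_levels = model$rate_spec$levels,
      coefficients = as.list(model$coefficients),
      residual_dof = model$residual_dof
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = unlist(x$coefficients),
      response = x$response,
      coding = x$coding,
      packaging_spec = packaging_spec(),
      rate_spec = factor_spec(
        "rate", as.numeric(x$rate_levels),
        coding = if (x$coding == "range") "range" else "level"
      ),
      residual_dof = as.integer(x$residual_dof)
    ),
    class = "quad_model"
  )
}

#' Write an ANOVA report as CSV
#'
#' Columns `term`, `sum_sq`, `df`, `mean_sq`, `F`, `p`. The R-squared
#' family, PRESS and adequate precision are not part of the row schema;
#' they travel in [glance.shelf_fit()].
#'
#' @param anova a `shelf_anova` table.
#' @param path CSV file path.
#' @export
write_anova_csv <- function(anova, path) {
  out <- as.data.frame(anova)
  names(out) <- c("term", "sum_sq", "df", "mean_sq", "F", "p")
  readr::write_csv(out, path)
  invisible(path)
}

#' Measured shelf-life gains against a reference substrate
#'
#' Differences of measured shelf-life between runs on residue-amended
#' substrates and the straw-only reference under the same packaging, e.g.
#' the published "0.5-1.2 days longer than wheat straw" contrasts.
#'
#' @param design a measured design tibble.
#' @param packaging packaging level under which to compare.
#' @param comparison_rates rates to compare; default all non-reference
#'   rates present under that packaging.
#' @param reference_rate the reference substrate rate (default 0, straw
#'   only). When the reference run is replicated its mean response is
#'   used.
#' @return A tibble with `rate`, `days`, `reference_days`, `gain_days`.
#' @examples
#' shelf_life_gain(study_shelf_life("OLPR_SCG", "ambient"), "PBP")
#' @export
shelf_life_gain <- function(design, packaging, comparison_rates = NULL,
                            reference_rate = 0) {
  sel <- design[design$packaging == packaging, ]
  ref <- sel$days[sel$rate == reference_rate]
  if (length(ref) == 0) {
    abort(sprintf("no reference run at packaging %s, rate %g",
                  packaging, reference_rate))
  }
  if (is.null(comparison_rates)) {
    comparison_rates <- sort(setdiff(unique(sel$rate), reference_rate))
  }
  missing_rates <- setdiff(comparison_rates, sel$rate)
  if (length(missing_rates)) {
    abort(sprintf("no run at packaging %s, rate(s) %s", packaging,
                  paste(missing_rates, collapse = ", ")))
  }
  cmp <- sel[sel$rate %in% comparison_rates, ]
  tibble(
    rate = cmp$rate,
    days = cmp$days,
    reference_days = mean(ref),
    gain_days = cmp$days - mean(ref)
  )
}

#' Run the full storage-trial analysis for one response
#'
#' Fits the quadratic surface to one measured run table, produces the
#' adequacy ANOVA, optimises the surface over the factor box, and (when a
#' TMC table is supplied or the packaged tables are used) summarises
#' consumability windows. Deterministic given the same inputs.
#'
#' @param residue_scheme,temperature which packaged tables to analyse;
#'   ignored when `design` is supplied.
#' @param design optional design tibble to analyse instead of the packaged
#'   tables.
#' @param tmc optional TMC tibble; default the packaged table for
#'   `temperature`.
#' @param coding coding passed to [fit_shelf_life()].
#' @param goal optimisation goal.
#' @param out_dir optional directory; when given, writes `model.json`,
#'   `anova.csv`, `optimization.json` and `tmc_windows.csv` there.
#' @return A list with elements `fit`, `anova`, `optimum`, `tmc_windows`
#'   and `provenance`.
#' @export
run_full_pipeline <- function(residue_scheme = "OLPR", temperature = "ambient",
                              design = NULL, tmc = NULL,
                              coding = c("level", "range"),
                              goal = c("maximize", "minimize"),
                              out_dir = NULL) {
  coding <- match.arg(coding)
  goal <- match.arg(goal)
  if (is.null(design)) design <- study_shelf_life(residue_scheme, temperature)
  if (is.null(tmc)) tmc <- study_tmc(temperature)
  fit <- fit_shelf_life(design, coding = coding)
  an <- anova_shelf(fit)
  opt <- optimize_shelf_life(fit, goal = goal)
  windows <- consumability_window(tmc)
  prov <- list(
    package = "shelfrsm",
    version = as.character(utils::packageVersion("shelfrsm")),
    residue_scheme = residue_scheme,
    temperature = temperature,
    coding = coding,
    goal = goal,
    n_runs = nrow(design)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_json(fit, file.path(out_dir, "model.json"))
    write_anova_csv(an, file.path(out_dir, "anova.csv"))
    jsonlite::write_json(c(as.list(opt), prov),
                         file.path(out_dir, "optimization.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(windows, file.path(out_dir, "tmc_windows.csv"))
  }
  list(fit = fit, anova = an, optimum = opt, tmc_windows = windows,
       provenance = prov)
}
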