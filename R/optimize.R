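#' Optimise storage conditions over the admissible factor box
#'
#' Maximises (or minimises) the fitted shelf-life surface over the
#' packaging levels and a closed rate interval. Packaging is enumerated —
#' it is a physical type, never interpolated — and for each admissible
#' level the fitted surface restricted to that level is a quadratic in the
#' actual rate (see [actual_rate_poly()]), optimised analytically: the
#' interior vertex when it lies in bounds and curves the right way,
#' otherwise the better endpoint. A dense grid scan (step `grid_step`)
#' verifies the analytic answer.
#'
#' @param fit a `shelf_fit` or `quad_model`.
#' @param goal `"maximize"` or `"minimize"` the predicted response.
#' @param rate_range closed interval for the rate; default the fitted level
#'   range.
#' @param packaging admissible packaging levels; default all three.
#' @param grid_step rate step of the verification grid (default 0.001).
#' @return A one-row tibble: `packaging`, `rate`, `predicted`,
#'   `desirability` and `method`. Attribute `candidates` holds the
#'   per-packaging optima; attribute `trace` a text account of the search.
#' @examples
#' fit <- fit_shelf_life(study_shelf_life("OLPR", "ambient"))
#' optimize_shelf_life(fit)
#' @export
optimize_shelf_life <- function(fit, goal = c("maximize", "minimize"),
                                rate_range = NULL, packaging = NULL,
                                grid_step = 0.001) {
  goal <- match.arg(goal)
  model <- as_quad_model(fit)
  lvl_range <- range(model$rate_spec$levels)
  if (is.null(rate_range)) rate_range <- lvl_range
  if (length(rate_range) != 2 || rate_range[1] >= rate_range[2]) {
    abort("`rate_range` must be an interval [min, max] with min < max")
  }
  if (rate_range[1] < lvl_range[1] || rate_range[2] > lvl_range[2]) {
    abort("`rate_range` must lie within the fitted rate range")
  }
  if (is.null(packaging)) packaging <- packaging_levels
  if (!all(packaging %in% packaging_levels)) {
    abort("`packaging` must be a subset of VBP, NONE, PBP")
  }
  sign <- if (goal == "maximize") 1 else -1

  best_in_level <- function(p) {
    a <- actual_rate_poly(model, p)
    cand <- rate_range
    vertex <- if (a[["a2"]] != 0) -a[["a1"]] / (2 * a[["a2"]]) else NA_real_
    # interior stationary point only counts when it is the right kind
    if (!is.na(vertex) && sign * a[["a2"]] < 0 &&
        vertex > rate_range[1] && vertex < rate_range[2]) {
      cand <- c(cand, vertex)
    }
    val <- a[["a0"]] + a[["a1"]] * cand + a[["a2"]] * cand^2
    i <- which.max(sign * val)
    tibble(packaging = p, rate = cand[i], predicted = val[i])
  }
  candidates <- purrr::map_dfr(setNames(nm = packaging), best_in_level)
  i <- which.max(sign * candidates$predicted)
  out <- candidates[i, ]

  # dense-grid verification of the analytic optimum
  grid <- surface_grid(
    model,
    rate_steps = max(2L, ceiling(diff(rate_range) / grid_step)),
    packaging = packaging, rate_range = rate_range
  )
  grid_best <- max(sign * grid$predicted)
  if (sign * out$predicted < grid_best - 1e-8) {
    abort("internal error: analytic optimum below the grid scan")
  }

  lo <- min(grid$predicted); hi <- max(grid$predicted)
  out$desirability <- if (hi > lo) {
    desirability(out$predicted, goal, lo, hi)
  } else 1
  out$method <- sprintf(
    "analytic per-level quadratic %s over rate in [%g, %g], grid-verified at step %g",
    goal, rate_range[1], rate_range[2], grid_step
  )
  attr(out, "candidates") <- candidates
  attr(out, "trace") <- sprintf(
    "enumerated packaging {%s}; per-level optima: %s; selected %s",
    paste(packaging, collapse = ", "),
    paste(sprintf("%s %.3f d at rate %.3f", candidates$packaging,
                  candidates$predicted, candidates$rate), collapse = "; "),
    out$packaging
  )
  out
}

#' Derringer desirability ramp
#'
#' Maps a response value onto \[0, 1\] for a one-sided goal: for
#' `"maximize"`, 0 at or below `low`, 1 at or above `high`, linear in
#' between; mirrored for `"minimize"`.
#'
#' @param value response value(s) in days.
#' @param goal `"maximize"` or `"minimize"`.
#' @param low,high ramp anchors with `low < high`.
#' @return Desirability in \[0, 1\].
#' @examples
#' desirability(7.5, "maximize", low = 5, high = 10)
#' @export
desirability <- function(value, goal = c("maximize", "minimize"), low, high) {
  goal <- match.arg(goal)
  if (low >= high) abort("`low` must be strictly less than `high`")
  d <- pmin(1, pmax(0, (value - low) / (high - low)))
  if (goal == "minimize") 1 - d else d
}

#' Prediction grid over the factor box
#'
#' Rectangular grid of predicted shelf-life over packaging levels and a
#' monotone rate axis; the raw material behind surface and contour plots.
#'
#' @param fit a `shelf_fit` or `quad_model`.
#' @param rate_steps number of rate intervals (>= 2).
#' @param packaging packaging levels to include.
#' @param rate_range rate interval; default the fitted level range.
#' @return A tibble with `packaging`, `packaging_code`, `rate`,
#'   `predicted`.
#' @export
surface_grid <- function(fit, rate_steps = 50, packaging = packaging_levels,
                         rate_range = NULL) {
  model <- as_quad_model(fit)
  if (rate_steps < 2) abort("`rate_steps` must be at least 2")
  if (is.null(rate_range)) rate_range <- range(model$rate_spec$levels)
  rates <- seq(rate_range[1], rate_range[2], length.out = rate_steps + 1)
  grid <- tidyr::expand_grid(packaging = packaging, rate = rates)
  grid$packaging_code <- code_factor(grid$packaging, model$packaging_spec)
  grid$predicted <- predict(model, grid)
  grid[, c("packaging", "packaging_code", "rate", "predicted")]
}
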