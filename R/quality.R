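#' Percent weight loss during storage
#'
#' `100 * (W0 - Wt) / W0`. Mass gain is not modelled: `Wt > W0` is an
#' error.
#'
#' @param w0 initial weight in g (> 0).
#' @param wt weight at the observation day in g (0 < wt <= w0).
#' @return Weight loss in percent.
#' @examples
#' weight_loss(100, 95)
#' @export
weight_loss <- function(w0, wt) {
  if (any(w0 <= 0) || any(wt <= 0)) abort("weights must be positive")
  if (any(wt > w0)) abort("`wt` exceeds `w0`: mass gain is not modelled")
  100 * (w0 - wt) / w0
}

#' Veil-opening metric
#'
#' Computed exactly as published: `100 * (Vt - Vf) / Vt` where `Vt` is the
#' total number of partial veils and `Vf` the number of open veils. Note
#' that as printed this is the percentage of veils NOT open, even though
#' the study narrative treats rising values as deterioration; the
#' complementary fraction is available via `convention = "opened"`.
#'
#' @param vt total veil count (>= 1).
#' @param vf open veil count (0 <= vf <= vt).
#' @param convention `"printed"` (the published formula, default) or
#'   `"opened"` (its complement `100 * Vf / Vt`).
#' @return Percentage in \[0, 100\].
#' @examples
#' veil_opening(10, 3)
#' @export
veil_opening <- function(vt, vf, convention = c("printed", "opened")) {
  convention <- match.arg(convention)
  if (any(vt < 1)) abort("`vt` must be at least 1")
  if (any(vf < 0) || any(vf > vt)) abort("`vf` must satisfy 0 <= vf <= vt")
  printed <- 100 * (vt - vf) / vt
  if (convention == "opened") 100 - printed else printed
}

#' Consumability flags from quality measurements
#'
#' Applies the storage-quality acceptability rules: weight loss of at most
#' 5 percent (inclusive, "around 5%"), instrumented firmness score of at
#' least 3.0 on the 1-9 scale, and a veil-opening metric below 70 percent.
#' The overall flag is the conjunction. The veil rule is evaluated on the
#' published veil metric (see [veil_opening()]); the
#' `veil_metric_convention` attribute of the result records which
#' convention was used.
#'
#' @param data a tibble with columns `w0`, `wt`, `firmness`, `veils_total`,
#'   `veils_open` (and any identifying columns, which are carried through).
#' @param veil_convention passed to [veil_opening()].
#' @return The input with `weight_loss_pct`, `veil_opening_pct`,
#'   `weight_ok`, `firmness_ok`, `veil_ok` and `overall` columns appended.
#' @examples
#' acceptability(tibble::tibble(
#'   w0 = 100, wt = 95.1, firmness = 3.3, veils_total = 10, veils_open = 4
#' ))
#' @export
acceptability <- function(data, veil_convention = c("printed", "opened")) {
  veil_convention <- match.arg(veil_convention)
  need <- c("w0", "wt", "firmness", "veils_total", "veils_open")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(data$firmness < 1 | data$firmness > 9)) {
    abort("firmness scores must lie on the 1-9 scale")
  }
  out <- data |>
    mutate(
      weight_loss_pct = weight_loss(.data$w0, .data$wt),
      veil_opening_pct = veil_opening(.data$veils_total, .data$veils_open,
                                      convention = veil_convention),
      weight_ok = .data$weight_loss_pct <= 5.0,
      firmness_ok = .data$firmness >= 3.0,
      veil_ok = .data$veil_opening_pct < 70.0,
      overall = .data$weight_ok & .data$firmness_ok & .data$veil_ok
    )
  attr(out, "veil_metric_convention") <- veil_convention
  out
}
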