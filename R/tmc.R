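#' Classify total microbial counts into contamination bands
#'
#' Aerobic plate counts in log10 CFU/g are graded into four contamination
#' bands: low (< 5.0), medium (5.0 to 6.5), high (above 6.5 up to 8.05) and
#' very high (above 8.05). The published band edges leave gaps between 5.0
#' and 5.1 and between 8.0 and 8.1 at the one-decimal resolution of the
#' data; the low/medium edge is closed at 5.0 (a reading of exactly 5.0 log
#' CFU/g is medium) and the high/very-high edge at the 8.05 midpoint, the
#' closure under which every one-decimal reading classifies uniquely and
#' the published day-by-day band fractions are reproduced exactly.
#'
#' @param tmc numeric vector of counts in log10 CFU/g (>= 0).
#' @return An ordered factor with levels `low < medium < high < very_high`.
#' @examples
#' classify_tmc(c(4.9, 5.0, 6.6, 8.2))
#' @export
classify_tmc <- function(tmc) {
  if (any(is.na(tmc)) || any(tmc < 0)) {
    abort("TMC values must be non-negative log10 CFU/g")
  }
  lv <- cut(tmc,
    breaks = c(-Inf, tmc_band_edges, Inf),
    labels = c("low", "medium", "high", "very_high"),
    right = FALSE, ordered_result = TRUE
  )
  # cut() with right = FALSE puts 6.5 in "high" and 8.05 in "very_high";
  # the bands are left-open there, so reassign the two edge cases.
  lv[tmc == tmc_band_edges[2]] <- "medium"
  lv[tmc == tmc_band_edges[3]] <- "high"
  lv
}

tmc_band_edges <- c(5.0, 6.5, 8.05)

#' Log-transform colony counts
#'
#' @param cfu counts in CFU/g, strictly positive.
#' @return log10 CFU/g.
#' @export
log_cfu <- function(cfu) {
  if (any(is.na(cfu)) || any(cfu <= 0)) abort("CFU counts must be positive")
  log10(cfu)
}

#' Summarise contamination bands on a storage day
#'
#' Counts and fractions of each contamination band across the selected
#' series on one storage day, together with the min-max range of the
#' selected counts.
#'
#' @param data long-format TMC tibble with columns `packaging`,
#'   `substrate_code`, `temperature`, `day`, `log_cfu_g` (see
#'   [study_tmc()]).
#' @param day storage day, which must be observed in every selected series.
#' @param packaging optional packaging filter (e.g. `c("PBP", "VBP")` for
#'   packed mushrooms); default all.
#' @return A tibble with one row per contamination band: `level`, `n`,
#'   `fraction` (summing to 1), `tmc_min`, `tmc_max`.
#' @examples
#' tmc <- study_tmc("ambient")
#' tmc_level_summary(tmc, day = 3, packaging = c("PBP", "VBP"))
#' @export
tmc_level_summary <- function(data, day, packaging = NULL) {
  if (!is.null(packaging)) data <- data[data$packaging %in% packaging, ]
  if (nrow(data) == 0) abort("no series selected")
  missing_day <- data |>
    summarise(has = any(.data$day == !!day),
              .by = c("packaging", "substrate_code", "temperature")) |>
    filter(!.data$has)
  if (nrow(missing_day) > 0) {
    abort(sprintf(
      "day %d is not observed in series: %s", day,
      paste(missing_day$packaging, missing_day$substrate_code,
            sep = "/", collapse = ", ")
    ))
  }
  sel <- data[data$day == day, ]
  sel$level <- classify_tmc(sel$log_cfu_g)
  sel |>
    summarise(
      n = dplyr::n(),
      tmc_min = min(.data$log_cfu_g),
      tmc_max = max(.data$log_cfu_g),
      .by = "level"
    ) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(.data$level) |>
    select("level", "n", "fraction", "tmc_min", "tmc_max")
}

#' Consumability window of a stored batch
#'
#' The last observed storage day on which a series is still consumable:
#' counts above the threshold (8.1 log10 CFU/g by default, the level above
#' which batches are ranked unfavourable) end the window, and once it is
#' exceeded later dips below the threshold do not reopen it.
#'
#' @param data long-format TMC tibble; one or more series.
#' @param threshold consumability threshold in log10 CFU/g.
#' @return A tibble with one row per series (`packaging`,
#'   `substrate_code`, `temperature`) and `last_day`, the largest observed
#'   day with all counts up to and including it at or below the threshold
#'   (`NA` when the series starts above it).
#' @examples
#' consumability_window(study_tmc("cold_4C"))
#' @export
consumability_window <- function(data, threshold = 8.1) {
  if (nrow(data) == 0) abort("empty TMC table")
  data |>
    arrange(.data$day) |>
    summarise(
      last_day = {
        ok <- cumsum(.data$log_cfu_g > threshold) == 0
        if (any(ok)) max(.data$day[ok]) else NA_real_
      },
      .by = c("packaging", "substrate_code", "temperature")
    )
}

#' Packaged total-microbial-count tables
#'
#' The storage-trial TMC observations shipped with the package as long
#' CSVs: 27 series (3 packaging conditions x 9 substrate codes) observed on
#' 11 days per temperature. Substrate codes follow the study: M1 = wheat
#' straw/olive pruning residue mixtures, M2 = spent coffee ground mixtures,
#' M3 = combined mixtures; A is the straw-only control, B the low and C the
#' high residue rate. One ambient reading (M3A, no packaging, day 6) is
#' printed in the source table with a misplaced decimal ("103"); the
#' fixture records it as 10.3, the value consistent with the surrounding
#' trajectory.
#'
#' @param temperature `"ambient"` or `"cold_4C"`.
#' @return A tibble with columns `packaging`, `substrate_code`,
#'   `temperature`, `day`, `log_cfu_g`.
#' @export
study_tmc <- function(temperature = c("ambient", "cold_4C")) {
  temperature <- match.arg(temperature)
  file <- c(ambient = "tmc_ambient.csv", cold_4C = "tmc_cold_4C.csv")[[temperature]]
  path <- system.file("extdata", file, package = "shelfrsm", mustWork = TRUE)
  read_tmc_csv(path)
}
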