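#' Build the 13-run shelf-life design
#'
#' Constructs the replicated 3x3 layout used for every shelf-life response:
#' the full crossing of packaging type (VBP, none, PBP) with three residue
#' incorporation rates, with the (no packaging, rate 0) point run five times
#' in total (runs 1 and 10-13), giving 13 runs, 9 distinct settings and 4
#' pure-error degrees of freedom. Although described as a central composite
#' design, the layout has no axial points beyond the 3x3 grid and the
#' replicated point is a corner, not the geometric centre; it is built
#' exactly as run, not as a textbook CCD.
#'
#' @param residue_scheme which residue mixture the rate refers to: olive
#'   pruning residues (`"OLPR"`), spent coffee grounds (`"SCG"`), or the
#'   combined mixture (`"OLPR_SCG"`). OLPR and SCG use rate levels
#'   0 / 0.3 / 0.7; the combined scheme uses 0 / 0.17 / 0.33.
#' @return A tibble with columns `run`, `packaging`, `rate` and an all-`NA`
#'   `days` column ready to receive measured responses.
#' @examples
#' shelf_life_design("OLPR")
#' @export
shelf_life_design <- function(residue_scheme = c("OLPR", "SCG", "OLPR_SCG")) {
  residue_scheme <- match.arg(residue_scheme)
  rates <- rate_levels(residue_scheme)
  pack <- c("NONE", "NONE", "NONE", "PBP", "PBP", "PBP",
            "VBP", "VBP", "VBP", "NONE", "NONE", "NONE", "NONE")
  lvl <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 1, 1, 1)
  tibble(
    run = 1:13,
    packaging = pack,
    rate = rates[lvl],
    days = NA_real_
  )
}

rate_levels <- function(residue_scheme) {
  switch(residue_scheme,
    OLPR = c(0, 0.3, 0.7),
    SCG = c(0, 0.3, 0.7),
    OLPR_SCG = c(0, 0.17, 0.33),
    abort(sprintf("unknown residue scheme '%s'", residue_scheme))
  )
}

#' Group runs that share identical factor settings
#'
#' Replicate groups underlie the pure-error decomposition of the residual:
#' runs with identical packaging and rate settings form one group. In the
#' study layout one group has five members and the other eight are
#' singletons.
#'
#' @param design a design tibble with `packaging` and `rate` columns.
#' @return A tibble with one row per run: `run`, the factor settings, and a
#'   `group` id shared by replicates.
#' @export
replicate_groups <- function(design) {
  if (nrow(design) == 0) abort("design has no runs")
  design |>
    mutate(group = dplyr::cur_group_id(), .by = c("packaging", "rate")) |>
    select(any_of("run"), "packaging", "rate", "group")
}

#' Measured shelf-life data from the packaged study tables
#'
#' Loads one of the six transcribed run tables (three residue schemes at
#' each of two storage temperatures) shipped with the package as plain CSV.
#'
#' @inheritParams shelf_life_design
#' @param temperature `"ambient"` (20 degrees C) or `"cold_4C"`.
#' @return A 13-run tibble with columns `run`, `packaging`, `rate`, `days`.
#' @examples
#' study_shelf_life("OLPR", "ambient")
#' @export
study_shelf_life <- function(residue_scheme = c("OLPR", "SCG", "OLPR_SCG"),
                             temperature = c("ambient", "cold_4C")) {
  residue_scheme <- match.arg(residue_scheme)
  temperature <- match.arg(temperature)
  file <- sprintf(
    "shelflife_%s_%s.csv",
    c(ambient = "ambient", cold_4C = "cold4c")[[temperature]],
    tolower(residue_scheme)
  )
  path <- system.file("extdata", file, package = "shelfrsm", mustWork = TRUE)
  read_design_csv(path)
}
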