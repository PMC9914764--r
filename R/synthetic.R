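#' Simulate designed-experiment shelf-life responses
#'
#' Generates responses on a design layout from a known quadratic surface
#' plus i.i.d. Gaussian noise, emulating the structure of the storage
#' trials: a replicated 3x3 layout with run-to-run noise on the order of
#' the replicate standard deviation observed in the trials (about 0.2
#' days).
#'
#' @param layout a design tibble (e.g. [shelf_life_design()]); any
#'   existing response column is overwritten.
#' @param beta named coefficient vector `c(b0, b1, b2, b12, b11, b22)` of
#'   the true surface on the coded basis.
#' @param noise_sd standard deviation of the response noise in days
#'   (>= 0); default 0.2.
#' @param coding coding under which `beta` is interpreted.
#' @param seed integer seed; the same seed reproduces the table exactly.
#'   Randomness is scoped locally and does not disturb the global stream.
#' @return The layout with a simulated `days` column.
#' @examples
#' truth <- c(b0 = 4, b1 = 2, b2 = 0.5, b12 = -0.2, b11 = 1, b22 = -1)
#' sim <- simulate_design(shelf_life_design("OLPR"), truth, noise_sd = 0, seed = 1)
#' @export
simulate_design <- function(layout, beta, noise_sd = 0.2,
                            coding = c("level", "range"), seed = NULL) {
  coding <- match.arg(coding)
  stopifnot(all(c("packaging", "rate") %in% names(layout)))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  nm <- c("b0", "b1", "b2", "b12", "b11", "b22")
  if (!all(nm %in% names(beta))) {
    abort(paste0("`beta` must be named with: ", paste(nm, collapse = ", ")))
  }
  pack_spec <- packaging_spec()
  rate_spec <- factor_spec("rate", sort(unique(layout$rate)),
                           coding = if (coding == "range") "range" else "level")
  x1 <- code_factor(layout$packaging, pack_spec)
  x2 <- code_factor(layout$rate, rate_spec)
  mu <- beta[["b0"]] + beta[["b1"]] * x1 + beta[["b2"]] * x2 +
    beta[["b12"]] * x1 * x2 + beta[["b11"]] * x1^2 + beta[["b22"]] * x2^2
  eps <- local_rng(seed, rnorm(length(mu), 0, noise_sd))
  out <- as_tibble(layout)
  out$days <- mu + eps
  out
}

#' Simulate a total-microbial-count trajectory
#'
#' Counts grow linearly in storage time on the log10 scale with Gaussian
#' noise; noise is applied before a cumulative-maximum projection, so
#' trajectories are non-decreasing with occasional plateaus, like the
#' observed series. Values are rounded to one decimal, the resolution of
#' the plate-count tables.
#'
#' @param days strictly increasing integer vector of observation days.
#' @param intercept log10 CFU/g at day 0 (harvest contamination; about
#'   2.5-4 in the trials).
#' @param daily_increase growth in log10 CFU/g per day (>= 0).
#' @param noise_sd observation noise on the log scale; default 0.15.
#' @param seed integer seed (locally scoped).
#' @return A tibble with columns `day` and `log_cfu_g`.
#' @export
simulate_tmc <- function(days, intercept, daily_increase, noise_sd = 0.15,
                         seed = NULL) {
  if (is.unsorted(days, strictly = TRUE)) {
    abort("`days` must be strictly increasing")
  }
  if (daily_increase < 0) abort("`daily_increase` must be >= 0")
  raw <- intercept + daily_increase * days +
    local_rng(seed, rnorm(length(days), 0, noise_sd))
  tibble(day = days, log_cfu_g = round(pmax(cummax(raw), 0), 1))
}

#' Simulate a physicochemical quality series
#'
#' Weight decays geometrically (`Wt = W0 (1 - loss_fraction)^day`),
#' firmness decays linearly on the 1-9 score floored at 1, and the number
#' of open veils increases stochastically towards the total.
#'
#' @param days integer observation days.
#' @param w0 initial weight in g.
#' @param loss_fraction daily fractional weight loss in \[0, 1); default
#'   0.03 (roughly the unpacked ambient regime).
#' @param firmness0 firmness score at harvest (default 9, "very firm").
#' @param firmness_decay score lost per day (default 0.6).
#' @param veils_total total veil count per batch (default 10).
#' @param open_rate expected fraction of veils newly opening per day
#'   (default 0.08).
#' @param seed integer seed (locally scoped).
#' @return A tibble of quality records: `day`, `w0`, `wt`, `firmness`,
#'   `veils_total`, `veils_open`.
#' @export
simulate_quality <- function(days, w0 = 100, loss_fraction = 0.03,
                             firmness0 = 9, firmness_decay = 0.6,
                             veils_total = 10, open_rate = 0.08,
                             seed = NULL) {
  if (loss_fraction < 0 || loss_fraction >= 1) {
    abort("`loss_fraction` must be in [0, 1)")
  }
  p_open <- pmin(1, open_rate * days)
  opened <- local_rng(
    seed,
    cummax(stats::rbinom(length(days), veils_total, p_open))
  )
  tibble(
    day = days,
    w0 = w0,
    wt = w0 * (1 - loss_fraction)^days,
    firmness = pmax(1, firmness0 - firmness_decay * days),
    veils_total = veils_total,
    veils_open = opened
  )
}

# Evaluate `expr` under a locally seeded RNG stream; the global stream is
# untouched. With seed = NULL the current stream is used (still restored).
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}
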