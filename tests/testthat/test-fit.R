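test_that("the fitted surface reproduces the published predicted values", {
  amb <- fit_shelf_life(study_shelf_life("OLPR", "ambient"))
  p <- function(fit, pack, rate) {
    predict(fit, tibble::tibble(packaging = pack, rate = rate))
  }
  expect_equal(p(amb, "NONE", 0.3), 4.32, tolerance = TOL$predicted_days_tight)
  expect_equal(p(amb, "PBP", 0.3), 8.81, tolerance = TOL$predicted_days_tight)
  expect_equal(p(amb, "VBP", 0), 7.14, tolerance = TOL$predicted_days)
  cold <- fit_shelf_life(study_shelf_life("OLPR", "cold_4C"))
  expect_equal(p(cold, "NONE", 0.3), 7.46, tolerance = TOL$predicted_days_tight)
  # the coded origin (no packaging, middle rate) predicts the intercept
  expect_equal(p(amb, "NONE", 0.3),
               unname(amb$model$coefficients[["b0"]]))
})

test_that("QR solution equals the brute-force normal-equations oracle", {
  for (fx in all_fixture_fits()) {
    beta_ne <- normal_equations_fit(fx$fit$X, fx$design$days)
    expect_equal(unname(fx$fit$model$coefficients), unname(beta_ne),
                 tolerance = TOL$exact)
    # residuals orthogonal to every model column
    expect_lt(max(abs(crossprod(fx$fit$X, fx$fit$residuals))), 1e-9)
    # leverages are a projection diagonal: in (0,1], summing to p
    expect_equal(sum(fx$fit$leverages), 6, tolerance = 1e-9)
    expect_true(all(fx$fit$leverages > 0 & fx$fit$leverages <= 1))
  }
})

test_that("noiseless synthetic data returns the generating coefficients", {
  layout <- shelf_life_design("OLPR")
  set.seed(101)
  for (i in 1:100) {
    truth <- random_true_beta()
    d <- simulate_design(layout, truth, noise_sd = 0)
    fit <- fit_shelf_life(d)
    expect_equal(fit$model$coefficients[names(truth)], truth,
                 tolerance = TOL$exact)
  }
})

test_that("fitted values are invariant to the rate coding scheme", {
  for (fx in all_fixture_fits()) {
    f_level <- fx$fit
    f_range <- fit_shelf_life(fx$design, coding = "range")
    # full model: the interaction column differs between codings, but on
    # these layouts the fitted values move by well under the print precision
    expect_lt(max(abs(f_level$fitted - f_range$fitted)), 0.05)
    # without the interaction column the codings span the same space exactly
    r_level <- qr.resid(qr(f_level$X[, -4]), fx$design$days)
    r_range <- qr.resid(qr(f_range$X[, -4]), fx$design$days)
    expect_equal(r_level, r_range, tolerance = 1e-9)
  }
})

test_that("the coefficient report is complete, ordered and reorder-invariant", {
  d <- study_shelf_life("OLPR", "ambient")
  rep1 <- coefficients_report(fit_shelf_life(d))
  expect_identical(nrow(rep1), 6L)
  expect_identical(attr(rep1, "coding"), "level")
  # the interaction is the smallest coefficient in magnitude for this fit
  slopes <- rep1$estimate[rep1$term != "(Intercept)"]
  expect_equal(
    rep1$term[rep1$term != "(Intercept)"][which.min(abs(slopes))],
    "packaging:rate"
  )
  shuffled <- d[sample(nrow(d)), ]
  rep2 <- coefficients_report(fit_shelf_life(shuffled))
  expect_equal(rep1, rep2, ignore_attr = TRUE)
})

test_that("degenerate inputs fail with informative errors", {
  d <- study_shelf_life("OLPR", "ambient")
  # constant packaging makes the packaging columns collinear
  flat <- dplyr::mutate(d, packaging = "NONE")
  expect_error(fit_shelf_life(flat), "singular design.*b1")
  expect_error(fit_shelf_life(d[1:5, ]), "at least 7 runs")
  expect_error(fit_shelf_life(dplyr::mutate(d, days = -days)), ">= 0")
  fit <- fit_shelf_life(d)
  expect_error(
    predict(fit, tibble::tibble(packaging = "BAG", rate = 0.3)),
    "unknown packaging"
  )
  expect_warning(
    predict(fit, tibble::tibble(packaging = "PBP", rate = 0.8)),
    "extrapolation"
  )
  # a symmetric pure-quadratic response keeps only b0 and b22
  sym <- shelf_life_design("OLPR")
  x2 <- code_factor(sym$rate, factor_spec("rate", c(0, 0.3, 0.7)))
  sym$days <- 2 + x2^2
  b <- fit_shelf_life(sym)$model$coefficients
  expect_equal(unname(b[c("b1", "b2", "b12", "b11")]), rep(0, 4),
               tolerance = 1e-10)
  expect_equal(unname(b[["b22"]]), 1, tolerance = 1e-10)
})

test_that("a model survives a JSON write/read round trip", {
  fit <- fit_shelf_life(study_shelf_life("SCG", "cold_4C"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, fit$model$coefficients)
  expect_identical(back$coding, fit$model$coding)
  expect_equal(back$rate_spec$levels, fit$model$rate_spec$levels)
  expect_identical(back$residual_dof, fit$model$residual_dof)
  newpts <- tibble::tibble(packaging = c("VBP", "PBP"), rate = c(0.1, 0.55))
  expect_equal(predict(back, newpts), predict(fit, newpts))
})
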