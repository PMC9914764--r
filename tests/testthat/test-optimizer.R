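test_that("the analytic optimum agrees with a dense grid on every fixture fit", {
  for (fx in all_fixture_fits()) {
    opt <- optimize_shelf_life(fx$fit)
    grid <- surface_grid(fx$fit, rate_steps = 700)
    best <- grid[which.max(grid$predicted), ]
    step <- diff(sort(unique(grid$rate)))[1]
    expect_identical(opt$packaging, best$packaging)
    expect_lte(abs(opt$rate - best$rate), step + 1e-12)
    expect_gte(opt$predicted, best$predicted - 1e-9)
    # sanity: the optimum is not far below the best measured run
    resid_rms <- sqrt(mean(fx$fit$residuals^2))
    expect_gte(opt$predicted, max(fx$design$days) - 2 * resid_rms)
  }
})

test_that("the analytic optimum agrees with the grid on random quadratics", {
  layout <- shelf_life_design("OLPR")
  set.seed(11)
  for (i in 1:100) {
    d <- simulate_design(layout, random_true_beta(), noise_sd = 0.2)
    fit <- fit_shelf_life(d)
    opt <- optimize_shelf_life(fit)
    grid <- surface_grid(fit, rate_steps = 700)
    expect_gte(opt$predicted, max(grid$predicted) - 1e-9)
  }
})

test_that("an inert packaging factor leaves a pure rate vertex", {
  # response y = -(rate - 0.2)^2 + 5 regardless of packaging
  d <- shelf_life_design("OLPR")
  d$days <- -(d$rate - 0.2)^2 + 5
  opt <- optimize_shelf_life(fit_shelf_life(d))
  expect_equal(opt$rate, 0.2, tolerance = 1e-8)
  expect_equal(opt$predicted, 5, tolerance = 1e-8)
  # every packaging level attains the same maximum
  cand <- attr(opt, "candidates")
  expect_equal(cand$predicted, rep(5, 3), tolerance = 1e-8)
})

test_that("optima in actual units are invariant to the coding scheme", {
  for (fx in all_fixture_fits()) {
    o1 <- optimize_shelf_life(fit_shelf_life(fx$design, coding = "level"))
    o2 <- optimize_shelf_life(fit_shelf_life(fx$design, coding = "range"))
    expect_identical(o1$packaging, o2$packaging)
    expect_lte(abs(o1$rate - o2$rate), TOL$rate)
  }
})

test_that("goals, bounds and minimisation behave as specified", {
  fit <- fit_shelf_life(study_shelf_life("OLPR", "ambient"))
  narrow <- optimize_shelf_life(fit, rate_range = c(0, 0.1))
  expect_lte(narrow$rate, 0.1)
  worst <- optimize_shelf_life(fit, goal = "minimize")
  best <- optimize_shelf_life(fit)
  expect_lt(worst$predicted, best$predicted)
  only_vbp <- optimize_shelf_life(fit, packaging = "VBP")
  expect_identical(only_vbp$packaging, "VBP")
  expect_error(optimize_shelf_life(fit, rate_range = c(0.5, 0.2)), "interval")
  expect_error(optimize_shelf_life(fit, rate_range = c(0, 2)), "within")
  expect_error(optimize_shelf_life(fit, packaging = "BOX"), "subset")
})

test_that("the desirability ramp is the Derringer one-sided transform", {
  expect_equal(desirability(10, "maximize", 5, 10), 1)
  expect_equal(desirability(5, "maximize", 5, 10), 0)
  expect_equal(desirability(7.5, "maximize", 5, 10), 0.5)
  expect_equal(desirability(12, "maximize", 5, 10), 1)  # clipped
  expect_equal(desirability(5, "minimize", 5, 10), 1)
  expect_equal(desirability(7.5, "minimize", 5, 10), 0.5)
  expect_error(desirability(1, "maximize", 10, 5), "strictly less")
})

test_that("the surface grid is rectangular, monotone and pointwise exact", {
  fit <- fit_shelf_life(study_shelf_life("SCG", "ambient"))
  g <- surface_grid(fit, rate_steps = 2, packaging = c("PBP", "VBP"))
  expect_identical(nrow(g), 6L)  # 2 packaging x 3 rate points
  expect_true(all(diff(unique(g$rate)) > 0))
  expect_equal(
    g$predicted,
    predict(fit, g[, c("packaging", "rate")])
  )
  # constant model -> constant grid
  flat <- shelf_life_design("OLPR")
  flat$days <- rep(4.2, 13)
  gf <- surface_grid(fit_shelf_life(flat), rate_steps = 10)
  expect_equal(gf$predicted, rep(4.2, nrow(gf)), tolerance = 1e-9)
  expect_error(surface_grid(fit, rate_steps = 1), "at least 2")
})
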