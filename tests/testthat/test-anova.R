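test_that("the ambient OLPR fit reproduces the published adequacy table", {
  fit <- fit_shelf_life(study_shelf_life("OLPR", "ambient"))
  an <- anova_shelf(fit)
  row <- function(term) an[an$term == term, ]
  expect_equal(row("Model")$sum_sq, 73.04, tolerance = TOL$ss_rel)
  expect_equal(row("Residual")$sum_sq, 1.24, tolerance = 0.02)
  expect_equal(row("Model")$statistic, 82.15, tolerance = TOL$ss_rel)
  expect_equal(attr(an, "r.squared"), 0.9832, tolerance = TOL$r2)
  expect_equal(attr(an, "adj.r.squared"), 0.9713, tolerance = TOL$r2)
  expect_equal(attr(an, "adeq.precision"), 20.29, tolerance = 0.5)
  # pure error from the five replicates of (no packaging, rate 0)
  lof <- lack_of_fit(fit)
  expect_equal(lof$sum_sq[lof$term == "PureError"], 0.10, tolerance = 1e-10)
  expect_equal(lof$df[lof$term == "PureError"], 4)
  expect_equal(lof$statistic[1], 15.26, tolerance = 0.3)
  # degrees of freedom bookkeeping
  expect_equal(row("Model")$df, 5)
  expect_equal(row("Residual")$df, 7)
  expect_equal(row("Total")$df, 12)
})

test_that("cold-storage fits reproduce the published lack-of-fit and precision", {
  m1 <- fit_shelf_life(study_shelf_life("OLPR", "cold_4C"))
  expect_equal(lack_of_fit(m1)$statistic[1], 0.9425, tolerance = TOL$lof_f)
  m2 <- fit_shelf_life(study_shelf_life("SCG", "cold_4C"))
  expect_equal(adequate_precision(m2), 74.41, tolerance = TOL$adeq)
})

test_that("sums of squares are conserved on fixtures and random designs", {
  check_conservation <- function(fit) {
    an <- anova_shelf(fit)
    g <- function(term) an$sum_sq[an$term == term]
    expect_equal(g("Model") + g("Residual"), g("Total"),
                 tolerance = 1e-9 * max(1, g("Total")))
    expect_equal(g("LackOfFit") + g("PureError"), g("Residual"),
                 tolerance = 1e-9 * max(1, g("Total")))
    expect_true(all(an$sum_sq >= 0))
    expect_gte(attr(an, "press"), g("Residual"))
  }
  for (fx in all_fixture_fits()) check_conservation(fx$fit)
  layout <- shelf_life_design("SCG")
  set.seed(7)
  for (i in 1:200) {
    d <- simulate_design(layout, random_true_beta(), noise_sd = 0.3)
    check_conservation(fit_shelf_life(d))
  }
})

test_that("the PRESS shortcut equals explicit leave-one-out refitting", {
  for (fx in all_fixture_fits()) {
    press <- press_stat(fx$fit)
    oracle <- loo_press(fx$fit$X, fx$design$days)
    expect_equal(press, oracle, tolerance = TOL$exact * max(1, oracle))
  }
})

test_that("the R-squared family is ordered pred <= adj <= r2 on every fixture", {
  for (fx in all_fixture_fits()) {
    r <- r2_family(fx$fit)
    expect_lte(r$pred.r.squared, r$adj.r.squared)
    expect_lte(r$adj.r.squared, r$r.squared)
  }
})

test_that("pure error depends only on replicate groups, not on the model", {
  d <- study_shelf_life("OLPR", "ambient")
  pure <- function(coding) {
    lof <- lack_of_fit(fit_shelf_life(d, coding = coding))
    lof$sum_sq[lof$term == "PureError"]
  }
  direct <- sum(tapply(d$days, paste(d$packaging, d$rate), function(y) {
    sum((y - mean(y))^2)
  }))
  expect_equal(pure("level"), direct)
  expect_equal(pure("range"), direct)
})

test_that("partial and sequential sums of squares relate as they must", {
  fit <- fit_shelf_life(study_shelf_life("OLPR_SCG", "cold_4C"))
  part <- anova_shelf(fit, ss = "partial")
  seqn <- anova_shelf(fit, ss = "sequential")
  term_rows <- !(part$term %in%
                   c("Model", "Residual", "LackOfFit", "PureError", "Total"))
  # sequential term SS sum to the model SS; partial SS generally do not
  expect_equal(sum(seqn$sum_sq[term_rows]),
               seqn$sum_sq[seqn$term == "Model"], tolerance = 1e-9)
  # the last term entered has identical partial and sequential SS
  expect_equal(part$sum_sq[part$term == "rate^2"],
               seqn$sum_sq[seqn$term == "rate^2"], tolerance = 1e-9)
})

test_that("degenerate adequacy inputs are flagged or rejected", {
  # perfect quadratic data: zero residual -> infinite F flagged, pure error 0
  d <- shelf_life_design("OLPR")
  d$days <- simulate_design(d, null_truth, noise_sd = 0)$days
  fit <- fit_shelf_life(d)
  an <- anova_shelf(fit)
  expect_true(attr(an, "zero_residual"))
  expect_identical(an$statistic[an$term == "Model"], Inf)
  expect_identical(an$p.value[an$term == "Model"], 0)
  expect_equal(adequate_precision(fit), Inf)
  # no replicates -> lack of fit undefined
  nine <- dplyr::distinct(d, packaging, rate, .keep_all = TRUE)
  expect_error(lack_of_fit(fit_shelf_life(nine)), "0 df")
  # a run with leverage 1 determines its own fit -> PRESS undefined
  six <- nine[c(1, 2, 3, 4, 5, 7), ]  # six points spanning all levels
  seven <- dplyr::bind_rows(six, six[6, ])
  seven$days <- seven$days + c(rep(0, 6), 0.2)
  expect_error(press_stat(fit_shelf_life(seven)), "leverage 1")
  # constant response -> zero total SS
  flat <- dplyr::mutate(shelf_life_design("OLPR"), days = 5)
  expect_error(r2_family(fit_shelf_life(flat)), "undefined")
})
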