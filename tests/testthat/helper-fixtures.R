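# Fixtures are built in code; the six measured run tables and the two TMC
# tables also ship as CSVs under inst/extdata and load via study_shelf_life()
# / study_tmc().

all_fixture_fits <- function(coding = "level") {
  combos <- expand.grid(
    scheme = c("OLPR", "SCG", "OLPR_SCG"),
    temperature = c("ambient", "cold_4C"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(combos)), function(i) {
    d <- study_shelf_life(combos$scheme[i], combos$temperature[i])
    list(
      scheme = combos$scheme[i], temperature = combos$temperature[i],
      design = d, fit = fit_shelf_life(d, coding = coding)
    )
  })
}

# independent OLS oracle: explicit normal-equations solve
normal_equations_fit <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# independent PRESS oracle: explicit leave-one-out refitting
loo_press <- function(X, y) {
  sum(vapply(seq_along(y), function(i) {
    b <- normal_equations_fit(X[-i, , drop = FALSE], y[-i])
    (y[i] - drop(X[i, ] %*% b))^2
  }, numeric(1)))
}

random_true_beta <- function() {
  c(
    b0 = runif(1, 4, 10), b1 = runif(1, -1, 1), b2 = runif(1, -1, 1),
    b12 = runif(1, -0.5, 0.5), b11 = runif(1, -1.5, 0),
    b22 = runif(1, -1.5, 0)
  )
}

# a strictly positive quadratic surface used for null simulations
null_truth <- c(b0 = 6, b1 = 1, b2 = 0.8, b12 = -0.3, b11 = -1, b22 = -1.5)
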