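#' Fit the second-order shelf-life model
#'
#' Fits, by ordinary least squares on a QR factorisation, the six-term
#' second-order polynomial
#' \deqn{Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_{12} X_1 X_2 +
#'       \beta_{11} X_1^2 + \beta_{22} X_2^2}
#' where \eqn{X_1} is the coded packaging type and \eqn{X_2} the coded
#' residue incorporation rate. Packaging is an ordered three-level factor
#' carried on the numeric code -1/0/+1 (one model degree of freedom), never
#' expanded into nominal contrasts.
#'
#' @param data a design tibble with columns `packaging` (values among VBP,
#'   NONE, PBP), `rate` (numeric, exactly three distinct levels) and the
#'   response column.
#' @param response name of the response column, default `"days"`.
#' @param coding `"level"` (-1/0/+1 by level order; the default, matching
#'   the printed design codes) or `"range"` (affine map of the rate onto
#'   \[-1, 1\]; the middle rate is then not centred because 0.3 is not the
#'   midrange of \[0, 0.7\]). Fitted values are identical under both
#'   codings except through the interaction column.
#' @return An object of class `shelf_fit`: the coefficient vector with its
#'   coding metadata (a `quad_model`), per-run fitted values, residuals and
#'   leverages, and the data.
#' @examples
#' fit <- fit_shelf_life(study_shelf_life("OLPR", "ambient"))
#' glance(fit)
#' @export
fit_shelf_life <- function(data, response = "days",
                           coding = c("level", "range")) {
  coding <- match.arg(coding)
  need <- c("packaging", "rate", response)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (nrow(data) < 7) abort("need at least 7 runs with responses to fit 6 terms")
  if (any(data[[response]] < 0)) abort("shelf-life responses must be >= 0 days")

  pack_spec <- packaging_spec()
  rates <- sort(unique(data$rate))
  if (length(rates) != 3) {
    abort(sprintf("expected exactly 3 rate levels, found %d", length(rates)))
  }
  rate_spec <- factor_spec("rate", rates,
                           coding = if (coding == "range") "range" else "level")

  x1 <- code_factor(data$packaging, pack_spec)
  x2 <- code_factor(data$rate, rate_spec)
  X <- cbind(b0 = 1, b1 = x1, b2 = x2, b12 = x1 * x2, b11 = x1^2, b22 = x2^2)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0(
      "singular design: column(s) ", paste(dropped, collapse = ", "),
      " are collinear with earlier model columns"
    ))
  }
  y <- data[[response]]
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  h <- rowSums(qr.Q(qrx)^2)

  model <- structure(
    list(
      coefficients = beta,
      response = response,
      coding = coding,
      packaging_spec = pack_spec,
      rate_spec = rate_spec,
      residual_dof = nrow(data) - ncol(X)
    ),
    class = "quad_model"
  )
  structure(
    list(
      model = model,
      data = as_tibble(data),
      X = X,
      qr = qrx,
      fitted = fitted,
      residuals = resid,
      leverages = h
    ),
    class = "shelf_fit"
  )
}

#' @export
print.quad_model <- function(x, ...) {
  cat(sprintf(
    "<quad_model> %s ~ packaging * rate quadratic (%s coding, %d residual df)\n",
    x$response, x$coding, x$residual_dof
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.shelf_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("n = %d runs, residual SS = %.4f\n",
              nrow(x$data), sum(x$residuals^2)))
  invisible(x)
}

predict_coded <- function(model, x1, x2) {
  b <- model$coefficients
  b[["b0"]] + b[["b1"]] * x1 + b[["b2"]] * x2 + b[["b12"]] * x1 * x2 +
    b[["b11"]] * x1^2 + b[["b22"]] * x2^2
}

#' Re-express the fitted surface in actual rate units
#'
#' For one packaging level, the fitted model restricted to that level is a
#' quadratic through its predictions at the three rate levels. This returns
#' the coefficients `(a0, a1, a2)` of that quadratic in actual (fraction)
#' units, which is how predictions at unseen rates and the analytic
#' optimiser operate. Packaging is never interpolated between levels.
#'
#' @param model a `quad_model` or `shelf_fit`.
#' @param packaging one of `"VBP"`, `"NONE"`, `"PBP"`.
#' @return Named numeric vector `c(a0, a1, a2)`.
#' @export
actual_rate_poly <- function(model, packaging) {
  model <- as_quad_model(model)
  x1 <- code_factor(packaging, model$packaging_spec)
  rates <- model$rate_spec$levels
  x2 <- code_factor(rates, model$rate_spec)
  yy <- predict_coded(model, x1, x2)
  V <- cbind(1, rates, rates^2)
  setNames(drop(solve(V, yy)), c("a0", "a1", "a2"))
}

as_quad_model <- function(x) {
  if (inherits(x, "shelf_fit")) x$model
  else if (inherits(x, "quad_model")) x
  else abort("expected a quad_model or shelf_fit")
}

#' Predict shelf-life at given settings
#'
#' Evaluates the fitted surface at actual-unit settings. Packaging must be
#' one of the three study levels; the rate may be any value, with values
#' outside the fitted level range flagged by a warning (extrapolation) but
#' still evaluated via the actual-units quadratic.
#'
#' @param object a `shelf_fit`.
#' @param newdata a data frame with columns `packaging` and `rate`; when
#'   omitted, the design points used for fitting.
#' @param ... unused.
#' @return Numeric vector of predicted days.
#' @export
predict.shelf_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$model, newdata, ...)
}

#' @rdname predict.shelf_fit
#' @export
predict.quad_model <- function(object, newdata, ...) {
  stopifnot(all(c("packaging", "rate") %in% names(newdata)))
  rng <- range(object$rate_spec$levels)
  if (any(newdata$rate < rng[1] | newdata$rate > rng[2])) {
    warn(sprintf(
      "rate outside the fitted range [%g, %g]: prediction is an extrapolation",
      rng[1], rng[2]
    ))
  }
  polys <- lapply(
    setNames(nm = packaging_levels),
    function(p) actual_rate_poly(object, p)
  )
  bad <- setdiff(unique(newdata$packaging), packaging_levels)
  if (length(bad)) {
    abort(paste0("unknown packaging level(s): ", paste(bad, collapse = ", ")))
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    a <- polys[[newdata$packaging[i]]]
    r <- newdata$rate[i]
    a[["a0"]] + a[["a1"]] * r + a[["a2"]] * r^2
  }, numeric(1))
}

#' Ordered coefficient report
#'
#' All six coefficients of the fitted polynomial, in days per coded unit
#' (linear), days per coded unit squared (quadratic, interaction), with
#' classical OLS standard errors. The header attribute states the coding
#' convention the coefficients refer to; the report is invariant to run
#' reordering.
#'
#' @param x a `shelf_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`; attribute `coding` states the coded basis.
#' @method tidy shelf_fit
#' @export
tidy.shelf_fit <- function(x, ...) {
  ssres <- sum(x$residuals^2)
  df <- x$model$residual_dof
  sigma2 <- ssres / df
  XtX_inv <- chol2inv(qr.R(x$qr))
  se <- sqrt(sigma2 * diag(XtX_inv))
  est <- x$model$coefficients
  terms <- c("(Intercept)", "packaging", "rate", "packaging:rate",
             "packaging^2", "rate^2")
  out <- tibble(
    term = terms,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pf((est / se)^2, 1, df, lower.tail = FALSE)
  )
  attr(out, "coding") <- x$model$coding
  out
}

#' @rdname tidy.shelf_fit
#' @export
coefficients_report <- function(x, ...) tidy.shelf_fit(x, ...)

#' One-row model summary
#'
#' @param x a `shelf_fit`.
#' @param ... unused.
#' @return A tibble with the R-squared family (`r.squared`,
#'   `adj.r.squared`, `pred.r.squared`), `press`, `adeq.precision`, the
#'   overall model F `statistic` with its `p.value`, `sigma`, degrees of
#'   freedom and `nobs`.
#' @method glance shelf_fit
#' @export
glance.shelf_fit <- function(x, ...) {
  an <- anova_shelf(x)
  a <- attributes(an)
  model_row <- an[an$term == "Model", ]
  tibble(
    r.squared = a$r.squared,
    adj.r.squared = a$adj.r.squared,
    pred.r.squared = a$pred.r.squared,
    press = a$press,
    adeq.precision = a$adeq.precision,
    statistic = model_row$statistic,
    p.value = model_row$p.value,
    df = model_row$df,
    df.residual = x$model$residual_dof,
    sigma = sqrt(sum(x$residuals^2) / x$model$residual_dof),
    nobs = nrow(x$data)
  )
}

#' @param data unused (the fit carries its data).
#' @rdname glance.shelf_fit
#' @method augment shelf_fit
#' @export
augment.shelf_fit <- function(x, data = NULL, ...) {
  x$data |>
    mutate(
      .fitted = x$fitted,
      .resid = x$residuals,
      .hat = x$leverages
    )
}
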