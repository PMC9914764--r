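#' Model-adequacy ANOVA for a fitted shelf-life surface
#'
#' Produces the full diagnostic table for a fitted quadratic: per-term
#' partial-F rows, the overall model test, the residual split into lack of
#' fit and pure error (from replicated runs), and, as attributes, the
#' R-squared family, PRESS and adequate precision.
#'
#' Per-term sums of squares are partial (type III) by default: the increase
#' in residual sum of squares when that single column is dropped from the
#' full model. Sequential (type I) sums of squares, which add terms in the
#' model order, are available via `ss = "sequential"`; the two coincide on
#' orthogonal designs. Per-term rows for the linear and interaction terms
#' depend on the coding scheme; model-level, residual, lack-of-fit,
#' pure-error, R-squared and PRESS quantities do not (except through the
#' interaction column).
#'
#' @param fit a [fit_shelf_life()] result.
#' @param ss `"partial"` (type III, the default) or `"sequential"` (type I).
#' @return A tibble of class `shelf_anova` with columns `term`, `sum_sq`,
#'   `df`, `mean_sq`, `statistic`, `p.value` and rows Model, the five model
#'   terms, Residual, (when replicates exist) LackOfFit and PureError, and
#'   Total. Attributes: `r.squared`, `adj.r.squared`, `pred.r.squared`,
#'   `press`, `adeq.precision`, `coding`, `ss_type`.
#' @examples
#' fit <- fit_shelf_life(study_shelf_life("OLPR", "ambient"))
#' anova_shelf(fit)
#' @export
anova_shelf <- function(fit, ss = c("partial", "sequential")) {
  ss <- match.arg(ss)
  stopifnot(inherits(fit, "shelf_fit"))
  y <- fit$data[[fit$model$response]]
  X <- fit$X
  n <- length(y)
  p <- ncol(X)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_res <- n - p
  # an interpolating fit leaves residuals at rounding level only
  if (ss_res <= 1e-10 * max(ss_tot, 1)) ss_res <- 0
  ms_res <- ss_res / df_res

  term_names <- c("packaging", "rate", "packaging:rate",
                  "packaging^2", "rate^2")
  ss_term <- if (ss == "partial") {
    vapply(2:p, function(j) resid_ss(X[, -j, drop = FALSE], y) - ss_res,
           numeric(1))
  } else {
    cum_ss <- vapply(2:p, function(j) resid_ss(X[, 1:j, drop = FALSE], y),
                     numeric(1))
    -diff(c(resid_ss(X[, 1, drop = FALSE], y), cum_ss))
  }
  ss_term <- pmax(ss_term, 0)

  f_of <- function(ms) if (ms_res > 0) ms / ms_res else Inf
  p_of <- function(f, df1) {
    ifelse(is.infinite(f), 0, pf(f, df1, df_res, lower.tail = FALSE))
  }

  rows <- tibble(
    term = c("Model", term_names, "Residual"),
    sum_sq = c(ss_mod, ss_term, ss_res),
    df = c(p - 1, rep(1L, p - 1), df_res),
    mean_sq = sum_sq / df,
    statistic = c(f_of(ss_mod / (p - 1)), vapply(ss_term, f_of, numeric(1)),
                  NA_real_),
    p.value = c(p_of(statistic[1], p - 1), p_of(statistic[2:p], 1), NA_real_)
  )

  lof <- tryCatch(lack_of_fit(fit), error = function(e) NULL)
  if (!is.null(lof)) rows <- bind_rows(rows, lof)
  rows <- bind_rows(rows, tibble(
    term = "Total", sum_sq = ss_tot, df = n - 1L,
    mean_sq = NA_real_, statistic = NA_real_, p.value = NA_real_
  ))

  press <- press_stat(fit)
  attr(rows, "r.squared") <- 1 - ss_res / ss_tot
  attr(rows, "adj.r.squared") <- 1 - (ss_res / df_res) / (ss_tot / (n - 1))
  attr(rows, "pred.r.squared") <- 1 - press / ss_tot
  attr(rows, "press") <- press
  attr(rows, "adeq.precision") <- adequate_precision(fit)
  attr(rows, "coding") <- fit$model$coding
  attr(rows, "ss_type") <- ss
  attr(rows, "zero_residual") <- ms_res == 0
  class(rows) <- c("shelf_anova", class(rows))
  rows
}

resid_ss <- function(X, y) {
  q <- qr(X)
  sum(qr.resid(q, y)^2)
}

#' @export
print.shelf_anova <- function(x, ...) {
  cat(sprintf(
    "Shelf-life surface ANOVA (%s SS, %s coding)\n",
    attr(x, "ss_type"), attr(x, "coding")
  ))
  out <- as.data.frame(x)
  out$p.value <- format_pvalue(out$p.value)
  print(out, digits = 4, row.names = FALSE)
  cat(sprintf(
    "R2 %.4f  adj R2 %.4f  pred R2 %.4f  PRESS %.4f  adeq precision %.4f\n",
    attr(x, "r.squared"), attr(x, "adj.r.squared"),
    attr(x, "pred.r.squared"), attr(x, "press"), attr(x, "adeq.precision")
  ))
  invisible(x)
}

format_pvalue <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' Lack of fit versus pure error
#'
#' Splits the residual sum of squares into pure error (within replicate
#' groups, a model-free measure of run-to-run noise) and lack of fit
#' (between distinct design points, measuring model inadequacy). In the
#' study layout pure error carries 4 degrees of freedom from the five
#' replicates of the (no packaging, rate 0) run.
#'
#' @param fit a `shelf_fit`.
#' @return A tibble with rows `LackOfFit` and `PureError` (columns as in
#'   [anova_shelf()]); the lack-of-fit F compares its mean square to the
#'   pure-error mean square.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "shelf_fit"))
  y <- fit$data[[fit$model$response]]
  groups <- replicate_groups(fit$data)$group
  stats <- tibble(y = y, g = groups) |>
    mutate(dev = .data$y - mean(.data$y), .by = "g")
  df_pure <- length(y) - length(unique(groups))
  if (df_pure < 1) {
    abort("no replicated runs: pure error has 0 df, lack of fit is undefined")
  }
  ss_pure <- sum(stats$dev^2)
  ss_res <- sum(fit$residuals^2)
  ss_lof <- max(ss_res - ss_pure, 0)
  df_lof <- fit$model$residual_dof - df_pure
  ms_pure <- ss_pure / df_pure
  ms_lof <- ss_lof / df_lof
  f <- if (ms_pure > 0) ms_lof / ms_pure else Inf
  tibble(
    term = c("LackOfFit", "PureError"),
    sum_sq = c(ss_lof, ss_pure),
    df = c(df_lof, df_pure),
    mean_sq = c(ms_lof, ms_pure),
    statistic = c(f, NA_real_),
    p.value = c(
      if (is.infinite(f)) 0 else pf(f, df_lof, df_pure, lower.tail = FALSE),
      NA_real_
    )
  )
}

#' Prediction error sum of squares (PRESS)
#'
#' Leave-one-out prediction error computed through the leverage shortcut
#' \eqn{\sum_i (e_i / (1 - h_{ii}))^2}, which equals refitting the model n
#' times with each run held out. A leverage of 1 means the run determines
#' its own fitted value and leave-one-out prediction is undefined.
#'
#' @param fit a `shelf_fit`.
#' @return PRESS in days squared.
#' @export
press_stat <- function(fit) {
  stopifnot(inherits(fit, "shelf_fit"))
  h <- fit$leverages
  if (any(h >= 1 - 1e-10)) {
    abort("a run has leverage 1 (it determines its own fit); PRESS is undefined")
  }
  sum((fit$residuals / (1 - h))^2)
}

#' R-squared family
#'
#' `r.squared = 1 - SS_res/SS_tot`; the adjusted version penalises by
#' residual degrees of freedom; the predicted version replaces the residual
#' sum of squares with PRESS, so `pred <= adj <= r2` in regular cases.
#'
#' @param fit a `shelf_fit`.
#' @return A named list with `r.squared`, `adj.r.squared`, `pred.r.squared`.
#' @export
r2_family <- function(fit) {
  stopifnot(inherits(fit, "shelf_fit"))
  y <- fit$data[[fit$model$response]]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("total sum of squares is 0; R-squared is undefined")
  ss_res <- sum(fit$residuals^2)
  n <- length(y)
  list(
    r.squared = 1 - ss_res / ss_tot,
    adj.r.squared = 1 - (ss_res / fit$model$residual_dof) / (ss_tot / (n - 1)),
    pred.r.squared = 1 - press_stat(fit) / ss_tot
  )
}

#' Adequate precision (signal-to-noise ratio)
#'
#' The range of fitted values over the design points divided by their
#' average prediction standard error, `sqrt(p * MS_res / n)`. Values above
#' 4 conventionally indicate a surface usable for navigation of the design
#' space.
#'
#' @param fit a `shelf_fit`.
#' @return Dimensionless ratio; `Inf` when the residual mean square is 0.
#' @export
adequate_precision <- function(fit) {
  stopifnot(inherits(fit, "shelf_fit"))
  y <- fit$data[[fit$model$response]]
  ss_res <- sum(fit$residuals^2)
  if (ss_res <= 1e-10 * max(sum((y - mean(y))^2), 1)) return(Inf)
  ms_res <- ss_res / fit$model$residual_dof
  n <- nrow(fit$data)
  p <- ncol(fit$X)
  (max(fit$fitted) - min(fit$fitted)) / sqrt(p * ms_res / n)
}
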