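#' Experimental factor specifications
#'
#' A factor specification records the three levels of an experimental factor
#' and how actual levels are mapped to dimensionless coded values for model
#' fitting. Two coding schemes are supported:
#'
#' * `"level"`: the ordered levels map to -1, 0, +1 regardless of spacing.
#'   This matches the codes printed alongside the design (the middle residue
#'   rate is coded 0 even though 0.3 is not the midrange of \[0, 0.7\]).
#' * `"range"`: an affine map `(x - midrange) / halfrange`, so only the two
#'   extreme levels land on -1/+1; defined for continuous factors only.
#'
#' The packaging factor is an ordered categorical factor on a numeric code
#' (VBP = -1, no packaging = 0, PBP = +1); the residue incorporation rate is
#' continuous with three observed levels.
#'
#' @param name factor name, e.g. `"packaging"` or `"rate"`.
#' @param levels ordered vector of exactly three distinct actual levels
#'   (character for an ordinal factor, numeric for a continuous one).
#' @param coding `"level"` or `"range"`.
#' @return An object of class `factor_spec`.
#' @examples
#' rate <- factor_spec("rate", c(0, 0.3, 0.7))
#' code_factor(0.7, rate)                           # +1
#' code_factor(0.3, factor_spec("rate", c(0, 0.3, 0.7), coding = "range"))
#' @export
factor_spec <- function(name, levels, coding = c("level", "range")) {
  coding <- match.arg(coding)
  if (length(levels) != 3L || anyDuplicated(levels)) {
    abort("`levels` must contain exactly 3 distinct values.")
  }
  kind <- if (is.numeric(levels)) "continuous" else "ordinal_categorical"
  if (coding == "range" && kind != "continuous") {
    abort("range coding is only defined for continuous factors.")
  }
  structure(
    list(name = name, kind = kind, levels = levels, coding = coding),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf(
    "<factor_spec> %s (%s, %s coding): %s\n",
    x$name, x$kind, x$coding, paste(x$levels, collapse = ", ")
  ))
  invisible(x)
}

#' Map actual factor levels to coded values
#'
#' Under level coding the three ordered levels map to -1, 0, +1; any other
#' value is an error. Under range coding any value inside the level range is
#' mapped affinely, `(x - midrange) / halfrange`.
#'
#' @param value actual level(s).
#' @param spec a [factor_spec()].
#' @return Numeric coded value(s), dimensionless.
#' @export
code_factor <- function(value, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  if (spec$coding == "level") {
    idx <- match(value, spec$levels)
    if (anyNA(idx)) {
      abort(sprintf(
        "unknown level(s) %s for factor '%s' (levels: %s)",
        paste(unique(value[is.na(idx)]), collapse = ", "),
        spec$name, paste(spec$levels, collapse = ", ")
      ))
    }
    return(idx - 2)
  }
  lo <- min(spec$levels); hi <- max(spec$levels)
  if (any(value < lo | value > hi)) {
    abort(sprintf(
      "value outside [%g, %g] for range-coded factor '%s'", lo, hi, spec$name
    ))
  }
  (value - (lo + hi) / 2) / ((hi - lo) / 2)
}

#' Map coded values back to actual levels
#'
#' Inverse of [code_factor()]. Under level coding only -1, 0, +1 are valid;
#' under range coding the affine map is inverted for any coded value in
#' \[-1, 1\].
#'
#' @inheritParams code_factor
#' @param coded coded value(s).
#' @export
decode_factor <- function(coded, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  if (spec$coding == "level") {
    idx <- match(coded, c(-1, 0, 1))
    if (anyNA(idx)) abort("coded values must be -1, 0 or +1 under level coding")
    return(spec$levels[idx])
  }
  lo <- min(spec$levels); hi <- max(spec$levels)
  coded * (hi - lo) / 2 + (lo + hi) / 2
}

#' The packaging factor used throughout the study
#'
#' Vacuum bag packaging (VBP, code -1), no packaging (NONE, code 0) and
#' vented polyethylene bag packaging (PBP, code +1).
#'
#' @return A [factor_spec()].
#' @export
packaging_spec <- function() {
  factor_spec("packaging", c("VBP", "NONE", "PBP"))
}

packaging_levels <- c("VBP", "NONE", "PBP")
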