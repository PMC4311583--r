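#' Define a two-level screening factor
#'
#' A process factor for a Plackett-Burman screening design, with the actual
#' settings used at the low (`-1`) and high (`+1`) coded levels.
#'
#' @param name Factor label (e.g. `"CMC"`).
#' @param low Actual setting at the `-1` level.
#' @param high Actual setting at the `+1` level. Must differ from `low`;
#'   levels are attached by column label, so an "inverted" assignment
#'   (numerically `high < low`, as for pH in the cellulase study) is allowed
#'   when `allow_inverted = TRUE`.
#' @param allow_inverted Permit `high < low` (the sign matrix stays
#'   authoritative; the actual values merely label the two settings).
#' @return An object of class `pb_factor`.
#' @export
pb_factor <- function(name, low, high, allow_inverted = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low == high)
    stop("pb_factor '", name, "': low and high must be finite and distinct")
  if (high < low && !allow_inverted)
    stop("pb_factor '", name, "': high < low; set allow_inverted = TRUE if the ",
         "sign-to-level assignment is intentionally reversed")
  structure(list(name = name, low = low, high = high, role = "factor"),
            class = "pb_factor")
}

#' Define a central-composite-design factor
#'
#' A continuous factor for a CCD, parameterized by its center (coded 0) and
#' the step per coded unit, so that actual = center + step * coded.
#'
#' @param name Factor label.
#' @param center Actual value at coded level 0.
#' @param step Actual units per coded unit; must be positive.
#' @return An object of class `ccd_factor`.
#' @export
ccd_factor <- function(name, center, step) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  center <- as.numeric(center); step <- as.numeric(step)
  if (!is.finite(center)) stop("ccd_factor '", name, "': center must be finite")
  if (!is.finite(step) || step <= 0)
    stop("ccd_factor '", name, "': step must be a positive number")
  structure(list(name = name, center = center, step = step, role = "factor"),
            class = "ccd_factor")
}

#' Convert coded levels to actual factor settings
#'
#' Applies `actual = center + step * coded`. Physically infeasible results
#' (e.g. a negative concentration at the `-alpha` axial level) are returned
#' as computed, with a warning: designs are reported as constructed, never
#' silently clipped.
#'
#' @param factor A [ccd_factor()].
#' @param coded Numeric vector of coded levels.
#' @param warn_infeasible Warn when an actual concentration is negative.
#' @return Numeric vector of actual settings.
#' @export
coded_to_actual <- function(factor, coded, warn_infeasible = TRUE) {
  if (!inherits(factor, "ccd_factor"))
    stop("coded_to_actual() requires a ccd_factor (center/step parameterization)")
  actual <- factor$center + factor$step * as.numeric(coded)
  if (warn_infeasible && any(actual < 0))
    warning("factor '", factor$name, "': coded level(s) map to negative actual ",
            "value(s) (", paste(signif(actual[actual < 0], 6), collapse = ", "),
            "); returned as computed", call. = FALSE)
  actual
}

#' @rdname coded_to_actual
#' @param actual Numeric vector of actual settings.
#' @export
actual_to_coded <- function(factor, actual) {
  if (!inherits(factor, "ccd_factor"))
    stop("actual_to_coded() requires a ccd_factor")
  (as.numeric(actual) - factor$center) / factor$step
}

#' @export
print.pb_factor <- function(x, ...) {
  cat(sprintf("Two-level factor %s: -1 = %g, +1 = %g\n", x$name, x$low, x$high))
  invisible(x)
}

#' @export
print.ccd_factor <- function(x, ...) {
  cat(sprintf("CCD factor %s: center %g, step %g per coded unit\n",
              x$name, x$center, x$step))
  invisible(x)
}
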