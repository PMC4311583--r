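# Plackett-Burman screening analysis: main effects, dummy-variable error,
# t-based significance screening.

.check_pb_inputs <- function(design, response) {
  m <- design_matrix(design)
  if (!all(m %in% c(-1, 1)))
    stop("design is not a two-level (+1/-1) screening matrix")
  response <- as.numeric(response)
  if (length(response) != nrow(m))
    stop("response length (", length(response), ") does not match design runs (",
         nrow(m), ")")
  if (any(!is.finite(response))) stop("response contains non-finite values")
  list(m = m, y = response)
}

#' Main effect of a screening-design column
#'
#' The effect of a column is twice the mean signed response,
#' `2 * (sum(M+) - sum(M-)) / N`: for a balanced column this equals the mean
#' response at the high level minus the mean at the low level.
#'
#' @param design A [pb_design()] (or any +/-1 design data frame with a `run`
#'   column).
#' @param response Numeric response vector, one value per run.
#' @param column Column label.
#' @return Signed effect, in response units.
#' @export
pb_effect <- function(design, response, column) {
  z <- .check_pb_inputs(design, response)
  if (!column %in% colnames(z$m))
    stop("column '", column, "' not found in design")
  x <- z$m[, column]
  if (sum(x == 1) != sum(x == -1))
    stop("column '", column, "' is unbalanced; the effect formula assumes an ",
         "equal number of high and low runs")
  2 * sum(x * z$y) / length(z$y)
}

#' Experimental error from dummy columns
#'
#' Dummy (unassigned) columns carry no real factor, so their apparent effects
#' reflect experimental noise. The variance of an effect is estimated as
#' `Veff = sum(Ed^2) / n` over the `n` dummy-column effects `Ed`, and the
#' standard error of any effect is `Es = sqrt(Veff)`.
#'
#' @inheritParams pb_effect
#' @return A list with `dummy_effects`, `Veff`, `Es` and `n_dummy`.
#' @export
pb_dummy_error <- function(design, response) {
  dummies <- dummy_columns(design)
  if (length(dummies) == 0L)
    stop("design has no dummy columns; experimental error cannot be estimated")
  ed <- vapply(dummies, function(col) pb_effect(design, response, col), 0)
  veff <- sum(ed^2) / length(ed)
  list(dummy_effects = ed, Veff = veff, Es = sqrt(veff),
       n_dummy = length(ed))
}

#' Screen factors from a Plackett-Burman experiment
#'
#' Estimates every process-factor main effect, derives the pooled standard
#' error from the dummy columns, and tests each effect with a Student t
#' statistic `t = effect / Es` on `n_dummy` degrees of freedom (two-tailed).
#' A factor is flagged significant when its confidence, `100 * (1 - p)`,
#' meets the threshold.
#'
#' @inheritParams pb_effect
#' @param threshold Confidence threshold in percent (default 95).
#' @return A data frame of class `pb_screen` with one row per process factor:
#'   `factor`, `effect` (signed), `magnitude`, `std_error`, `t`, `p`,
#'   `confidence_pct`, `significant`; attributes `Veff`, `Es`,
#'   `dummy_effects`, `df`, `threshold`, and `degenerate_error` (TRUE when
#'   `Es = 0`, in which case nonzero effects get infinite t and p = 0).
#' @examples
#' study <- cellulase_pb()
#' scr <- pb_screen(study$design, study$response)
#' scr[scr$significant, "factor"]
#' @export
pb_screen <- function(design, response, threshold = 95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 100)
    stop("threshold must lie strictly between 0 and 100")
  err <- pb_dummy_error(design, response)
  procs <- process_columns(design)
  eff <- vapply(procs, function(col) pb_effect(design, response, col), 0)

  degenerate <- err$Es == 0
  if (degenerate) {
    t <- ifelse(eff == 0, 0, sign(eff) * Inf)
    p <- ifelse(eff == 0, 1, 0)
  } else {
    t <- eff / err$Es
    p <- 2 * stats::pt(-abs(t), df = err$n_dummy)
  }
  conf <- 100 * (1 - p)

  out <- data.frame(
    factor = procs,
    effect = unname(eff),
    magnitude = abs(unname(eff)),
    std_error = err$Es,
    t = unname(t),
    p = unname(p),
    confidence_pct = unname(conf),
    significant = unname(conf) >= threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "Veff") <- err$Veff
  attr(out, "Es") <- err$Es
  attr(out, "dummy_effects") <- err$dummy_effects
  attr(out, "df") <- err$n_dummy
  attr(out, "threshold") <- threshold
  attr(out, "degenerate_error") <- degenerate
  class(out) <- c("pb_screen", "data.frame")
  out
}

#' @export
print.pb_screen <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Plackett-Burman screening (%d factors, Es = %.6g on %d df, threshold %g%%)\n",
    nrow(x), attr(x, "Es"), attr(x, "df"), attr(x, "threshold")))
  if (isTRUE(attr(x, "degenerate_error")))
    cat("  [degenerate error estimate: all dummy effects are zero]\n")
  print.data.frame(cbind(
    x[, "factor", drop = FALSE],
    round(x[, c("effect", "magnitude", "std_error", "t", "p",
                "confidence_pct")], digits),
    x[, "significant", drop = FALSE]), row.names = FALSE)
  invisible(x)
}
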