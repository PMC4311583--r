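# Strict CSV I/O for designs and responses, plus the end-to-end two-stage
# pipeline (screen -> fit -> diagnose -> optimize).

.read_strict_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) == 0) stop("no data rows in ", path)
  df
}

.as_numeric_strict <- function(df, path, skip = character(0)) {
  for (col in setdiff(names(df), skip)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !df[[col]] %in% c("NA", ""))
    if (length(bad) > 0)
      stop("malformed numeric cell in ", path, ": row ", bad[1],
           ", column '", col, "' (value '", df[[col]][bad[1]], "')")
    if (any(is.na(v)))
      stop("missing value in ", path, ": column '", col, "'")
    df[[col]] <- v
  }
  df
}

#' Read a design matrix from CSV
#'
#' Expects a header row `run,<factor1>,...`; all cells numeric. Coded-value
#' domains are checked by design kind: a screening design may contain only
#' `+1`/`-1`. Column roles (process factor vs dummy) come from `roles`, a
#' named character vector or the path of a JSON sidecar mapping column to
#' role; columns not mentioned default to `"factor"`.
#'
#' @param path CSV path.
#' @param kind `"plackett-burman"` or `"central-composite"`.
#' @param roles Optional named character vector or JSON sidecar path.
#' @param factors Optional list of [ccd_factor()] to attach actual-level
#'   metadata (CCD only).
#' @return A `pb_design` or `ccd_design` data frame.
#' @export
read_design_csv <- function(path, kind = c("plackett-burman",
                                           "central-composite"),
                            roles = NULL, factors = NULL) {
  kind <- match.arg(kind)
  df <- .read_strict_csv(path)
  if (!identical(names(df)[1], "run"))
    stop("design CSV must start with a 'run' column: ", path)
  df <- .as_numeric_strict(df, path)
  if (anyDuplicated(df$run)) stop("duplicate run ids in ", path)
  cols <- setdiff(names(df), "run")

  if (is.character(roles) && length(roles) == 1 && file.exists(roles))
    roles <- unlist(jsonlite::read_json(roles))
  role_vec <- stats::setNames(rep("factor", length(cols)), cols)
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), cols)
    if (length(unknown) > 0)
      stop("roles name column(s) absent from the design: ",
           paste(unknown, collapse = ", "))
    if (!all(roles %in% c("factor", "dummy")))
      stop("roles must be 'factor' or 'dummy'")
    role_vec[names(roles)] <- roles
  }

  m <- as.matrix(df[, cols, drop = FALSE])
  if (kind == "plackett-burman") {
    if (!all(m %in% c(-1, 1)))
      stop("screening design must contain only +1/-1 coded values: ", path)
    attr(df, "roles") <- role_vec
    attr(df, "design_kind") <- kind
    class(df) <- c("pb_design", "data.frame")
  } else {
    attr(df, "design_kind") <- kind
    if (!is.null(factors)) {
      if (!identical(unname(vapply(factors, `[[`, "", "name")), cols))
        stop("factor metadata does not match design columns")
      actual <- m
      for (j in seq_along(factors))
        actual[, j] <- coded_to_actual(factors[[j]], m[, j],
                                       warn_infeasible = FALSE)
      attr(df, "factors") <- factors
      attr(df, "actual") <- data.frame(run = df$run, actual,
                                       check.names = FALSE)
    }
    class(df) <- c("ccd_design", "data.frame")
  }
  df
}

#' Read a response vector from CSV
#'
#' Expects columns `run,response`. When `design` is supplied, run ids and
#' counts are cross-checked.
#'
#' @param path CSV path.
#' @param design Optional design to validate against.
#' @return Numeric response vector ordered by the file's rows.
#' @export
read_response_csv <- function(path, design = NULL) {
  df <- .read_strict_csv(path)
  if (!identical(names(df), c("run", "response")))
    stop("response CSV must have exactly the columns run,response: ", path)
  df <- .as_numeric_strict(df, path)
  if (anyDuplicated(df$run)) stop("duplicate run ids in ", path)
  if (!is.null(design)) {
    if (nrow(df) != nrow(design))
      stop("response has ", nrow(df), " rows but design has ", nrow(design))
    if (!all(df$run == design$run))
      stop("response run ids do not match the design")
  }
  df$response
}

#' Write a design (and its role sidecar) to CSV
#'
#' @param design A `pb_design` or `ccd_design`.
#' @param path Output CSV path; a `_roles.json` sidecar is written next to it
#'   when the design has dummy columns, and an `_actual.csv` file when actual
#'   levels are attached.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  roles <- attr(design, "roles")
  if (!is.null(roles) && any(roles == "dummy"))
    jsonlite::write_json(as.list(roles),
                         sub("\\.csv$", "_roles.json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  actual <- attr(design, "actual")
  if (!is.null(actual))
    utils::write.csv(actual, sub("\\.csv$", "_actual.csv", path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param response Numeric response vector aligned to `design`.
#' @export
write_response_csv <- function(response, design, path) {
  utils::write.csv(data.frame(run = design$run, response = response), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

.extdata <- function(...) {
  system.file("extdata", ..., package = "pbrsm", mustWork = TRUE)
}

#' The cellulase screening experiment (bundled case study)
#'
#' The 12-run, two-level screening experiment over eight medium and process
#' factors (CMC, sucrose, yeast extract, peptone, K2HPO4, MgSO4, temperature,
#' pH) plus three dummy columns, with cellulase activity (U/mL) as response,
#' from a Bacillus amyloliquefaciens medium-optimization study.
#'
#' Note the pH column's sign-to-level assignment is inverted relative to the
#' other rows (`+1` is pH 5, `-1` is pH 9), exactly as the study assigned it.
#'
#' @return List: `design` (a `pb_design`), `response` (U/mL), `factors`
#'   (list of [pb_factor()]).
#' @export
cellulase_pb <- function() {
  design <- read_design_csv(.extdata("cellulase_pb_design.csv"),
                            kind = "plackett-burman",
                            roles = .extdata("cellulase_pb_design_roles.json"))
  response <- read_response_csv(.extdata("cellulase_pb_response.csv"), design)
  fx <- utils::read.csv(.extdata("cellulase_pb_factors.csv"))
  factors <- lapply(seq_len(nrow(fx)), function(i)
    pb_factor(fx$factor[i], fx$low[i], fx$high[i], allow_inverted = TRUE))
  names(factors) <- fx$factor
  list(design = design, response = response, factors = factors)
}

#' The cellulase central composite experiment (bundled case study)
#'
#' The 20-run rotatable CCD (8 factorial + 6 axial + 6 center runs,
#' alpha = 1.681793) over CMC (g%), MgSO4 (g%) and pH, with cellulase
#' activity (U/mL) as response. The MgSO4 `-alpha` level is negative
#' (-0.1034 g%), as the design was constructed — physically infeasible but
#' retained.
#'
#' @return List: `design` (a `ccd_design` with actual-level metadata),
#'   `response` (U/mL), `factors` (list of [ccd_factor()]).
#' @export
cellulase_ccd <- function() {
  fx <- utils::read.csv(.extdata("cellulase_ccd_factors.csv"))
  factors <- lapply(seq_len(nrow(fx)), function(i)
    ccd_factor(fx$factor[i], fx$center[i], fx$step[i]))
  names(factors) <- fx$factor
  design <- read_design_csv(.extdata("cellulase_ccd_design.csv"),
                            kind = "central-composite", factors = factors)
  attr(design, "alpha") <- rotatable_alpha(nrow(fx))
  attr(design, "n_center") <- 6L
  response <- read_response_csv(.extdata("cellulase_ccd_response.csv"), design)
  list(design = design, response = response, factors = factors)
}

#' Reported validation figures of the cellulase case study
#'
#' Values the original study reports around its optimum that are experimental
#' measurements or claims, not quantities this package computes: the stated
#' optimal medium (CMC 1.84 g%, MgSO4 0.275 g%, pH 8.5), the activity the
#' study attributes to the model at that medium (29.95 U/mL — which equals
#' the observed response of the CMC axial run; the fitted model itself
#' predicts 28.31881 U/mL there), the wet-lab validation activity
#' (30.62 U/mL) and the claimed fold-increase over the unoptimized baseline
#' (6.81, baseline not reported). Kept as metadata for comparison only.
#'
#' @return Named list of the reported values.
#' @export
cellulase_reported <- function() {
  list(optimum_actual = c(CMC = 1.84, MgSO4 = 0.275, pH = 8.5),
       reported_predicted_at_optimum = 29.95,
       validated_activity = 30.62,
       fold_increase = 6.81)
}

# -- configuration ----------------------------------------------------------

#' Validate a study configuration
#'
#' A configuration drives [run_pipeline()]: screening threshold, alpha
#' policy, optimization region. Accepts an R list or the path of a JSON
#' file. Rejects thresholds outside (0, 100), non-positive steps, unknown
#' alpha policies and unknown regions.
#'
#' @param config List or JSON path.
#' @return The validated configuration list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  defaults <- list(threshold = 95, alpha = "rotatable", region = "box",
                   radius = NULL)
  config <- utils::modifyList(defaults, config)
  if (!is.numeric(config$threshold) || config$threshold <= 0 ||
      config$threshold >= 100)
    stop("config: threshold must lie strictly between 0 and 100")
  if (!(identical(config$alpha, "rotatable") ||
        (is.numeric(config$alpha) && config$alpha > 0)))
    stop("config: alpha must be 'rotatable' or a positive number")
  if (!config$region %in% c("box", "sphere"))
    stop("config: region must be 'box' or 'sphere'")
  if (!is.null(config$ccd_factors)) {
    cf <- config$ccd_factors
    if (any(unlist(lapply(cf, `[[`, "step")) <= 0))
      stop("config: factor steps must be positive")
  }
  config
}

#' Run the two-stage optimization pipeline
#'
#' Screens the two-level experiment, selects significant factors, fits the
#' second-order model to the follow-up CCD, computes the ANOVA and fit
#' diagnostics, and locates the stationary point and the constrained optimum
#' over the design region.
#'
#' @param pb List with `design` and `response` for the screening stage (as
#'   returned by [cellulase_pb()]).
#' @param ccd List with `design` and `response` for the surface stage.
#' @param config Configuration list or JSON path (see [validate_config()]).
#' @param out_dir Optional directory: result tables are written as CSV/JSON.
#' @return List of class `pbrsm_pipeline`: `screening`, `significant`,
#'   `fit`, `anova`, `stats`, `stationary` (NULL when the quadratic form is
#'   singular), `optimum`, `config`.
#' @examples
#' res <- run_pipeline(cellulase_pb(), cellulase_ccd())
#' res$significant
#' @export
run_pipeline <- function(pb, ccd, config = list(), out_dir = NULL) {
  config <- validate_config(config)
  screening <- pb_screen(pb$design, pb$response, threshold = config$threshold)
  significant <- screening$factor[screening$significant]

  fit <- quad_fit(ccd$design, ccd$response)
  anova <- rsm_anova(fit)
  stats <- fit_stats(fit, anova)
  stationary <- tryCatch(stationary_point(fit), error = function(e) NULL)
  optimum <- optimize_region(fit, region = config$region,
                             radius = config$radius)

  out <- list(screening = screening, significant = significant, fit = fit,
              anova = anova, stats = stats, stationary = stationary,
              optimum = optimum, config = config)
  class(out) <- "pbrsm_pipeline"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(screening),
                     file.path(out_dir, "screening.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(anova),
                     file.path(out_dir, "anova.csv"), row.names = FALSE)
    utils::write.csv(data.frame(run = ccd$design$run,
                                observed = ccd$response,
                                predicted = fit$fitted),
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    utils::write.csv(data.frame(term = names(fit$coefficients),
                                estimate = as.numeric(fit$coefficients)),
                     file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)
    summary <- list(
      significant = significant,
      diagnostics = stats[c("R2", "adj_R2", "CV_pct", "adequate_precision")],
      optimum = list(coded = as.list(optimum$coded),
                     actual = as.list(optimum$actual),
                     predicted = optimum$predicted,
                     region = optimum$region, radius = optimum$radius),
      stationary = if (!is.null(stationary))
        list(coded = as.list(stationary$coded),
             predicted = stationary$predicted,
             nature = stationary$nature))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.pbrsm_pipeline <- function(x, ...) {
  cat("Two-stage media optimization\n\n")
  print(x$screening)
  cat("\nSignificant at ", attr(x$screening, "threshold"), "%: ",
      paste(x$significant, collapse = ", "), "\n\n", sep = "")
  print(x$anova)
  cat(sprintf("\nR2 = %.4f, CV = %.2f%%, adequate precision = %.3f\n",
              x$stats$R2, x$stats$CV_pct, x$stats$adequate_precision))
  print(x$optimum)
  invisible(x)
}
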