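# Design construction: Plackett-Burman screening designs (cyclic generator
# construction) and rotatable central composite designs in coded units.

# Cyclic generator rows for Plackett-Burman designs. Each N-run design is
# built from its (N-1)-length generator: run 1 is the generator, runs
# 2..(N-1) are successive one-position right rotations, run N is all -1.
.pb_generators <- list(
  `8`  = c(+1, +1, +1, -1, +1, -1, -1),
  `12` = c(+1, +1, -1, +1, +1, +1, -1, -1, -1, +1, -1),
  `16` = c(+1, +1, +1, +1, -1, +1, -1, +1, +1, -1, -1, +1, -1, -1, -1),
  `20` = c(+1, +1, -1, -1, +1, +1, +1, +1, -1, +1, -1, +1, -1, -1, -1, -1,
           +1, +1, -1)
)

#' Generate a Plackett-Burman screening design
#'
#' Builds the two-level orthogonal screening matrix by cyclic rotation of a
#' stored generator row: the generator is run 1, each subsequent run rotates
#' it one position, and the final run is all `-1`. Columns beyond
#' `n_process` are flagged as dummy (unassigned) columns, whose apparent
#' effects estimate experimental error.
#'
#' @param n_runs Number of runs; a multiple of 4 with a stored generator
#'   (8, 12, 16 or 20).
#' @param n_process Number of real process factors.
#' @param n_dummy Number of dummy columns; `n_process + n_dummy` must equal
#'   `n_runs - 1`.
#' @param factor_names Optional labels for the process columns (defaults to
#'   `A`, `B`, ...; dummies continue the sequence).
#' @return A data frame of `-1`/`+1` coded levels (one column per design
#'   column, plus a `run` column), of class `pb_design`, carrying a `roles`
#'   attribute (`"factor"` or `"dummy"` per column).
#' @examples
#' d <- pb_design(12, n_process = 8, n_dummy = 3)
#' colSums(as.matrix(d[, -1]))  # every column balanced: sums to 0
#' @export
pb_design <- function(n_runs, n_process, n_dummy = n_runs - 1L - n_process,
                      factor_names = NULL) {
  key <- as.character(n_runs)
  if (!key %in% names(.pb_generators))
    stop("no Plackett-Burman generator stored for n_runs = ", n_runs,
         "; supported sizes: ", paste(names(.pb_generators), collapse = ", "))
  n_process <- as.integer(n_process); n_dummy <- as.integer(n_dummy)
  if (n_process < 1L || n_dummy < 0L)
    stop("n_process must be >= 1 and n_dummy >= 0")
  if (n_process + n_dummy != n_runs - 1L)
    stop("n_process + n_dummy (", n_process + n_dummy,
         ") must equal n_runs - 1 (", n_runs - 1L, ")")

  gen <- .pb_generators[[key]]
  k <- length(gen)
  m <- matrix(NA_real_, nrow = n_runs, ncol = k)
  row <- gen
  for (i in seq_len(n_runs - 1L)) {
    m[i, ] <- row
    row <- c(row[k], row[-k])
  }
  m[n_runs, ] <- -1

  if (is.null(factor_names)) {
    cols <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, k - 26)))))[seq_len(k)]
  } else {
    if (length(factor_names) != n_process)
      stop("factor_names must have length n_process")
    cols <- c(factor_names,
              if (n_dummy > 0) paste0("D", seq_len(n_dummy)))
  }
  colnames(m) <- cols
  roles <- c(rep("factor", n_process), rep("dummy", n_dummy))
  names(roles) <- cols

  out <- data.frame(run = seq_len(n_runs), m, check.names = FALSE)
  attr(out, "roles") <- roles
  attr(out, "design_kind") <- "plackett-burman"
  class(out) <- c("pb_design", "data.frame")
  out
}

#' Axial distance for a rotatable central composite design
#'
#' Rotatability (prediction variance depending only on the distance from the
#' design center) requires the axial points at `(2^k)^(1/4)` coded units.
#'
#' @param k Number of factors, `k >= 1`.
#' @return The coded axial distance.
#' @examples
#' rotatable_alpha(3)  # 1.681793
#' @export
rotatable_alpha <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  (2^k)^0.25
}

#' Construct a central composite design
#'
#' Emits the standard run order: the `2^k` full factorial at coded `+/-1`
#' (Yates order, first factor varying fastest), then `2k` axial runs (one
#' factor at `-alpha` then `+alpha`, others at 0, in factor order), then
#' `n_center` all-zero center replicates. Run order is deterministic; no
#' randomization is applied.
#'
#' @param factors List of [ccd_factor()] objects (defines `k`).
#' @param alpha Axial distance in coded units: `"rotatable"` (default,
#'   `(2^k)^(1/4)`) or a positive number.
#' @param n_center Number of center-point replicates.
#' @param warn_infeasible Passed to [coded_to_actual()] when deriving actual
#'   levels.
#' @return A data frame of coded levels (`run` column plus one column per
#'   factor), class `ccd_design`, with attributes `factors`, `alpha`,
#'   `n_center` and `actual` (a parallel data frame of actual levels).
#' @examples
#' f <- list(ccd_factor("CMC", 1, 0.5), ccd_factor("MgSO4", 0.275, 0.225),
#'           ccd_factor("pH", 8.5, 1.5))
#' d <- ccd_design(f, n_center = 6)
#' nrow(d)  # 2^3 + 2*3 + 6 = 20
#' @export
ccd_design <- function(factors, alpha = "rotatable", n_center = 6L,
                       warn_infeasible = FALSE) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "ccd_factor")))
    stop("factors must be a list of ccd_factor objects")
  k <- length(factors)
  if (k < 1L) stop("at least one factor is required")
  n_center <- as.integer(n_center)
  if (n_center < 0L) stop("n_center must be >= 0")
  if (identical(alpha, "rotatable")) {
    alpha <- rotatable_alpha(k)
  } else {
    alpha <- as.numeric(alpha)
    if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  }

  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("factor names must be unique")

  # factorial block, Yates order (first factor fastest)
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  # axial block: factor j at -alpha/+alpha, rest 0
  axial <- matrix(0, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k)
  coded <- rbind(fact, axial, center)
  dimnames(coded) <- list(NULL, nm)

  actual <- coded
  for (j in seq_len(k))
    actual[, j] <- coded_to_actual(factors[[j]], coded[, j],
                                   warn_infeasible = warn_infeasible)

  out <- data.frame(run = seq_len(nrow(coded)), coded, check.names = FALSE)
  attr(out, "factors") <- factors
  attr(out, "alpha") <- alpha
  attr(out, "n_center") <- n_center
  attr(out, "actual") <- data.frame(run = out$run, actual, check.names = FALSE)
  attr(out, "design_kind") <- "central-composite"
  class(out) <- c("ccd_design", "data.frame")
  out
}

#' Actual-unit view of a design
#'
#' @param design A `ccd_design`.
#' @return Data frame of actual factor settings, parallel to the coded design.
#' @export
actual_levels <- function(design) {
  a <- attr(design, "actual")
  if (is.null(a)) stop("design carries no actual-level metadata")
  a
}

# coded design columns (drops the run id), as a numeric matrix
design_matrix <- function(design) {
  cols <- setdiff(names(design), "run")
  as.matrix(as.data.frame(design)[, cols, drop = FALSE])
}

# labels of process (non-dummy) columns
process_columns <- function(design) {
  roles <- attr(design, "roles")
  if (is.null(roles)) return(setdiff(names(design), "run"))
  names(roles)[roles == "factor"]
}

# labels of dummy columns
dummy_columns <- function(design) {
  roles <- attr(design, "roles")
  if (is.null(roles)) return(character(0))
  names(roles)[roles == "dummy"]
}
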