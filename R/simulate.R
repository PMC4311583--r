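# Seeded simulation of design-response datasets with known ground truth,
# so screening and surface fitting can be validated end to end.

#' Simulate responses for a Plackett-Burman design
#'
#' Generates `y = baseline + sum(effect_j / 2 * x_j) + noise`, with the coded
#' slope set to half the stated effect so that the screening estimator (the
#' difference between mean response at the high and low level) recovers each
#' true effect exactly in the noiseless case. Dummy columns contribute
#' nothing by construction.
#'
#' @param design A [pb_design()].
#' @param effects Named numeric vector: true effect per process factor
#'   (response units); every process column must be present.
#' @param baseline Mean response (intercept).
#' @param noise_sd Standard deviation of i.i.d. Gaussian run-to-run noise.
#' @param seed RNG seed (required, so simulated studies are reproducible).
#' @return Numeric response vector, one value per run.
#' @examples
#' d <- pb_design(12, 8, 3)
#' y <- simulate_pb(d, effects = c(A = 17.5, B = 0, C = 0, D = 0, E = 0,
#'                                 F = 0, G = 0, H = 0), seed = 1)
#' @export
simulate_pb <- function(design, effects, baseline = 20, noise_sd = 0, seed) {
  procs <- process_columns(design)
  if (!is.numeric(effects) || is.null(names(effects)))
    stop("effects must be a named numeric vector")
  missing <- setdiff(procs, names(effects))
  if (length(missing) > 0)
    stop("effects missing for process factor(s): ",
         paste(missing, collapse = ", "))
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing(seed)) stop("seed is required")
  m <- design_matrix(design)[, procs, drop = FALSE]
  mu <- baseline + drop(m %*% (effects[procs] / 2))
  set.seed(seed)
  mu + stats::rnorm(nrow(m), 0, noise_sd)
}

#' Simulate responses for a central composite design
#'
#' Evaluates a known second-order polynomial (in coded variables) at each
#' design point and adds seeded i.i.d. Gaussian noise; center replicates
#' receive independent noise draws, so pure error estimates `noise_sd^2`.
#'
#' @param design A [ccd_design()].
#' @param truth Named list of true coded-scale coefficients: `intercept`,
#'   `linear` (named per factor), `quadratic` (named per factor), and
#'   `interaction` (named `"A:B"` style, every pair) — the full set is
#'   required.
#' @param noise_sd Standard deviation of Gaussian noise.
#' @param seed RNG seed (required).
#' @return Numeric response vector, one value per run.
#' @export
simulate_ccd <- function(design, truth, noise_sd = 0, seed) {
  coded <- design_matrix(design)
  nm <- colnames(coded)
  k <- length(nm)
  need_inter <- if (k >= 2) {
    unlist(lapply(seq_len(k - 1), function(i) paste0(nm[i], ":", nm[(i + 1):k])))
  } else character(0)
  ok <- is.list(truth) && is.numeric(truth$intercept) &&
    all(nm %in% names(truth$linear)) && all(nm %in% names(truth$quadratic)) &&
    all(need_inter %in% names(truth$interaction))
  if (!ok)
    stop("truth must supply intercept, linear and quadratic terms for ",
         paste(nm, collapse = ", "), ", and interactions ",
         paste(need_inter, collapse = ", "))
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing(seed)) stop("seed is required")
  beta <- c(truth$intercept, truth$linear[nm],
            truth$interaction[need_inter], truth$quadratic[nm])
  mu <- drop(quad_model_matrix(coded) %*% beta)
  set.seed(seed)
  mu + stats::rnorm(length(mu), 0, noise_sd)
}

#' Coefficients of the cellulase case-study surface as a simulation truth
#'
#' Convenience constructor: the fitted second-order model from the bundled
#' cellulase CCD, rounded to two decimals as conventionally reported, in the
#' list layout [simulate_ccd()] expects. Useful as a realistic truth for
#' simulation studies.
#'
#' @return A truth list (`intercept`, `linear`, `interaction`, `quadratic`).
#' @export
cellulase_truth <- function() {
  list(intercept = 27.32,
       linear = c(CMC = 1.28, MgSO4 = 0.86, pH = -2.27),
       interaction = c("CMC:MgSO4" = -0.85, "CMC:pH" = 0.98,
                       "MgSO4:pH" = -0.006),
       quadratic = c(CMC = -0.41, MgSO4 = -1.94, pH = -1.33))
}
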