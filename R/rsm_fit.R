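# Second-order response surface fitting in coded variables, ANOVA with
# lack-of-fit decomposition, and the usual fit diagnostics.

# Expanded second-order model matrix for a coded k-factor design:
# intercept, linear terms, pairwise interactions, pure quadratics.
quad_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  nm <- colnames(coded)
  if (is.null(nm)) nm <- paste0("X", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(coded)))
  for (j in seq_len(k)) cols[[nm[j]]] <- coded[, j]
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      cols[[paste0(nm[i], ":", nm[j])]] <- coded[, i] * coded[, j]
  }
  for (j in seq_len(k)) cols[[paste0(nm[j], "^2")]] <- coded[, j]^2
  do.call(cbind, cols)
}

#' Fit a second-order polynomial response surface
#'
#' Ordinary least squares of the response on the full quadratic expansion of
#' the coded design: intercept, linear terms, all pairwise interactions and
#' pure quadratic terms. Coefficients are reported on the coded scale (one
#' coded unit = one factor step), which is the scale on which a rotatable
#' CCD is orthogonal and the scale response-surface models are conventionally
#' reported on.
#'
#' @param design A [ccd_design()] (or data frame of coded levels with a
#'   `run` column).
#' @param response Numeric response vector, one value per run.
#' @return An object of class `quad_fit`: coefficients (split into
#'   `intercept`, `linear`, `interaction`, `quadratic`), the full
#'   `coefficients` vector in model-matrix order, `fitted`, `residuals`,
#'   `n`, `p`, `residual_df`, the factor names, and the coded design.
#' @examples
#' study <- cellulase_ccd()
#' fit <- quad_fit(study$design, study$response)
#' predict(fit, data.frame(CMC = 0, MgSO4 = 0, pH = 0))
#' @export
quad_fit <- function(design, response) {
  coded <- design_matrix(design)
  y <- as.numeric(response)
  if (length(y) != nrow(coded))
    stop("response length does not match design run count")
  if (any(!is.finite(y))) stop("response contains non-finite values")
  k <- ncol(coded)
  X <- quad_model_matrix(coded)
  p <- ncol(X)
  if (nrow(X) <= p)
    stop("insufficient runs: the quadratic model has ", p,
         " parameters but only ", nrow(X), " runs; no residual df")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: model matrix is rank deficient; collinear ",
         "column(s): ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)

  nm <- colnames(coded)
  inter_names <- if (k >= 2) {
    unlist(lapply(seq_len(k - 1), function(i)
      paste0(nm[i], ":", nm[(i + 1):k])))
  } else character(0)
  out <- list(
    coefficients = beta,
    intercept = unname(beta[1]),
    linear = beta[nm],
    interaction = beta[inter_names],
    quadratic = beta[paste0(nm, "^2")],
    factor_names = nm,
    coded = coded,
    factors = attr(design, "factors"),
    fitted = fitted,
    residuals = y - fitted,
    response = y,
    n = nrow(X),
    p = p,
    residual_df = nrow(X) - p
  )
  class(out) <- "quad_fit"
  out
}

#' Predict from a fitted quadratic surface
#'
#' @param object A [quad_fit()] model.
#' @param newdata Data frame or matrix of coded levels (columns named after
#'   the model's factors); defaults to the design points.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quad_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(as.data.frame(newdata)[, object$factor_names,
                                              drop = FALSE])
  unname(drop(quad_model_matrix(newdata) %*% object$coefficients))
}

#' @export
print.quad_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Second-order response surface in %d coded factors (%s)\n",
              length(x$factor_names), paste(x$factor_names, collapse = ", ")))
  cat(sprintf("  n = %d runs, %d parameters, %d residual df\n",
              x$n, x$p, x$residual_df))
  print(round(x$coefficients, digits))
  invisible(x)
}

# replicate groups: rows identical in every coded column (tolerance tol)
replicate_groups <- function(coded, tol = 1e-9) {
  key <- apply(round(coded / tol) * tol, 1, paste, collapse = "\r")
  match(key, unique(key))
}

#' ANOVA for a fitted quadratic surface
#'
#' Partitions the corrected total sum of squares into the model and residual,
#' the model into single-term contributions (by deletion: SS of the full
#' model's residual increase when the term is dropped — equal to the
#' sequential SS on an orthogonal CCD), and the residual into lack-of-fit
#' and pure error pooled within replicate groups (runs identical in all
#' coded columns; for a standard CCD these are the center replicates).
#'
#' @param fit A [quad_fit()] model.
#' @return A data frame of class `rsm_anova` with columns `source`, `SS`,
#'   `df`, `MS`, `F`, `p`; rows: `Model`, each model term, `Residual`,
#'   `Lack of fit`, `Pure error` (when replicate runs exist), and
#'   `Cor total`. Term and model F ratios are against the residual mean
#'   square; lack-of-fit is against pure error.
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  y <- fit$response
  X <- quad_model_matrix(fit$coded)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- sum((fit$fitted - mean(y))^2)
  df_mod <- fit$p - 1L
  df_res <- fit$residual_df
  ms_res <- ss_res / df_res

  rows <- data.frame(source = "Model", SS = ss_mod, df = df_mod,
                     MS = ss_mod / df_mod,
                     F = (ss_mod / df_mod) / ms_res,
                     p = stats::pf((ss_mod / df_mod) / ms_res, df_mod, df_res,
                                   lower.tail = FALSE),
                     stringsAsFactors = FALSE)

  # single-term deletion SS against the full model
  for (j in 2:fit$p) {
    fit_j <- stats::lm.fit(X[, -j, drop = FALSE], y)
    ss_j <- sum(fit_j$residuals^2) - ss_res
    f_j <- ss_j / ms_res
    rows <- rbind(rows, data.frame(
      source = colnames(X)[j], SS = ss_j, df = 1L, MS = ss_j,
      F = f_j, p = stats::pf(f_j, 1, df_res, lower.tail = FALSE)))
  }

  rows <- rbind(rows, data.frame(source = "Residual", SS = ss_res, df = df_res,
                                 MS = ms_res, F = NA_real_, p = NA_real_))

  grp <- replicate_groups(fit$coded)
  has_reps <- any(duplicated(grp))
  if (has_reps) {
    ss_pe <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
    df_pe <- length(y) - length(unique(grp))
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    rows <- rbind(rows,
      data.frame(source = "Lack of fit", SS = ss_lof, df = df_lof,
                 MS = ss_lof / df_lof, F = f_lof,
                 p = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)),
      data.frame(source = "Pure error", SS = ss_pe, df = df_pe,
                 MS = ss_pe / df_pe, F = NA_real_, p = NA_real_))
  } else {
    message("no replicate runs: lack-of-fit/pure-error rows omitted")
  }
  rows <- rbind(rows, data.frame(source = "Cor total", SS = ss_tot,
                                 df = length(y) - 1L, MS = NA_real_,
                                 F = NA_real_, p = NA_real_))
  rownames(rows) <- NULL
  attr(rows, "has_replicates") <- has_reps
  class(rows) <- c("rsm_anova", "data.frame")
  rows
}

#' Fit diagnostics for a quadratic surface
#'
#' @param fit A [quad_fit()] model.
#' @param anova Optional precomputed [rsm_anova()] table.
#' @return List with `R2` (model SS over corrected total SS), `adj_R2`,
#'   `CV_pct` (100 * sqrt(residual MS) / mean response; `NA` with a flag
#'   when the mean response is 0), and `adequate_precision`
#'   (range of fitted values over sqrt(p * residual MS / n); values above 4
#'   indicate an adequate signal-to-noise ratio).
#' @export
fit_stats <- function(fit, anova = rsm_anova(fit)) {
  ss <- function(src) anova$SS[anova$source == src]
  df <- function(src) anova$df[anova$source == src]
  ms_res <- ss("Residual") / df("Residual")
  r2 <- ss("Model") / ss("Cor total")
  adj <- 1 - (1 - r2) * df("Cor total") / df("Residual")
  ybar <- mean(fit$response)
  cv <- if (ybar == 0) NA_real_ else 100 * sqrt(ms_res) / abs(ybar)
  ap <- (max(fit$fitted) - min(fit$fitted)) /
    sqrt(fit$p * ms_res / fit$n)
  list(R2 = r2, adj_R2 = adj, CV_pct = cv, adequate_precision = ap,
       cv_undefined = ybar == 0)
}

#' @export
print.rsm_anova <- function(x, ...) {
  y <- x
  y$SS <- signif(y$SS, 6); y$MS <- signif(y$MS, 6)
  y$F <- signif(y$F, 5); y$p <- signif(y$p, 4)
  print.data.frame(y, row.names = FALSE, na.print = "")
  invisible(x)
}
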