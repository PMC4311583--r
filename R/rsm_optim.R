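# Optimum location on a fitted quadratic surface: analytic stationary point,
# exact constrained maximization over a coded box or sphere, and prediction
# grids for surface/contour plots.

# quadratic-form matrix B (diagonal = pure quadratic coefficients,
# off-diagonal = interaction/2) and linear part b, so that
# yhat(x) = intercept + b'x + x'Bx
quad_parts <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  nm <- fit$factor_names
  k <- length(nm)
  B <- diag(as.numeric(fit$quadratic), k)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      B[i, j] <- B[j, i] <- fit$interaction[[paste0(nm[i], ":", nm[j])]] / 2
    }
  }
  dimnames(B) <- list(nm, nm)
  list(b0 = fit$intercept, b = stats::setNames(as.numeric(fit$linear), nm),
       B = B, k = k, nm = nm)
}

eval_quad <- function(parts, x) {
  x <- as.numeric(x)
  parts$b0 + sum(parts$b * x) + drop(t(x) %*% parts$B %*% x)
}

# map a coded point to actual units when the fit carries factor metadata
.coded_point_to_actual <- function(fit, x) {
  if (is.null(fit$factors)) return(NULL)
  stats::setNames(
    vapply(seq_along(fit$factors), function(j)
      coded_to_actual(fit$factors[[j]], x[j], warn_infeasible = FALSE), 0),
    fit$factor_names)
}

#' Stationary point of a fitted quadratic surface
#'
#' Solves for the coded point where the gradient of the fitted surface
#' vanishes, `2 B x = -b`, and classifies it by the eigenvalues of the
#' quadratic-form matrix `B`: all negative, a maximum; all positive, a
#' minimum; mixed signs, a saddle.
#'
#' @param fit A [quad_fit()] model.
#' @param tol Relative tolerance for treating an eigenvalue as zero.
#' @return List of class `stationary_point`: `coded`, `actual` (when factor
#'   metadata is available), `predicted`, `nature`, `eigenvalues`.
#' @export
stationary_point <- function(fit, tol = 1e-10) {
  parts <- quad_parts(fit)
  ev <- eigen(parts$B, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(abs(ev)) < tol * scale)
    stop("quadratic-form matrix is singular (stationary ridge); use ",
         "optimize_region() for a constrained optimum instead")
  x <- drop(solve(2 * parts$B, -parts$b))
  names(x) <- parts$nm
  nature <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
            else "saddle"
  out <- list(coded = x,
              actual = .coded_point_to_actual(fit, x),
              predicted = eval_quad(parts, x),
              nature = nature,
              eigenvalues = ev)
  class(out) <- "stationary_point"
  out
}

#' @export
print.stationary_point <- function(x, digits = 4, ...) {
  cat("Stationary point (", x$nature, ")\n", sep = "")
  cat("  coded:    ", paste(sprintf("%s = %.*g", names(x$coded), digits,
                                    x$coded), collapse = ", "), "\n")
  if (!is.null(x$actual))
    cat("  actual:   ", paste(sprintf("%s = %.*g", names(x$actual), digits,
                                      x$actual), collapse = ", "), "\n")
  cat(sprintf("  predicted response: %.*g\n", digits, x$predicted))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, digits), collapse = ", "),
      "\n")
  invisible(x)
}

# exact maximum of a quadratic over the box [lo, hi]^k by KKT enumeration:
# every maximizer has each coordinate either at a bound or with zero partial
# derivative, so enumerate the 3^k bound patterns and solve the free block.
.max_quad_box <- function(parts, lo, hi) {
  k <- parts$k
  best <- NULL; best_val <- -Inf
  patterns <- expand.grid(rep(list(c("lo", "free", "hi")), k),
                          stringsAsFactors = FALSE)
  for (r in seq_len(nrow(patterns))) {
    pat <- as.character(patterns[r, ])
    x <- numeric(k)
    x[pat == "lo"] <- lo[pat == "lo"]
    x[pat == "hi"] <- hi[pat == "hi"]
    free <- which(pat == "free")
    if (length(free) > 0) {
      Bff <- parts$B[free, free, drop = FALSE]
      rhs <- -(parts$b[free] +
                 2 * parts$B[free, -free, drop = FALSE] %*% x[-free])
      xf <- tryCatch(drop(solve(2 * Bff, rhs)), error = function(e) NULL)
      if (is.null(xf)) next  # degenerate face: its sup lies on a sub-face
      if (any(xf < lo[free] - 1e-12) || any(xf > hi[free] + 1e-12)) next
      x[free] <- pmin(pmax(xf, lo[free]), hi[free])
    }
    val <- eval_quad(parts, x)
    if (val > best_val) { best_val <- val; best <- x }
  }
  list(x = best, value = best_val)
}

# exact maximum of a quadratic over the ball |x| <= r (trust-region style
# eigenvalue solve, maximization convention)
.max_quad_sphere <- function(parts, r) {
  eg <- eigen(parts$B, symmetric = TRUE)
  lam <- eg$values; V <- eg$vectors
  bt <- drop(crossprod(V, parts$b))           # b in eigenbasis
  # interior candidate: concave and stationary point inside the ball
  cands <- list()
  if (max(lam) < 0) {
    xs <- drop(V %*% (-bt / (2 * lam)))
    if (sqrt(sum(xs^2)) <= r) cands <- c(cands, list(xs))
  }
  # boundary: x(mu) = V diag(1/(2 mu - 2 lam)) bt with mu > max(lam),
  # |x(mu)| decreasing in mu; solve |x(mu)| = r
  lmax <- max(lam)
  norm_at <- function(mu) sqrt(sum((bt / (2 * (mu - lam)))^2))
  eps <- 1e-10 * max(1, abs(lmax))
  if (norm_at(lmax + eps) >= r) {
    upper <- lmax + eps + 1
    while (norm_at(upper) > r) upper <- lmax + (upper - lmax) * 2
    mu <- stats::uniroot(function(m) norm_at(m) - r,
                         c(lmax + eps, upper), tol = 1e-14)$root
    cands <- c(cands, list(drop(V %*% (bt / (2 * (mu - lam))))))
  } else {
    # hard case: b nearly orthogonal to the top eigenspace; move along the
    # top eigenvector from the limiting solution until the boundary
    xs <- drop(V %*% ifelse(abs(lam - lmax) < eps, 0,
                            bt / (2 * (lmax - lam))))
    v1 <- V[, which.max(lam)]
    tau <- sqrt(max(r^2 - sum(xs^2), 0))
    cands <- c(cands, list(xs + tau * v1), list(xs - tau * v1))
  }
  vals <- vapply(cands, function(x) eval_quad(parts, x), 0)
  i <- which.max(vals)
  list(x = cands[[i]], value = vals[i])
}

#' Constrained maximum of a fitted quadratic surface
#'
#' Maximizes the fitted second-order polynomial over the experimental region
#' in coded units: either the box `[-radius, +radius]^k` (default, the axial
#' cube) or the ball of that radius. Both solves are analytic and
#' deterministic — the box by enumerating the `3^k` bound patterns of the
#' KKT conditions, the ball by the eigenvalue (trust-region) equation — so
#' the result is the exact global constrained optimum, not a local search.
#'
#' @param fit A [quad_fit()] model.
#' @param region `"box"` or `"sphere"`.
#' @param radius Region half-width / radius in coded units; defaults to the
#'   largest absolute coded level in the design (the axial distance for a
#'   CCD).
#' @return List of class `region_optimum`: `coded`, `actual` (when factor
#'   metadata is available), `predicted`, `region`, `radius`.
#' @examples
#' study <- cellulase_ccd()
#' optimize_region(quad_fit(study$design, study$response))
#' @export
optimize_region <- function(fit, region = c("box", "sphere"), radius = NULL) {
  region <- match.arg(region)
  parts <- quad_parts(fit)
  if (is.null(radius)) radius <- max(abs(fit$coded))
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  res <- if (region == "box") {
    .max_quad_box(parts, rep(-radius, parts$k), rep(radius, parts$k))
  } else {
    .max_quad_sphere(parts, radius)
  }
  x <- stats::setNames(res$x, parts$nm)
  out <- list(coded = x,
              actual = .coded_point_to_actual(fit, x),
              predicted = res$value,
              region = region, radius = radius)
  class(out) <- "region_optimum"
  out
}

#' @export
print.region_optimum <- function(x, digits = 4, ...) {
  cat(sprintf("Constrained maximum over the coded %s (radius %.4g)\n",
              x$region, x$radius))
  cat("  coded:  ", paste(sprintf("%s = %.*g", names(x$coded), digits,
                                  x$coded), collapse = ", "), "\n")
  if (!is.null(x$actual))
    cat("  actual: ", paste(sprintf("%s = %.*g", names(x$actual), digits,
                                    x$actual), collapse = ", "), "\n")
  cat(sprintf("  predicted response: %.*g\n", digits, x$predicted))
  invisible(x)
}

#' Prediction grid over two factors
#'
#' Evaluates the fitted surface on a rectangular coded grid over one factor
#' pair, holding the remaining factors at supplied levels — the numbers
#' behind a response-surface or contour plot.
#'
#' @param fit A [quad_fit()] model.
#' @param pair Character vector of two distinct factor names.
#' @param fixed Named vector of coded levels for every remaining factor
#'   (default: all at 0, the design center).
#' @param resolution Grid points per axis (>= 2).
#' @param limits Coded range per axis, default the design's largest absolute
#'   coded level.
#' @return Data frame with the two varied factors' coded levels and
#'   `predicted`; attribute `fixed` records the held levels.
#' @export
surface_grid <- function(fit, pair, fixed = NULL, resolution = 50,
                         limits = NULL) {
  stopifnot(inherits(fit, "quad_fit"))
  nm <- fit$factor_names
  if (length(pair) != 2L || anyDuplicated(pair) || !all(pair %in% nm))
    stop("pair must name two distinct model factors")
  if (resolution < 2) stop("resolution must be at least 2")
  others <- setdiff(nm, pair)
  if (is.null(fixed)) fixed <- stats::setNames(rep(0, length(others)), others)
  if (!all(others %in% names(fixed)))
    stop("fixed must supply a coded level for: ",
         paste(setdiff(others, names(fixed)), collapse = ", "))
  if (is.null(limits)) {
    r <- max(abs(fit$coded))
    limits <- c(-r, r)
  }
  s <- seq(limits[1], limits[2], length.out = resolution)
  g <- expand.grid(s, s)
  names(g) <- pair
  pts <- matrix(0, nrow(g), length(nm), dimnames = list(NULL, nm))
  pts[, pair[1]] <- g[[1]]; pts[, pair[2]] <- g[[2]]
  for (o in others) pts[, o] <- fixed[[o]]
  g$predicted <- predict(fit, pts)
  attr(g, "fixed") <- fixed[others]
  g
}
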