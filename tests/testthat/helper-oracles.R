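# Independent oracles used across tests: these re-derive quantities by a
# different route than the package (regression slopes, normal equations,
# direct polynomial evaluation, grid search) so agreement is evidence, not
# circularity.

# full second-order model matrix, built directly (independent of the package)
oracle_quad_mm <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  out <- cbind(1, coded)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      out <- cbind(out, coded[, i] * coded[, j])
  }
  cbind(out, coded^2)
}

# evaluate a quadratic with coefficient vector in the package's term order
oracle_quad_eval <- function(beta, pts) {
  drop(oracle_quad_mm(as.matrix(pts)) %*% beta)
}

# grid argmax of a quadratic over a box, coarse pass then local refinement
oracle_box_argmax <- function(beta, k, radius, coarse = 0.05, fine = 0.005) {
  sweep_grid <- function(lo, hi, by) {
    axes <- lapply(seq_len(k), function(j) seq(lo[j], hi[j], by = by))
    g <- as.matrix(expand.grid(axes))
    v <- oracle_quad_eval(beta, g)
    list(x = g[which.max(v), ], value = max(v))
  }
  c1 <- sweep_grid(rep(-radius, k), rep(radius, k), coarse)
  lo <- pmax(c1$x - coarse, -radius); hi <- pmin(c1$x + coarse, radius)
  sweep_grid(lo, hi, fine)
}

# the three-factor cellulase CCD study, fitted
cellulase_ccd_fit <- function() {
  study <- cellulase_ccd()
  quad_fit(study$design, study$response)
}

# a random full-rank quadratic model on the 20-run rotatable CCD
random_quad_fit <- function(seed, concave = FALSE) {
  set.seed(seed)
  f <- list(ccd_factor("X1", 0, 1), ccd_factor("X2", 0, 1),
            ccd_factor("X3", 0, 1))
  d <- ccd_design(f, n_center = 6)
  quad_coef <- if (concave) -runif(3, 0.5, 2) else rnorm(3)
  truth <- list(intercept = rnorm(1, 20),
                linear = stats::setNames(rnorm(3), c("X1", "X2", "X3")),
                interaction = stats::setNames(rnorm(3, sd = 0.3),
                  c("X1:X2", "X1:X3", "X2:X3")),
                quadratic = stats::setNames(quad_coef, c("X1", "X2", "X3")))
  y <- simulate_ccd(d, truth, noise_sd = 0, seed = seed + 1)
  list(fit = quad_fit(d, y), truth = truth, design = d, response = y)
}
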