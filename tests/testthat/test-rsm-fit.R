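test_that("least squares matches a normal-equations oracle", {
  set.seed(3)
  for (seed in 1:5) {
    rq <- random_quad_fit(seed)
    y <- rq$response + rnorm(20, 0, 2)  # add noise so the fit is nontrivial
    fit <- quad_fit(rq$design, y)
    X <- oracle_quad_mm(as.matrix(rq$design[, -1]))
    beta_oracle <- unname(drop(solve(crossprod(X), crossprod(X, y))))
    expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-10)
    expect_equal(fit$fitted + fit$residuals, y, tolerance = 1e-10)
  }
})

test_that("noiseless synthetic responses are recovered exactly", {
  rq <- random_quad_fit(17)
  beta_true <- c(rq$truth$intercept, rq$truth$linear,
                 rq$truth$interaction, rq$truth$quadratic)
  expect_equal(unname(rq$fit$coefficients), unname(beta_true),
               tolerance = 1e-8)
  an <- rsm_anova(rq$fit)
  expect_equal(an$SS[an$source == "Residual"], 0, tolerance = 1e-16)
  expect_equal(an$SS[an$source == "Pure error"], 0, tolerance = 1e-16)
  expect_equal(fit_stats(rq$fit, an)$R2, 1, tolerance = 1e-12)
})

test_that("case-study fit reproduces the published surface and predictions", {
  fit <- cellulase_ccd_fit()
  # coefficients, to the conventional 2-decimal reporting
  expect_equal(unname(round(fit$coefficients, 2)),
               c(27.32, 1.28, 0.87, -2.27, -0.86, 0.98, -0.01, -0.41, -1.94,
                 -1.33))
  # rounding aside, the headline terms to higher precision
  expect_equal(fit$intercept, 27.31957, tolerance = 1e-5)
  expect_equal(unname(fit$linear["pH"]), -2.2734, tolerance = 1e-4)
  # predicted responses at the center and at the CMC axial run
  expect_equal(predict(fit, data.frame(CMC = 0, MgSO4 = 0, pH = 0)),
               27.31957, tolerance = 1e-5)
  expect_equal(fit$fitted[10], 28.31881, tolerance = 1e-4)
  expect_equal(predict(fit, data.frame(CMC = 1.681793, MgSO4 = 0, pH = 0)),
               28.31881, tolerance = 1e-4)
})

test_that("ANOVA partitions sums of squares consistently", {
  for (seed in c(5, 23)) {
    rq <- random_quad_fit(seed)
    y <- rq$response + rnorm(20, 0, 1.5)
    fit <- quad_fit(rq$design, y)
    an <- rsm_anova(fit)
    ss <- function(src) an$SS[an$source == src]
    expect_equal(ss("Model") + ss("Residual"), ss("Cor total"),
                 tolerance = 1e-8)
    expect_equal(ss("Lack of fit") + ss("Pure error"), ss("Residual"),
                 tolerance = 1e-8)
    expect_equal(an$df[an$source == "Model"] +
                   an$df[an$source == "Residual"],
                 an$df[an$source == "Cor total"])
    # orthogonal design: deletion SS of linear/interaction terms = b^2 * sum(x^2)
    X <- oracle_quad_mm(as.matrix(rq$design[, -1]))
    term_names <- names(fit$coefficients)
    for (j in 2:7) {
      expect_equal(an$SS[an$source == term_names[j]],
                   unname(fit$coefficients[j]^2 * sum(X[, j]^2)),
                   tolerance = 1e-8, info = term_names[j])
    }
  }
})

test_that("case-study ANOVA reproduces the published table", {
  fit <- cellulase_ccd_fit()
  an <- rsm_anova(fit)
  ss <- function(src) an$SS[an$source == src]
  f <- function(src) an$F[an$source == src]
  expect_equal(ss("Model"), 189.98589, tolerance = 1e-4)
  expect_equal(ss("Residual"), 55.63221, tolerance = 1e-4)
  expect_equal(ss("Cor total"), 245.61819, tolerance = 1e-4)
  expect_equal(f("Model"), 3.79448, tolerance = 1e-4)
  expect_equal(an$p[an$source == "Model"], 0.0247, tolerance = 0.005)
  expect_equal(f("pH"), 12.68749, tolerance = 1e-4)
  expect_equal(ss("pH"), 70.58331, tolerance = 1e-4)
  expect_equal(ss("MgSO4^2"), 54.12976, tolerance = 1e-4)
  expect_equal(f("Lack of fit"), 1.080324, tolerance = 1e-5)
  expect_equal(an$p[an$source == "Lack of fit"], 0.4672, tolerance = 1e-3)
  expect_equal(ss("Pure error"), 26.74208, tolerance = 1e-4)
  expect_equal(an$df[an$source == "Pure error"], 5)
})

test_that("fit diagnostics match the published values", {
  fit <- cellulase_ccd_fit()
  st <- fit_stats(fit)
  expect_equal(st$CV_pct, 9.51, tolerance = 0.001)
  expect_equal(st$adequate_precision, 6.553, tolerance = 1e-3)
  expect_equal(st$R2, 189.98589 / 245.61819, tolerance = 1e-5)
})

test_that("degenerate fits are rejected with informative errors", {
  f <- lapply(1:3, function(j) ccd_factor(paste0("X", j), 0, 1))
  # too few runs: n <= p
  d_small <- ccd_design(f, n_center = 1)
  d_small <- d_small[1:9, ]
  class(d_small) <- c("ccd_design", "data.frame")
  expect_error(quad_fit(d_small, rnorm(9)), "insufficient runs")
  # collinear: duplicate a factor
  d <- ccd_design(f, n_center = 6)
  d2 <- d; d2$X3 <- d2$X2
  class(d2) <- class(d)
  expect_error(quad_fit(d2, rnorm(20)), "rank deficient|collinear")
  # no replicates: lack-of-fit omitted with a message
  d3 <- d[c(1:14, 15), ]
  class(d3) <- class(d)
  set.seed(1)
  fit3 <- quad_fit(d3, rnorm(15, 20))
  expect_message(an3 <- rsm_anova(fit3), "no replicate")
  expect_false("Lack of fit" %in% an3$source)
})
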