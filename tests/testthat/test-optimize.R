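test_that("the gradient vanishes at the stationary point", {
  for (seed in 1:100) {
    rq <- random_quad_fit(seed)
    sp <- tryCatch(stationary_point(rq$fit), error = function(e) NULL)
    if (is.null(sp)) next  # near-singular random draw
    # numeric gradient of the fitted surface at the stationary point
    h <- 1e-6
    for (j in 1:3) {
      up <- dn <- sp$coded
      up[j] <- up[j] + h; dn[j] <- dn[j] - h
      g <- (predict(rq$fit, t(as.matrix(up))) -
              predict(rq$fit, t(as.matrix(dn)))) / (2 * h)
      expect_lt(abs(g), 1e-6)
    }
    # nature agrees with eigenvalue signs
    ev <- sp$eigenvalues
    expected <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
                else "saddle"
    expect_identical(sp$nature, expected)
  }
})

test_that("simple surfaces are classified correctly", {
  f1 <- list(ccd_factor("X1", 0, 1))
  d1 <- ccd_design(f1, n_center = 3)
  # y = 10 - x^2: maximum at 0 with value 10
  y <- 10 - d1$X1^2
  sp <- stationary_point(quad_fit(d1, y))
  expect_equal(unname(sp$coded), 0, tolerance = 1e-8)
  expect_equal(sp$predicted, 10, tolerance = 1e-8)
  expect_identical(sp$nature, "maximum")

  # y = x1^2 - x2^2: saddle at the origin
  f2 <- list(ccd_factor("X1", 0, 1), ccd_factor("X2", 0, 1))
  d2 <- ccd_design(f2, n_center = 3)
  y2 <- d2$X1^2 - d2$X2^2
  sp2 <- stationary_point(quad_fit(d2, y2))
  expect_equal(unname(sp2$coded), c(0, 0), tolerance = 1e-8)
  expect_identical(sp2$nature, "saddle")
})

test_that("constrained box optimum agrees with a fine grid oracle", {
  fit <- cellulase_ccd_fit()
  r <- rotatable_alpha(3)
  opt <- optimize_region(fit, "box", radius = r)
  oracle <- oracle_box_argmax(unname(fit$coefficients), 3, r)
  expect_equal(opt$predicted, oracle$value, tolerance = 1e-3)
  expect_gte(opt$predicted, oracle$value - 1e-10)
  expect_true(all(abs(opt$coded) <= r + 1e-9))

  # random surfaces, including non-concave ones where the max is on the hull
  for (seed in c(2, 9, 31)) {
    rq <- random_quad_fit(seed)
    o <- optimize_region(rq$fit, "box", radius = 1.5)
    g <- oracle_box_argmax(unname(rq$fit$coefficients), 3, 1.5)
    expect_gte(o$predicted + 1e-9, g$value)
    expect_equal(o$predicted, g$value, tolerance = 1e-3)
    expect_true(all(abs(o$coded) <= 1.5 + 1e-9))
  }
})

test_that("sphere optimum stays on the ball and dominates a direction sweep", {
  for (seed in c(4, 12, 27)) {
    rq <- random_quad_fit(seed)
    o <- optimize_region(rq$fit, "sphere", radius = 1.3)
    expect_lte(sqrt(sum(o$coded^2)), 1.3 + 1e-8)
    set.seed(seed)
    u <- matrix(rnorm(3 * 500), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- u * 1.3 * runif(500)^(1 / 3)
    colnames(pts) <- rq$fit$factor_names
    expect_gte(o$predicted + 1e-8, max(predict(rq$fit, pts)))
  }
})

test_that("a concave interior optimum equals the stationary point", {
  for (seed in c(6, 14)) {
    rq <- random_quad_fit(seed, concave = TRUE)
    sp <- stationary_point(rq$fit)
    if (sp$nature != "maximum" || any(abs(sp$coded) > 1)) next
    for (region in c("box", "sphere")) {
      o <- optimize_region(rq$fit, region, radius = 1.681793)
      expect_equal(unname(o$coded), unname(sp$coded), tolerance = 1e-8)
      expect_equal(o$predicted, sp$predicted, tolerance = 1e-10)
    }
  }
})

test_that("surface grids are consistent with the model and symmetric in pair order", {
  fit <- cellulase_ccd_fit()
  g <- surface_grid(fit, c("CMC", "MgSO4"), resolution = 51)
  expect_equal(nrow(g), 51^2)
  center <- g[abs(g$CMC) < 1e-9 & abs(g$MgSO4) < 1e-9, "predicted"]
  expect_equal(center, predict(fit, data.frame(CMC = 0, MgSO4 = 0, pH = 0)),
               tolerance = 1e-10)

  # transposing the pair permutes, not changes, the predictions
  g2 <- surface_grid(fit, c("MgSO4", "CMC"), resolution = 51)
  m1 <- matrix(g$predicted, 51, 51)
  m2 <- matrix(g2$predicted, 51, 51)
  expect_equal(m1, t(m2), tolerance = 1e-12)

  # fitted pH main effect is negative, so the optimum over (MgSO4, pH)
  # at center CMC sits at coded pH < 0
  g3 <- surface_grid(fit, c("MgSO4", "pH"), resolution = 101)
  expect_lt(g3$pH[which.max(g3$predicted)], 0)

  expect_error(surface_grid(fit, c("CMC", "CMC")), "distinct")
  expect_error(surface_grid(fit, c("CMC", "MgSO4"), resolution = 1),
               "at least 2")
})
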