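test_that("12-run screening design is the cyclic generator construction", {
  d <- pb_design(12, n_process = 8, n_dummy = 3)
  m <- as.matrix(d[, -1])
  expect_equal(nrow(m), 12)
  expect_equal(ncol(m), 11)
  # first run is the generator, last run is all low
  expect_equal(unname(m[1, ]), c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1))
  expect_equal(unname(m[12, ]), rep(-1, 11))
  # each run is a one-position rotation of the previous
  for (i in 2:11)
    expect_equal(unname(m[i, ]), unname(c(m[i - 1, 11], m[i - 1, 1:10])))
  # roles: last 3 columns are dummies
  roles <- attr(d, "roles")
  expect_equal(unname(roles), c(rep("factor", 8), rep("dummy", 3)))
})

test_that("screening designs are balanced and mutually orthogonal", {
  for (n in c(8, 12, 16, 20)) {
    m <- as.matrix(pb_design(n, n_process = n - 1, n_dummy = 0)[, -1])
    expect_true(all(colSums(m == 1) == n / 2), info = paste("runs =", n))
    # brute force over every distinct column pair
    for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m))
      expect_identical(sum(m[, i] * m[, j]), 0)
  }
})

test_that("unsupported or inconsistent screening dimensions are rejected", {
  expect_error(pb_design(10, 9), "supported sizes")
  expect_error(pb_design(12, 8, 2), "n_runs - 1")
  expect_error(pb_design(12, 0, 11), "n_process")
})

test_that("rotatable axial distance is (2^k)^(1/4)", {
  expect_equal(rotatable_alpha(3), 1.681793, tolerance = 1e-6)
  expect_equal(rotatable_alpha(2), sqrt(2))
  expect_equal(rotatable_alpha(4), 2)
  expect_error(rotatable_alpha(0), "positive")
})

test_that("CCD has factorial, axial and center blocks in standard order", {
  f <- list(ccd_factor("CMC", 1, 0.5), ccd_factor("MgSO4", 0.275, 0.225),
            ccd_factor("pH", 8.5, 1.5))
  d <- ccd_design(f, n_center = 6)
  m <- as.matrix(d[, -1])
  a <- rotatable_alpha(3)
  expect_equal(nrow(m), 2^3 + 2 * 3 + 6)
  expect_true(all(abs(m[1:8, ]) == 1))              # factorial block
  expect_equal(unname(m[9, ]), c(-a, 0, 0))          # axial pairs in order
  expect_equal(unname(m[10, ]), c(a, 0, 0))
  expect_equal(unname(m[14, ]), c(0, 0, a))
  expect_true(all(m[15:20, ] == 0))                  # center replicates
  expect_equal(unname(colSums(m)), rep(0, 3))        # symmetry
  expect_equal(unname(colSums(m^2)), rep(8 + 2 * a^2, 3), tolerance = 1e-12)
})

test_that("CCD run count is conserved for k = 2, 3, 4", {
  for (k in 2:4) {
    f <- lapply(seq_len(k), function(j) ccd_factor(paste0("X", j), 0, 1))
    d <- ccd_design(f, n_center = 4)
    expect_equal(nrow(d), 2^k + 2 * k + 4)
  }
})

test_that("rotatable CCD has direction-independent prediction variance", {
  f <- lapply(1:3, function(j) ccd_factor(paste0("X", j), 0, 1))
  d <- ccd_design(f, n_center = 6)
  X <- oracle_quad_mm(as.matrix(d[, -1]))
  XtXi <- solve(crossprod(X))
  set.seed(11)
  for (r in c(0.5, 1, 1.5)) {
    u <- matrix(rnorm(3 * 40), ncol = 3)
    u <- r * u / sqrt(rowSums(u^2))
    v <- vapply(seq_len(nrow(u)), function(i) {
      x <- oracle_quad_mm(u[i, , drop = FALSE])
      drop(x %*% XtXi %*% t(x))
    }, 0)
    expect_lt(diff(range(v)) / mean(v), 1e-8)
  }
})

test_that("coded/actual mapping matches the case-study levels and round-trips", {
  cmc <- ccd_factor("CMC", 1.0, 0.5)
  mg <- ccd_factor("MgSO4", 0.275, 0.225)
  a <- rotatable_alpha(3)
  expect_equal(coded_to_actual(cmc, a), 1.840896, tolerance = 1e-6)
  expect_equal(coded_to_actual(cmc, 0), 1.0)
  expect_warning(lvl <- coded_to_actual(mg, -a), "negative")
  expect_equal(lvl, -0.10340, tolerance = 1e-4)
  for (coded in c(-a, -1, 0, 1, a))
    expect_equal(actual_to_coded(mg, coded_to_actual(mg, coded,
                                                     warn_infeasible = FALSE)),
                 coded, tolerance = 1e-12)
})

test_that("factor constructors validate their levels", {
  expect_error(ccd_factor("X", 0, -1), "positive")
  expect_error(pb_factor("pH", 9, 5), "inverted")
  expect_silent(pb_factor("pH", 9, 5, allow_inverted = TRUE))
  expect_error(coded_to_actual(pb_factor("A", 0, 1), 1), "ccd_factor")
})
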