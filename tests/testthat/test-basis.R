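test_that("constant and step bases evaluate to the expected indicator columns", {
  b <- eval_basis(2:40, basis_spec("constant"))
  expect_identical(dim(b$values), c(39L, 1L))
  expect_true(all(b$values == 1))

  # single cut-off at lag 20 over lags 2-40: strata of sizes 18 and 21
  s <- eval_basis(2:40, basis_spec("step", knots = 20,
                                   boundary = c(1.5, 40.5), intercept = TRUE))
  expect_identical(ncol(s$values), 2L)
  expect_equal(unname(colSums(s$values)), c(18, 21))
  expect_true(all(rowSums(s$values) == 1))

  # without intercept the first stratum is the reference
  s2 <- eval_basis(2:40, basis_spec("step", knots = 20,
                                    boundary = c(1.5, 40.5)))
  expect_identical(ncol(s2$values), 1L)
  expect_equal(unname(s2$values[, 1]), as.numeric(2:40 >= 20))
})

test_that("B-spline bases satisfy partition of unity and dimension bookkeeping", {
  set.seed(1)
  x <- runif(200, 0, 40)
  b <- eval_basis(x, basis_spec("bspline", degree = 2, knots = c(13.3, 26.7),
                                boundary = c(0, 40), intercept = TRUE))
  expect_equal(rowSums(b$values), rep(1, 200), tolerance = 1e-12)

  # quadratic, 2 knots: 5 columns with intercept, 4 without
  expect_identical(ncol(b$values), 5L)
  expect_identical(basis_dim(basis_spec("bspline", 2, c(13.3, 26.7),
                                        c(0, 40), intercept = FALSE)), 4L)
  # natural cubic: #knots + 1 (+ intercept)
  expect_identical(basis_dim(basis_spec("nspline", knots = 2.5,
                                        boundary = c(0, 10))), 2L)
  expect_identical(basis_dim(basis_spec("nspline", knots = 2.5,
                                        boundary = c(0, 10),
                                        intercept = TRUE)), 3L)
  expect_identical(basis_dim(basis_spec("threshold", knots = c(1, 2),
                                        boundary = c(0, 10))), 2L)
})

test_that("dropping the intercept left-constrains the curve to zero at l0", {
  spec <- basis_spec("bspline", degree = 2, knots = 13.3, boundary = c(2, 40),
                     intercept = TRUE)
  b <- eval_basis(2:40, spec)
  expect_identical(ncol(b$values), 4L)
  b2 <- drop_intercept(b)
  expect_identical(ncol(b2$values), 3L)
  # the evaluated row at the left boundary is identically zero, so any
  # coefficient vector predicts a null risk at lag 2
  expect_equal(unname(b2$values[1, ]), rep(0, 3))
  expect_error(drop_intercept(eval_basis(1:5, basis_spec("constant"))),
               "intercept")
})

test_that("right constraint zeroes the basis row at the end of the lag window", {
  spec <- basis_spec("bspline", degree = 2, knots = 20, boundary = c(0, 40),
                     intercept = FALSE)
  b <- eval_basis(0:40, spec)
  expect_identical(ncol(b$values), 3L)
  b2 <- apply_right_constraint(b)
  expect_identical(ncol(b2$values), 2L)
  expect_equal(unname(b2$values[41, ]), rep(0, 2))
  # any linear combination is therefore exactly zero at L
  set.seed(2)
  for (r in 1:5) {
    eta <- rnorm(2)
    expect_identical(drop(b2$values[41, ] %*% eta), 0)
  }
  expect_error(apply_right_constraint(eval_basis(1:5, basis_spec("linear"))),
               "B-spline")
})

test_that("centering returns the basis row at the reference exposure", {
  expect_equal(center_basis_row(basis_spec("linear", boundary = c(0, 10)), 0), 0)
  expect_equal(center_basis_row(basis_spec("logshift", boundary = c(0, 10),
                                           shift = 1), 0), 0)
  spec <- basis_spec("bspline", 2, 5, c(0, 10))
  expect_equal(center_basis_row(spec, 3),
               unname(drop(eval_basis(3, spec)$values)))
  expect_error(center_basis_row(spec, 12), "outside")
})

test_that("spline evaluation refuses out-of-boundary points unless extrapolation is requested", {
  spec <- basis_spec("bspline", 2, 5, c(0, 10))
  expect_error(eval_basis(c(1, 11), spec), "boundary")
  # opt-in extrapolation continues linearly from the boundary
  m <- eval_basis(c(10, 10.5, 11), spec, extrapolate = TRUE)$values
  expect_equal(m[3, ] - m[2, ], m[2, ] - m[1, ], tolerance = 1e-10)
  expect_error(basis_spec("bspline", 2, knots = c(5, 3), boundary = c(0, 10)),
               "increasing")
  expect_error(basis_spec("bspline", 2, knots = 12, boundary = c(0, 10)),
               "inside")
})

test_that("eval_basis is deterministic and permutation-equivariant", {
  set.seed(3)
  x <- runif(50, 0, 40)
  perm <- sample(50)
  for (spec in list(basis_spec("bspline", 2, 20, c(0, 40), intercept = TRUE),
                    basis_spec("step", knots = c(10, 30), boundary = c(0, 40),
                               intercept = TRUE),
                    basis_spec("logshift", boundary = c(0, 40)))) {
    a <- eval_basis(x, spec)$values
    b <- eval_basis(x[perm], spec)$values
    expect_identical(a[perm, , drop = FALSE], b)
    expect_identical(a, eval_basis(x, spec)$values)
  }
})

test_that("the unique-value fast path agrees with direct evaluation", {
  set.seed(4)
  x <- sample(runif(40, 0, 10), 5000, replace = TRUE)  # heavy repetition
  for (spec in list(basis_spec("bspline", 2, 5, c(0, 10)),
                    basis_spec("nspline", knots = 5, boundary = c(0, 10)),
                    basis_spec("threshold", knots = 3, boundary = c(0, 10)))) {
    fast <- eval_basis(x, spec)$values
    slow <- do.call(rbind, lapply(x, function(xi)
      eval_basis(xi, spec)$values))
    expect_equal(fast, slow, tolerance = 1e-14)
  }
})

test_that("basis specs survive the flat-list serialization round trip", {
  specs <- list(basis_spec("bspline", 2, c(13.3, 26.7), c(2, 40),
                           intercept = TRUE, right_constrained = TRUE),
                basis_spec("step", knots = 20, boundary = c(1.5, 40.5),
                           intercept = TRUE),
                basis_spec("logshift", boundary = c(0, 100), shift = 2))
  for (s in specs)
    expect_equal(basis_spec_from_list(basis_spec_to_list(s)), s)
})
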