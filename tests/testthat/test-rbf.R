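all_kernels <- c("thin_plate", "multiquadric", "inverse_multiquadric",
                 "completely_regularized_spline", "tension_spline")

test_that("kernels match their closed forms at and near the origin", {
  expect_equal(rbf_kernel_eval(rbf_kernel("multiquadric", 3), 0), 3)
  expect_equal(rbf_kernel_eval(rbf_kernel("inverse_multiquadric", 4), 0), 1 / 4)
  expect_equal(rbf_kernel_eval(rbf_kernel("thin_plate", 2), 0), 0)
  # analytic small-r limits of the spline kernels
  expect_equal(rbf_kernel_eval(rbf_kernel("completely_regularized_spline"), 0), 0)
  expect_equal(rbf_kernel_eval(rbf_kernel("tension_spline"), 0), 0)
  expect_lt(rbf_kernel_eval(rbf_kernel("completely_regularized_spline"), 1e-7), 1e-12)
  expect_lt(rbf_kernel_eval(rbf_kernel("tension_spline"), 1e-7), 1e-12)
})

test_that("regularized spline agrees with a quadrature oracle for E1", {
  # sigma = 2, r = 1 gives u = 1: value is log(1) + E1(1) + C_E
  got <- rbf_kernel_eval(rbf_kernel("completely_regularized_spline", 2), 1)
  expect_equal(got, e1_quadrature(1) + 0.577215, tolerance = 1e-8)
  # a second point off the special case
  u <- (2 * 0.7 / 2)^2
  expect_equal(rbf_kernel_eval(rbf_kernel("completely_regularized_spline", 2), 0.7),
               log(u) + e1_quadrature(u) + 0.577215, tolerance = 1e-8)
})

test_that("tension spline agrees with the Bessel closed form", {
  s <- 1.5; r <- 0.8
  expect_equal(rbf_kernel_eval(rbf_kernel("tension_spline", s), r),
               log(s * r / 2) + besselK(s * r, 0) + 0.577215)
  expect_error(rbf_kernel_eval(rbf_kernel("tension_spline"), -1), "nonnegative")
})

test_that("every kernel family interpolates exactly at the data sites", {
  loc <- scatter_layout(12, seed = 3)
  z <- smooth_field(loc)
  for (kind in all_kernels) {
    m <- rbf_fit(loc, z, rbf_kernel(kind, 1))
    expect_equal(rbf_predict(m, loc), z, tolerance = 1e-6,
                 info = kind)
  }
})

test_that("constant data is reproduced everywhere", {
  loc <- scatter_layout(10, seed = 5)
  targets <- scatter_layout(30, seed = 6)
  for (kind in all_kernels) {
    m <- rbf_fit(loc, rep(7.5, 10), rbf_kernel(kind, 1))
    expect_equal(rbf_predict(m, targets), rep(7.5, 30), tolerance = 1e-6,
                 info = kind)
  }
})

test_that("fitted weights solve the documented augmented system", {
  # independent dense solve of the same system, standardized identically
  loc <- scatter_layout(5, seed = 21)
  z <- smooth_field(loc)
  kern <- rbf_kernel("tension_spline", 0.01)
  m <- rbf_fit(loc, z, kern)
  ctr <- colMeans(loc)
  scl <- sqrt(mean(apply(loc, 2, var)))
  xs <- sweep(loc, 2, ctr) / scl
  D <- as.matrix(dist(xs))
  A <- rbind(cbind(rbf_kernel_eval(kern, D), 1), c(rep(1, 5), 0))
  sol <- solve(A, c(z, 0))
  expect_equal(m$weights, sol[1:5], tolerance = 1e-8)
  expect_equal(m$bias, sol[6], tolerance = 1e-8)
  # residual of the augmented system is tiny relative to the value scale
  expect_lt(max(abs(A %*% c(m$weights, m$bias) - c(z, 0))),
            1e-8 * max(abs(z)))
})

test_that("collinear stations remain solvable with the bias term", {
  loc <- cbind(seq(0, 100, length.out = 8), 0)
  z <- 2 + 0.3 * loc[, 1]
  m <- rbf_fit(loc, z, rbf_kernel("thin_plate", 1))
  expect_equal(rbf_predict(m, loc), z, tolerance = 1e-6)
})

test_that("splines may overshoot the data range, unlike IDW", {
  # a sharp peak between stations forces overshoot
  loc <- cbind(seq(0, 10, length.out = 9), 0)
  z <- c(0, 0, 0, 8, 10, 8, 0, 0, 0)
  m <- rbf_fit(loc, z, rbf_kernel("thin_plate", 1))
  fine <- cbind(seq(0, 10, length.out = 201), 0)
  pred <- rbf_predict(m, fine)
  # the spline rings below the flat shoulders of the peak
  expect_lt(min(pred), min(z))
})

test_that("predictions are invariant to a common rescaling of coordinates", {
  # internal standardization makes the fitted surface scale-free
  loc <- scatter_layout(9, seed = 13)
  z <- smooth_field(loc)
  targets <- scatter_layout(7, seed = 14)
  for (kind in c("completely_regularized_spline", "tension_spline")) {
    k <- rbf_kernel(kind, 2)
    p1 <- rbf_predict(rbf_fit(loc, z, k), targets)
    p2 <- rbf_predict(rbf_fit(loc * 1000, z, k), targets * 1000)
    expect_equal(p1, p2, tolerance = 1e-8, info = kind)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(rbf_fit(rbind(c(0, 0)), 1, rbf_kernel()), "at least 2")
  expect_error(rbf_fit(rbind(c(0, 0), c(0, 0)), c(1, 2), rbf_kernel()),
               "duplicate")
  expect_error(rbf_kernel("multiquadric", -1), "sigma")
})

test_that("held-out error shrinks as the sample grows on a smooth field", {
  # spline convergence: same field, doubled sampling density
  hold <- scatter_layout(20, seed = 77, extent = 80) + 10
  truth <- smooth_field(hold)
  mae_at <- function(n) {
    loc <- scatter_layout(n, seed = 101)
    z <- smooth_field(loc)
    sel <- rbf_select_sigma(loc, z, "completely_regularized_spline")
    m <- rbf_fit(loc, z, rbf_kernel("completely_regularized_spline", sel$sigma))
    mean(abs(rbf_predict(m, hold) - truth))
  }
  expect_lt(mae_at(100), mae_at(50))
})
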