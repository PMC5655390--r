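test_that("empirical semivariogram matches hand-computed cases", {
  # one pair, one bin: gamma = (3 - 1)^2 / 2 = 2
  ev <- empirical_semivariogram(rbind(c(0, 0), c(1, 0)), c(1, 3),
                                n_lags = 1, max_dist = 2)
  expect_equal(ev$gamma, 2)
  expect_equal(ev$np, 1L)
  # constant field: zero semivariance in every retained bin
  loc <- scatter_layout(30, seed = 2)
  ev <- empirical_semivariogram(loc, rep(4, 30))
  expect_true(all(ev$gamma == 0))
  expect_true(all(diff(ev$dist) > 0))
  expect_true(all(ev$np >= 1))
  # all pairs beyond max_dist is an error
  expect_error(empirical_semivariogram(rbind(c(0, 0), c(100, 0)), c(1, 2),
                                       max_dist = 1), "within max_dist")
})

test_that("semivariance rises towards the range on a simulated field", {
  s <- simulate_grf(100, model = variogram_model("gaussian", 0, 1, 2500),
                    seed = 31)
  v <- station_values(s, "pm25")
  ev <- empirical_semivariogram(v$locations, v$values)
  near <- ev$gamma[ev$dist < 800]
  far <- ev$gamma[ev$dist > 2000 & ev$dist < 4000]
  expect_lt(mean(near), mean(far))
})

test_that("variogram models evaluate to their closed forms", {
  m <- variogram_model("gaussian", nugget = 0.2, psill = 1.5, range = 100)
  # sill limit far beyond the range
  expect_equal(variogram_eval(m, 100 * 100), 1.7, tolerance = 1e-9)
  # gamma(0) = 0 by convention; nugget only for h > 0
  expect_equal(variogram_eval(m, 0), 0)
  expect_equal(variogram_eval(m, 1e-9), 0.2, tolerance = 1e-9)
  # stable with shape 2 degenerates to gaussian
  st <- variogram_model("stable", 0.2, 1.5, 100, shape = 2)
  h <- seq(0, 500, by = 7)
  expect_equal(variogram_eval(st, h), variogram_eval(m, h))
  # hole effect at half the range: sin(pi)/pi = 0 so value is the sill
  he <- variogram_model("hole_effect", 0.1, 2, 60)
  expect_equal(variogram_eval(he, 30), 0.1 + 2)
  # J-Bessel uses J0
  jb <- variogram_model("j_bessel", 0.1, 2, 60)
  expect_equal(variogram_eval(jb, 45), 0.1 + 2 * (1 - besselJ(2 * pi * 45 / 60, 0)))
  expect_error(variogram_eval(m, -1), "nonnegative")
})

test_that("weighted least squares recovers noise-free parameters", {
  truth <- variogram_model("gaussian", nugget = 0.3, psill = 2, range = 1500)
  h <- seq(100, 3000, length.out = 10)
  ev <- structure(
    data.frame(dist = h, gamma = variogram_eval(truth, h),
               np = rep(50L, 10)),
    class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(ev, "gaussian")
  expect_equal(fit$nugget, 0.3, tolerance = 0.01)
  expect_equal(fit$psill, 2, tolerance = 0.01)
  expect_equal(fit$range, 1500, tolerance = 0.01 * 1500)
  # too few bins is a precondition failure
  expect_error(fit_variogram(ev[1:2, ], "gaussian"), "3")
})

test_that("kriging honours symmetry and the unbiasedness constraint", {
  m <- variogram_model("gaussian", 0, 1, 10)
  # two equidistant stations: prediction is the average
  kp <- kriging_predict(rbind(c(-1, 0), c(1, 0), c(0, 50)), c(10, 30, 20),
                        rbind(c(0, 0)), m, check_hull = FALSE)
  expect_equal(kp$predictions, 20, tolerance = 1e-8)
  # weights sum to one on an arbitrary five-station layout
  loc <- scatter_layout(5, seed = 12)
  z <- smooth_field(loc)
  kp <- kriging_predict(loc, z, scatter_layout(4, seed = 13), m,
                        check_hull = FALSE, details = TRUE)
  expect_equal(colSums(kp$weights), rep(1, 4), tolerance = 1e-8)
})

test_that("ordinary kriging equals an independent dense solve", {
  loc <- scatter_layout(4, seed = 19)
  z <- smooth_field(loc)
  m <- variogram_model("stable", 0.1, 1.2, 40, shape = 1.3)
  targets <- scatter_layout(6, seed = 20)
  got <- kriging_predict(loc, z, targets, m, check_hull = FALSE)
  # oracle: assemble and solve the augmented system directly
  G <- variogram_eval(m, as.matrix(dist(loc)))
  A <- rbind(cbind(G, 1), c(rep(1, 4), 0))
  oracle <- apply(targets, 1, function(t0) {
    g0 <- variogram_eval(m, sqrt(colSums((t(loc) - t0)^2)))
    sol <- solve(A, c(g0, 1))
    sum(sol[1:4] * z)
  })
  expect_equal(got$predictions, oracle, tolerance = 1e-10)
})

test_that("exactness at data sites and nonnegative kriging variance", {
  loc <- scatter_layout(9, seed = 23)
  z <- smooth_field(loc)
  m0 <- variogram_model("gaussian", 0, 1, 60)
  kp <- kriging_predict(loc, z, loc, m0, check_hull = FALSE)
  expect_equal(kp$predictions, z, tolerance = 1e-6)
  expect_equal(kp$variance, rep(0, 9), tolerance = 1e-6)
  away <- kriging_predict(loc, z, scatter_layout(11, seed = 24), m0,
                          check_hull = FALSE)
  expect_true(all(away$variance >= 0))
  # with gamma(0) = 0 the solved system stays exact under a nugget too;
  # nugget filtering (measurement-error smoothing) is deliberately not done
  mn <- variogram_model("gaussian", 0.4, 1, 60)
  kpn <- kriging_predict(loc, z, loc, mn, check_hull = FALSE)
  expect_equal(kpn$predictions, z, tolerance = 1e-6)
})

test_that("universal kriging with zero-order drift reproduces ordinary", {
  loc <- scatter_layout(12, seed = 29)
  z <- smooth_field(loc)
  targets <- scatter_layout(8, seed = 30)
  m <- variogram_model("gaussian", 0.05, 1, 50)
  ok <- kriging_predict(loc, z, targets, m, mode = "ordinary",
                        check_hull = FALSE)
  uk0 <- kriging_predict(loc, z, targets, m, mode = "universal",
                         drift_order = 0, check_hull = FALSE)
  expect_equal(uk0$predictions, ok$predictions, tolerance = 1e-10)
  expect_equal(uk0$variance, ok$variance, tolerance = 1e-10)
})

test_that("nearest station dominates the weights on a transect", {
  loc <- cbind(c(0, 10, 20, 35, 60), 0)
  z <- c(3, 4, 5, 6, 7)
  m <- variogram_model("gaussian", 0.01, 1, 25)
  kp <- kriging_predict(loc, z, rbind(c(11, 0)), m, check_hull = FALSE,
                        details = TRUE)
  expect_equal(which.max(abs(kp$weights[, 1])), 2L)
})

test_that("extrapolation outside the hull warns but proceeds", {
  loc <- scatter_layout(6, seed = 40)
  z <- smooth_field(loc)
  m <- variogram_model("gaussian", 0.1, 1, 50)
  expect_warning(
    kriging_predict(loc, z, rbind(c(1e4, 1e4)), m),
    "convex hull")
})
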