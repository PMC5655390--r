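test_that("identical seeds reproduce the identical network", {
  a <- simulate_grf(30, seed = 5)
  b <- simulate_grf(30, seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c <- simulate_grf(30, seed = 6)
  expect_false(identical(as.data.frame(a)$pm25_mean,
                         as.data.frame(c)$pm25_mean))
  # the caller's RNG stream is untouched
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(simulate_grf(10, seed = 99)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("degenerate configurations collapse to the floor / drift", {
  flat <- simulate_grf(10, model = variogram_model("gaussian", 0, 0, 1000),
                       value_floor = 12, seed = 1)
  expect_equal(as.data.frame(flat)$pm25_mean, rep(12, 10))
  plane <- simulate_grf(10, model = NULL, drift = c(1, 0.001, 0),
                        value_floor = 5, seed = 2)
  d <- as.data.frame(plane)
  expect_equal(d$pm25_mean, 5 + 1 + 0.001 * d$easting, tolerance = 1e-12)
})

test_that("marginal variance matches the configured sill", {
  vars <- vapply(1:20, function(sd) {
    var(station_values(simulate_grf(200, seed = sd), "pm25")$values)
  }, numeric(1))
  expect_gt(mean(vars), 0.6)
  expect_lt(mean(vars), 1.6)
})

test_that("oscillatory covariances are validity-checked and simulable", {
  # sinc and J0 correlations are (borderline) positive definite in 2-D;
  # the eigenvalue check passes and near-zero modes are handled by the
  # Cholesky jitter retry
  for (kind in c("hole_effect", "j_bessel")) {
    s <- simulate_grf(60, model = variogram_model(kind, 0, 1, 1500),
                      bbox = c(0, 5000, 0, 5000), seed = 3)
    v <- station_values(s, "pm25")$values
    expect_length(v, 60)
    expect_true(all(is.finite(v)))
  }
})

test_that("truth surface evaluates the drift and rejects stochastic configs", {
  tg <- rbind(c(2, 3), c(10, 0))
  expect_equal(truth_surface(tg, c(0, 1, 0), value_floor = 2),
               c(4, 12))
  expect_equal(truth_surface(tg, c(5, 0, 0)), c(5, 5))
  expect_error(
    truth_surface(tg, c(0, 1, 0), model = variogram_model("gaussian", 0.1, 1, 10)),
    "drift-only")
})

test_that("universal kriging recovers a noiseless plane exactly", {
  s <- simulate_grf(40, model = NULL, drift = c(5, 0.002, -0.001),
                    value_floor = 40, seed = 7)
  v <- station_values(s, "pm25")
  tg <- rbind(c(1000, 2000), c(3500, 5000), c(6000, 1000))
  kp <- kriging_predict(v$locations, v$values, tg,
                        variogram_model("gaussian", 0, 1, 2000),
                        mode = "universal", check_hull = FALSE)
  expect_equal(kp$predictions,
               truth_surface(tg, c(5, 0.002, -0.001), 40),
               tolerance = 1e-6)
})

test_that("variogram range is recoverable from simulated fields", {
  fits <- vapply(1:20, function(sd) {
    v <- station_values(simulate_grf(200, seed = sd), "pm25")
    fit_variogram(empirical_semivariogram(v$locations, v$values),
                  "gaussian")$range
  }, numeric(1))
  expect_gt(mean(fits), 0.7 * 2000)
  expect_lt(mean(fits), 1.3 * 2000)
})

test_that("drift-aware kriging beats ordinary kriging on drifted fields", {
  wins <- vapply(1:5, function(sd) {
    s <- simulate_grf(60, model = variogram_model("gaussian", 0.1, 1, 2000),
                      drift = c(0, 0.002, 0.001), value_floor = 50, seed = sd)
    uk <- cv_metrics(suppressWarnings(
      loocv(s, "pm25", kriging_spec("universal", "gaussian"), lambda = 0)))[["rmse"]]
    ok <- cv_metrics(suppressWarnings(
      loocv(s, "pm25", kriging_spec("ordinary", "gaussian"), lambda = 0)))[["rmse"]]
    uk < ok
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("no method finds structure in a pure-nugget field", {
  ratios <- sapply(1:5, function(sd) {
    s <- simulate_grf(60, model = variogram_model("gaussian", 1, 0, 2000),
                      value_floor = 50, seed = sd)
    v <- station_values(s, "pm25")
    sdv <- sd(v$values)
    c(idw = cv_metrics(suppressWarnings(
        loocv(s, "pm25", idw_spec(1), lambda = 0)))[["rmse"]] / sdv,
      ok = cv_metrics(suppressWarnings(
        loocv(s, "pm25", kriging_spec("ordinary", "gaussian"),
              lambda = 0)))[["rmse"]] / sdv)
  })
  expect_true(all(abs(rowMeans(ratios) - 1) < 0.2))
})
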