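test_that("model construction enforces stability, lag and duplicate rules", {
  expect_silent(m <- ar1_model(0.9))
  expect_lt(m$spectral_radius, 1)
  expect_error(ar1_model(1.1), "spectral radius")
  expect_error(make_var_model(2, data.frame(source = 1, target = 2, lag = 0,
                                            coefficient = 0.3)),
               "lag")
  expect_error(make_var_model(2, data.frame(source = c(1, 1), target = c(2, 2),
                                            lag = c(1, 1),
                                            coefficient = c(0.3, 0.2))),
               "duplicate")
  expect_error(make_var_model(2, data.frame(source = 3, target = 1, lag = 1,
                                            coefficient = 0.3)),
               "indices")
  # empty link set: valid pure-noise model
  m0 <- make_var_model(3)
  expect_equal(nrow(m0$links), 0)
  expect_equal(m0$spectral_radius, 0)
})

test_that("pure-noise simulation is white within sampling error", {
  s <- simulate_process(make_var_model(3), 2000, seed = 1)
  expect_equal(dim(s$values), c(2000L, 3L))
  for (j in 1:3) {
    expect_lt(abs(mean(s$values[, j])), 4 / sqrt(2000))
    r1 <- cor(s$values[-2000, j], s$values[-1, j])
    expect_lt(abs(r1), 4 / sqrt(2000))
  }
})

test_that("autoregressive simulation reproduces the closed-form autocorrelation", {
  s <- simulate_process(ar1_model(0.6), 3000, seed = 2)
  x <- s$values[, 1]
  expect_equal(cor(x[-3000], x[-1]), 0.6, tolerance = 0.1)
  # a^tau decay at tau = 2
  expect_equal(cor(x[1:2998], x[3:3000]), 0.36, tolerance = 0.15)
})

test_that("a lagged cross-link leaves its signature in the lagged covariance", {
  m <- make_var_model(2, data.frame(source = 1, target = 2, lag = 1,
                                    coefficient = 0.5))
  s <- simulate_process(m, 5000, seed = 3)
  x <- s$values
  lag_cov <- cov(x[-5000, 1], x[-1, 2])
  # cov(X1_{t-1}, X2_t) = 0.5 * var(X1) = 0.5 for unit-variance innovations
  expect_gt(lag_cov, 0)
  expect_equal(lag_cov, 0.5, tolerance = 0.1)
})

test_that("simulation is seed-deterministic and approximately stationary", {
  m <- random_stable_model(4, 3, seed = 5)
  a <- simulate_process(m, 500, seed = 9)
  b <- simulate_process(m, 500, seed = 9)
  expect_identical(a$values, b$values)
  s <- simulate_process(m, 4000, seed = 10)
  half <- 1:2000
  for (j in 1:4) {
    x1 <- s$values[half, j]; x2 <- s$values[-half, j]
    se <- sd(s$values[, j]) / sqrt(2000)
    expect_lt(abs(mean(x1) - mean(x2)), 5 * se)
    expect_lt(abs(sd(x1) - sd(x2)) / sd(s$values[, j]), 0.2)
  }
})

test_that("smoothing kernel and decimation behave as direct convolution", {
  s <- simulate_process(make_var_model(2), 100, seed = 4)
  out <- apply_hrf_downsample(s, kernel = 1)
  expect_equal(out$values, s$values)
  # unit impulse through a known 5-tap kernel reproduces the kernel
  kern <- c(0.1, 0.3, 0.4, 0.15, 0.05)
  imp <- roi_ts(matrix(c(rep(0, 4), 1, rep(0, 10)), ncol = 1), "a",
                sampling_interval = 1)
  conv <- apply_hrf_downsample(imp, kernel = kern)
  expect_equal(conv$values[1:5, 1], kern)
  # decimation carries the new sampling interval; 2.8 s from 1.4 s is factor 2
  s2 <- roi_ts(s$values, s$labels, sampling_interval = 1.4)
  down <- apply_hrf_downsample(s2, kernel = 1, out_interval = 2.8)
  expect_equal(down$sampling_interval, 2.8)
  expect_equal(nrow(down$values), 50)
  expect_error(apply_hrf_downsample(s2, kernel = 1, out_interval = 2.1),
               "integer multiple")
})

test_that("fixture round-trips through the reader with its ground truth", {
  m <- example_motor_model()
  expect_equal(length(m$labels), 14)
  expect_identical(m$labels, motor_roi_table()$abbreviation)
  s <- simulate_process(m, 60, seed = 6, sampling_interval = 2.8)
  d <- withr::local_tempdir()
  files <- write_fixture(s, m, d)
  expect_equal(length(files), 14 + 3)
  back <- read_roi_timeseries(file.path(d, paste0(m$labels, ".txt")),
                              sampling_interval = 2.8)
  expect_equal(back$values, s$values, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$labels, m$labels)
  truth <- read.delim(file.path(d, "truth_links.tsv"))
  expect_equal(truth, m$links, ignore_attr = TRUE)
  m2 <- read_fixture_model(file.path(d, "model.yml"))
  expect_equal(m2$links, m$links, ignore_attr = TRUE)
})
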