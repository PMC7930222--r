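test_that("partial correlation handles perfect dependence and known partials", {
  x <- rnorm(100)
  res <- parcorr_test(x, x)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 0)
  # constructed triple: x = z + u, y = z + v with cor(u, v) = 0.5, so the
  # partial correlation of x and y given z is exactly 0.5
  set.seed(11)
  n <- 2000
  z <- rnorm(n); u <- rnorm(n); v <- 0.5 * u + sqrt(0.75) * rnorm(n)
  res <- parcorr_test(z + u, z + v, z)
  expect_equal(res$statistic, 0.5, tolerance = 0.06)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$cond_dim, 1)
  # affine invariance of the statistic
  res2 <- parcorr_test(3 * (z + u) - 5, -2 * (z + v) + 1, 10 * z + 4)
  expect_equal(abs(res2$statistic), abs(res$statistic), tolerance = 1e-12)
  expect_error(parcorr_test(x, rnorm(50)), "equal length")
  expect_error(parcorr_test(x[1:4], x[1:4], matrix(rnorm(12), 4, 3)), "small")
  expect_error(parcorr_test(x, rnorm(100), cbind(x, 2 * x)), "singular")
})

test_that("partial-correlation null is calibrated on a common-driver design", {
  # x <- z -> y: conditioning on z makes x and y independent, so the
  # rejection rate at alpha should match alpha
  set.seed(12)
  n_rep <- 400
  p <- replicate(n_rep, {
    z <- rnorm(150)
    parcorr_test(0.8 * z + rnorm(150), 0.8 * z + rnorm(150), z)$p_value
  })
  rate <- mean(p <= 0.01)
  band <- qbinom(c(0.005, 0.995), n_rep, 0.01) / n_rep
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
  # without conditioning the dependence is detected essentially always
  set.seed(13)
  z <- rnorm(500)
  expect_lt(parcorr_test(0.8 * z + rnorm(500), 0.8 * z + rnorm(500))$p_value,
            1e-6)
})

test_that("k-NN mutual information matches the Gaussian closed form", {
  # average a few replicates: a single draw has estimator sd ~ 0.02
  set.seed(14)
  est <- mean(replicate(8, {
    g <- gaussian_pair(1000, 0.6)
    cmi_knn(g$x, g$y, k = 10)
  }))
  expect_lt(abs(est - (-0.5 * log(1 - 0.36))), 0.03)
  # independence: small (possibly negative), never clipped
  est0 <- cmi_knn(rnorm(1000), rnorm(1000), k = 10)
  expect_lt(abs(est0), 0.05)
  expect_error(cmi_knn(rnorm(10), rnorm(10), k = 10), "k")
})

test_that("conditioning removes common-driver information", {
  set.seed(15)
  n <- 800
  z <- rnorm(n)
  x <- 0.8 * z + 0.6 * rnorm(n)
  y <- 0.8 * z + 0.6 * rnorm(n)
  mi <- cmi_knn(x, y, k = 10)
  cmi <- cmi_knn(x, y, z, k = 10)
  expect_gt(mi, 0.15)        # marginal dependence is strong
  expect_lt(abs(cmi), 0.06)  # conditionally independent by construction
})

test_that("the estimator is invariant to monotone marginal transforms", {
  set.seed(16)
  g <- gaussian_pair(1000, 0.6)
  est <- cmi_knn(g$x, g$y, k = 10)
  # probability-integral transforms: strictly monotone, bounded marginals
  est_t <- cmi_knn(pnorm(g$x), pnorm(g$y), k = 10)
  expect_lt(abs(est_t - est), 0.05)
})

test_that("duplicate samples are handled by deterministic jitter", {
  set.seed(17)
  x <- round(rnorm(300), 1)   # heavy ties
  y <- round(0.8 * x + rnorm(300), 1)
  est1 <- cmi_knn(x, y, k = 5)
  est2 <- cmi_knn(x, y, k = 5)
  expect_identical(est1, est2)
  expect_true(is.finite(est1))
  expect_gt(est1, 0.1)
})

test_that("permutation test detects strong coupling and is seed-deterministic", {
  set.seed(18)
  g <- gaussian_pair(500, 0.8)
  cfg <- knn_config(k = 10, n_permutations = 100, seed = 5)
  res <- cmi_knn_test(g$x, g$y, config = cfg)
  expect_equal(res$p_value, 1 / 101)
  res2 <- cmi_knn_test(g$x, g$y, config = cfg)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$statistic, res2$statistic)
  # B below any useful resolution is flagged
  low <- cmi_knn_test(g$x, g$y, config = knn_config(k = 5, n_permutations = 10,
                                                    seed = 1))
  expect_true(isTRUE(attr(low, "low_resolution")))
})

test_that("permutation p-values are roughly uniform under independence", {
  set.seed(19)
  cfg <- knn_config(k = 5, n_permutations = 39, seed = 3)
  p <- replicate(40, cmi_knn_test(rnorm(120), rnorm(120), config = cfg)$p_value)
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
  expect_lte(mean(p <= 0.05), 0.2)
})

test_that("both tests agree on clear linear-Gaussian decisions", {
  set.seed(20)
  cfg <- knn_config(k = 8, n_permutations = 49, seed = 9)
  agree_dep <- agree_ind <- 0
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    g <- gaussian_pair(300, 0.5)
    dep_both <- parcorr_test(g$x, g$y)$p_value <= 0.02 &&
      cmi_knn_test(g$x, g$y, config = cfg)$p_value <= 0.02
    w <- list(x = rnorm(300), y = rnorm(300))
    ind_both <- parcorr_test(w$x, w$y)$p_value > 0.02 &&
      cmi_knn_test(w$x, w$y, config = cfg)$p_value > 0.02
    agree_dep <- agree_dep + dep_both
    agree_ind <- agree_ind + ind_both
  }
  expect_gte(agree_dep, n_rep - 1)
  expect_gte(agree_ind, n_rep - 2)
})
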