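test_that("constructor rejects invalid mixtures", {
  expect_error(tnmix(c(0.5, 0.6), c(0, 1), 1, c(-1, 1)), "sum to 1")
  expect_error(tnmix(1, 0, 0, c(-1, 1)), "strictly positive")
  expect_error(tnmix(1, 0, 1, c(1, 1)), "lo < hi")
  expect_error(tnmix(1, 100, 0.1, c(-1, 1)), "no mass")
})

test_that("cdf matches closed forms and is total on the reals", {
  m <- std_mix()
  # truncation at +/-30 sd is negligible: compare against pnorm
  x <- c(-3, -1, 0, 0.5, 2)
  expect_equal(ptnmix(x, m), pnorm(x), tolerance = 1e-10)
  expect_identical(ptnmix(-31, m), 0)
  expect_identical(ptnmix(31, m), 1)
  expect_identical(ptnmix(Inf, m), 1)
  expect_identical(ptnmix(m$support[2], m), 1)
  # symmetric two-component mixture: cdf(centre) = 0.5
  m2 <- tnmix(c(0.5, 0.5), c(-2, 2), c(1, 1), c(-10, 10))
  expect_equal(ptnmix(0, m2), 0.5, tolerance = 1e-12)
})

test_that("cdf agrees with numerical integration of the density", {
  m <- tnmix(c(0.3, 0.7), c(-2, 4), c(1.5, 3), c(-8, 12))
  for (x in c(-5, 0, 3, 9)) {
    num <- integrate(function(u) dtnmix(u, m), -8, x, rel.tol = 1e-10)$value
    expect_equal(ptnmix(x, m), num, tolerance = 1e-7)
  }
})

test_that("quantile inverts the cdf and handles flat mixtures", {
  m <- tnmix(c(0.4, 0.6), c(-1, 3), c(1, 2), c(-10, 12))
  for (p in c(0.01, 0.05, 0.5, 0.95, 0.99)) {
    expect_equal(ptnmix(qtnmix(p, m), m), p, tolerance = 1e-6)
  }
  # symmetric about 0 => median 0
  expect_equal(qtnmix(0.5, std_mix()), 0, tolerance = 1e-6)
  # near-uniform mixture on [0, 10]: quantile(0.25) ~ 2.5
  expect_equal(qtnmix(0.25, flat_mix(0, 10)), 2.5, tolerance = 1e-3)
  expect_error(qtnmix(0, m), "inside")
  expect_error(qtnmix(1.2, m), "inside")
})

test_that("moments match closed-form oracles", {
  # N(0,1) truncated to [-30, 30]: truncation negligible
  mo <- tnmix_moments(std_mix())
  expect_equal(mo$mean, 0, tolerance = 1e-9)
  expect_equal(mo$sd, 1, tolerance = 1e-9)
  # half-normal: N(0,1) truncated to [0, 30] has mean sqrt(2/pi)
  mo_half <- tnmix_moments(tnmix(1, 0, 1, c(0, 30)))
  expect_equal(mo_half$mean, sqrt(2 / pi), tolerance = 1e-9)
  expect_equal(mo_half$sd, sqrt(1 - 2 / pi), tolerance = 1e-9)
  # symmetric mixture: mean 0
  m2 <- tnmix(c(0.5, 0.5), c(-2, 2), c(1, 1), c(-20, 20))
  expect_equal(tnmix_moments(m2)$mean, 0, tolerance = 1e-12)
})

test_that("closed-form moments agree with quadrature and Monte Carlo", {
  m <- tnmix(c(0.6, 0.4), c(1, 7), c(2, 1.5), c(0, 12))
  closed <- tnmix_moments(m)
  quad <- tnmix_moments(m, method = "quadrature")
  expect_equal(closed$mean, quad$mean, tolerance = 1e-8)
  expect_equal(closed$sd, quad$sd, tolerance = 1e-8)
  n <- 1e6
  set.seed(123)
  x <- rtnmix(n, m)
  se_mean <- closed$sd / sqrt(n)
  expect_lt(abs(mean(x) - closed$mean), 3 * se_mean)
  expect_lt(abs(sd(x) - closed$sd), 3 * closed$sd / sqrt(2 * n))
})

test_that("interval masses and renormalisation conserve probability", {
  m <- tnmix(c(0.5, 0.5), c(-3, 5), c(2, 4), c(-10, 10))
  mo <- tnmix_moments(m, intervals = list(c(-10, 10), c(-2, 2)))
  expect_equal(mo$interval_mass[1], 1, tolerance = 1e-9)
  total <- integrate(function(u) dtnmix(u, m), -10, 10, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("every cdf is non-decreasing on a dense support grid", {
  mixes <- list(std_mix(), flat_mix(),
                tnmix(c(0.2, 0.8), c(-5, 2), c(0.5, 6), c(-15, 15)),
                tnmix(c(0.9, 0.1), c(5, 14), c(2, 0.7), c(0, 16)))
  for (m in mixes) {
    g <- seq(m$support[1], m$support[2], length.out = 1e4)
    expect_true(all(diff(ptnmix(g, m)) >= -1e-12))
  }
})

test_that("sampling is exact: draws stay inside the support", {
  m <- tnmix(c(0.5, 0.5), c(-1, 18), c(4, 3), c(0, 16))
  set.seed(9)
  x <- rtnmix(5e4, m)
  expect_true(all(x >= 0 & x <= 16))
})
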