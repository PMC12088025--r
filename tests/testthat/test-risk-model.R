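test_that("the risk equation honours its boundary identities", {
  m <- preset_model()
  # t = 0: the latent phase cannot already be over, so P(SBA) = 1
  expect_identical(p_sba(m, "nulliparous", 0, -7)$p_sba, 1)
  expect_identical(p_sba(m, "multiparous", 0, no_mwh())$p_sba, 1)
  # no MWH stay: F drops out entirely
  est <- p_sba(m, "multiparous", 6, no_mwh())
  expect_identical(est$f_of_d, 1)
  expect_equal(est$p_sba, 1 - est$gk_of_t, tolerance = 1e-15)
  # t at the top of G's support with no MWH: G = 1, so P(SBA) = 0
  hi <- m$G$multiparous$mix$support[2]
  expect_equal(p_sba(m, "multiparous", hi, no_mwh())$p_sba, 0)
  # product identity holds to machine precision
  est2 <- p_sba(m, "nulliparous", 7.5, -14)
  expect_equal(est2$p_sba, 1 - est2$gk_of_t * est2$f_of_d, tolerance = 1e-12)
})

test_that("p_sba matches an independent truncated-normal oracle", {
  # single-component inputs evaluated via pnorm directly, not via the
  # package's mixture code path
  fmix <- tnmix(1, -2, 8, c(-30, 30))
  gmix <- tnmix(1, 5, 3, c(0, 16))
  model <- sba_model(
    onset = surrogate_dist(fmix, "onset"),
    latent_nulliparous = surrogate_dist(tnmix(1, 7, 3, c(0, 30)), "latent",
                                        parity = "nulliparous"),
    latent_multiparous = surrogate_dist(gmix, "latent",
                                        parity = "multiparous"))
  tn_cdf <- function(x, mu, s, lo, hi)
    (pnorm(x, mu, s) - pnorm(lo, mu, s)) /
    (pnorm(hi, mu, s) - pnorm(lo, mu, s))
  t <- 6.5; d <- -10
  expected <- 1 - tn_cdf(t, 5, 3, 0, 16) * tn_cdf(d, -2, 8, -30, 30)
  expect_equal(p_sba(model, "multiparous", t, d)$p_sba, expected,
               tolerance = 1e-12)
})

test_that("scenarios are validated", {
  m <- preset_model()
  expect_error(p_sba(m, "multiparous", -1, 0), "non-negative")
  expect_error(p_sba(m, "multiparous", 5, 3), "at most 0")
  expect_error(p_sba(m, "neither", 5, 0), "arg")
  # parity mismatch between slot and distribution is caught at fit time
  wrong <- preset_model()$G$multiparous
  expect_error(sba_model(latent_nulliparous = wrong), "parity mismatch")
  expect_error(sba_model(latent_nulliparous = "friedman_multiparous"),
               "multiparous women")
})

test_that("risk categories use the half-open colour bands", {
  expect_identical(as.character(risk_category(c(0.89, 0.90, 0.949, 0.95, 1))),
                   c("salmon", "light_green", "light_green", "dark_green",
                     "dark_green"))
  expect_error(risk_category(1.2), "probability")
  expect_error(risk_category(-0.1), "probability")
})

test_that("P(SBA) is monotone in access time and move date", {
  m <- preset_model()
  ts <- c(0, 0.5, 1, 2, 4, 6, 8, 10, 12, 14)
  ds <- c(no_mwh(), 0, -7, -14, -21, -28)
  for (k in c("nulliparous", "multiparous")) {
    for (d in ds) {
      p <- vapply(ts, function(t) p_sba(m, k, t, d)$p_sba, numeric(1))
      expect_true(all(diff(p) <= 1e-12))  # longer access time, lower P
    }
    for (t in ts) {
      p <- vapply(ds, function(d) p_sba(m, k, t, d)$p_sba, numeric(1))
      expect_true(all(diff(p) >= -1e-12))  # earlier move, higher P
    }
  }
})

test_that("multiparous risk exceeds nulliparous risk without an MWH", {
  # holds over the body of the latent distributions; above ~9 h the
  # calibrated surrogates cross because the printed 95th percentiles force
  # the nulliparous mixture to defer 5% of its mass beyond 20 h
  m <- preset_model()
  for (t in seq(1, 9, by = 0.5)) {
    expect_lte(p_sba(m, "multiparous", t, no_mwh())$p_sba,
               p_sba(m, "nulliparous", t, no_mwh())$p_sba + 1e-12)
  }
})

test_that("the worked example recommends moving 2 weeks before the EDD", {
  m <- preset_model()
  rec <- recommend_move_date(m, "multiparous", parse_access_time("10h15"),
                             threshold = 0.90)
  expect_identical(rec$move_date, -14)
  expect_true(rec$met)
  expect_gte(rec$p_sba, 0.90)
})

test_that("recommendation picks the least burdensome adequate candidate", {
  m <- preset_model()
  # a very short access time is already safe without any MWH stay
  rec <- recommend_move_date(m, "nulliparous", 0.25, threshold = 0.90)
  expect_identical(rec$move_date, no_mwh())
  expect_true(rec$met)
  # an unmeetable threshold returns the best candidate, flagged
  rec2 <- recommend_move_date(m, "multiparous", 10, threshold = 0.9999)
  expect_identical(rec2$move_date, -28)
  expect_false(rec2$met)
  expect_identical(rec2$p_sba, max(rec2$candidates$p_sba))
  # adding candidates dominated by the chosen one changes nothing
  rec3 <- recommend_move_date(m, "multiparous", 10.25, threshold = 0.90,
                              candidates = c(no_mwh(), 0, -7, -14))
  rec4 <- recommend_move_date(m, "multiparous", 10.25, threshold = 0.90,
                              candidates = c(no_mwh(), 0, -7, -14, -21, -28))
  expect_identical(rec3$move_date, rec4$move_date)
  expect_identical(rec3$p_sba, rec4$p_sba)
  expect_error(recommend_move_date(m, "multiparous", 10,
                                   candidates = numeric(0)), "non-empty")
})

test_that("predict vectorises the risk equation over scenario rows", {
  m <- preset_model()
  nd <- data.frame(parity = c("nulliparous", "multiparous", "multiparous"),
                   access_time = c(2, 10.5, 0),
                   move_date = c(no_mwh(), -14, -28))
  out <- predict(m, nd)
  expect_identical(nrow(out), 3L)
  for (i in 1:3) {
    expect_equal(out$p_sba[i],
                 p_sba(m, nd$parity[i], nd$access_time[i],
                       nd$move_date[i])$p_sba)
  }
  expect_true(all(out$p_sba >= 0 & out$p_sba <= 1))
  # move_date defaults to no MWH stay
  out2 <- predict(m, data.frame(parity = "multiparous", access_time = 5))
  expect_identical(out2$f_of_d, 1)
})

test_that("random scenarios keep P(SBA) inside [0, 1]", {
  m <- preset_model()
  set.seed(31)
  nd <- data.frame(
    parity = sample(c("nulliparous", "multiparous"), 200, replace = TRUE),
    access_time = runif(200, 0, 40),
    move_date = sample(c(no_mwh(), 0, -runif(50, 0, 60)), 200, replace = TRUE))
  out <- predict(m, nd)
  expect_true(all(out$p_sba >= 0 & out$p_sba <= 1))
})

test_that("simulate draws independent, reproducible labour timings", {
  m <- preset_model()
  s1 <- simulate(m, nsim = 200, seed = 5)
  s2 <- simulate(m, nsim = 200, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$onset_offset >= -30 & s1$onset_offset <= 30))
  expect_true(all(s1$latent_hours >= 0))
  expect_setequal(unique(s1$parity), c("nulliparous", "multiparous"))
})

test_that("model print and summary expose the fitted inputs", {
  m <- preset_model()
  expect_output(print(m), "P\\(SBA\\) = 1 - Gk\\(t\\) F\\(d\\)")
  s <- summary(m)
  expect_equal(s$inputs$mean, c(-1.48, 7.1, 5.3), tolerance = 1e-2)
  expect_output(print(s), "latent phase G, multiparous")
})
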