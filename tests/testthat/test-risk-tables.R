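test_that("the default interval grid matches the device layout", {
  g <- default_interval_grid()
  expect_identical(nrow(g), 22L)
  expect_identical(g$upper[1], 1)
  expect_identical(c(g$lower[4], g$upper[4]), c(3, 3.5))
  expect_identical(g$label[4], "3-3.5")
  expect_identical(g$upper[22], 12.5)
  expect_true(all(g$lower < g$upper))
  expect_true(all(g$lower[-1] == g$upper[-22]))  # contiguous rows
})

test_that("cells use the conservative upper-bound convention", {
  m <- preset_model()
  cell <- cell_value(m, c(10, 10.5), "multiparous", no_mwh())
  at_upper <- p_sba(m, "multiparous", 10.5, no_mwh())
  at_lower <- p_sba(m, "multiparous", 10, no_mwh())
  expect_identical(cell$p_sba, at_upper$p_sba)
  expect_lte(cell$p_sba, at_lower$p_sba)
  expect_identical(cell_value(m, c(0, 1), "nulliparous")$access_time, 1)
  expect_error(cell_value(m, c(5, 4), "multiparous"), "lower < upper")
})

test_that("a full table fills every cell and is doubly monotone", {
  m <- preset_model()
  for (k in c("nulliparous", "multiparous")) {
    tab <- build_risk_table(m, k)
    expect_identical(nrow(tab), 132L)  # 22 intervals x 6 scenarios
    pm <- matrix(tab$p_sba, nrow = 22)
    # rows: later columns = earlier moves = safer
    expect_true(all(apply(pm, 1, function(r) all(diff(r) >= -1e-12))))
    # columns: longer access times = riskier
    expect_true(all(apply(pm, 2, function(c) all(diff(c) <= 1e-12))))
    # conservative convention: every cell <= the value at its lower bound
    lower_p <- predict(m, data.frame(parity = k, access_time = tab$lower,
                                     move_date = tab$move_date))$p_sba
    expect_true(all(tab$p_sba <= lower_p + 1e-12))
  }
})

test_that("moving 4 weeks early is uniformly safe; parity orders the risk", {
  m <- preset_model()
  tn <- build_risk_table(m, "nulliparous")
  tm <- build_risk_table(m, "multiparous")
  expect_true(all(tn$p_sba[tn$scenario == "minus_28"] >= 0.95))
  expect_true(all(tm$p_sba[tm$scenario == "minus_28"] >= 0.95))
  # parity ordering over the body of the latent distributions (the
  # calibrated surrogates cross above ~9 h; see the methods vignette)
  body <- tn$upper <= 9
  expect_true(all(tn$p_sba[tn$scenario == "no_mwh" & body] >=
                  tm$p_sba[tm$scenario == "no_mwh" & body]))
})

test_that("tables round-trip exactly through CSV and JSON", {
  m <- preset_model()
  tab <- build_risk_table(m, "multiparous")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_risk_table(tab, csv)
  back <- read_risk_table(csv)
  expect_identical(back$p_sba, tab$p_sba)
  expect_identical(back$scenario, tab$scenario)
  expect_identical(as.character(back$category), as.character(tab$category))
  expect_identical(attr(back, "parity"), "multiparous")
  header <- strsplit(readLines(csv, n = 1), ",")[[1]]
  expect_identical(header[1], "access_time")
  expect_true(all(c("no_mwh", "on_edd", "minus_7", "minus_14", "minus_21",
                    "minus_28") %in% header))
  json <- withr::local_tempfile(fileext = ".json")
  export_risk_table(tab, json)
  back2 <- read_risk_table(json)
  expect_identical(back2$p_sba, tab$p_sba)
  # wheel view: six concentric rings keyed by interval label
  obj <- jsonlite::read_json(json)
  expect_identical(length(obj$rings), 6L)
  expect_identical(names(obj$rings[[1]]), default_interval_grid()$label)
  expect_error(export_risk_table(tab, "table.xlsx"), "format")
})

test_that("CI columns survive the export round-trip", {
  set.seed(77)
  model <- sba_model(onset = sample_cohort("khambalia", 400, seed = 1),
                     latent_nulliparous = sample_cohort("friedman_nulliparous",
                                                        200, seed = 2),
                     latent_multiparous = sample_cohort("friedman_multiparous",
                                                        200, seed = 3))
  cfg <- bootstrap_config(max_iterations = 150, convergence_window = 50,
                          seed = 9)
  tab <- build_risk_table(model, "multiparous", ci = cfg)
  expect_true(all(tab$ci_low <= tab$p_sba + 0.03))
  expect_true(all(tab$ci_low >= 0 & tab$ci_high <= 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_risk_table(tab, csv)
  back <- read_risk_table(csv)
  expect_identical(back$ci_low, tab$ci_low)
  expect_identical(back$ci_high, tab$ci_high)
})

test_that("CIs are refused for surrogate-backed models", {
  expect_error(build_risk_table(preset_model(), "multiparous",
                                ci = bootstrap_config(seed = 1)),
               "resample")
  expect_error(build_risk_table(preset_model(), "multiparous", ci = TRUE),
               "bootstrap_config")
})
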