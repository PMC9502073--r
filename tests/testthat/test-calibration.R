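test_that("two points determine the exact line", {
  fit <- fit_linear_pka(c(270, 284), c(10, 20), "N", "demo")
  expect_equal(fit$a, 10 / 14, tolerance = 1e-9)
  expect_equal(fit$b, 10 - 270 * 10 / 14, tolerance = 1e-9)  # -182.857
  expect_equal(fit$r2, 1)
})

test_that("noiseless sets are recovered exactly and errors vanish", {
  dg <- c(250, 262, 271, 280, 295)
  fit <- fit_linear_pka(dg, 0.601 * dg - 146.8, "N", "noiseless")
  expect_equal(fit$a, 0.601, tolerance = 1e-9)
  expect_equal(fit$b, -146.8, tolerance = 1e-7 / 146.8)
  expect_equal(fit$mue, 0, tolerance = 1e-10)
  expect_equal(fit$rms, 0, tolerance = 1e-10)
})

test_that("calibration OLS matches the closed-form oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    dg <- stats::runif(n, 240, 320)
    pka <- 0.65 * dg - 160 + stats::rnorm(n, 0, 1.5)
    fit <- fit_linear_pka(dg, pka)
    orc <- ols_oracle(dg, pka)
    expect_equal(fit$a, orc$a, tolerance = 1e-9)
    expect_equal(fit$b, orc$b, tolerance = 1e-9)
    expect_equal(fit$r2, orc$r2, tolerance = 1e-9)
    # OLS residuals are centred
    expect_lt(abs(mean(fit$residuals)), 1e-9)
    expect_gte(fit$rms, fit$mue)
  }
})

test_that("shifting the abscissae moves only the intercept", {
  set.seed(5)
  dg <- stats::runif(8, 250, 300)
  pka <- 0.62 * dg - 150 + stats::rnorm(8, 0, 1)
  f0 <- fit_linear_pka(dg, pka)
  c_shift <- 37.5
  f1 <- fit_linear_pka(dg + c_shift, pka)
  expect_equal(f1$a, f0$a, tolerance = 1e-9)
  expect_equal(f1$b, f0$b - f0$a * c_shift, tolerance = 1e-9)
  expect_equal(f1$r2, f0$r2, tolerance = 1e-9)
  expect_equal(f1$mue, f0$mue, tolerance = 1e-9)
  expect_equal(f1$rms, f0$rms, tolerance = 1e-9)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_linear_pka(270, 10), "at least 2")
  expect_error(fit_linear_pka(c(270, 270, 270), c(10, 11, 12)),
               "zero variance")
  expect_error(fit_linear_pka(c(270, 280), c(10, 20, 30)), "same length")
})

test_that("prediction follows the calibration line", {
  fitN <- preset_equation("N")
  expect_equal(predict_pka(fitN, 146.8 / 0.601), 0, tolerance = 0.01)
  fitC <- preset_equation("C")
  expect_equal(predict_pka(fitC, 290), 26.15, tolerance = 0.01 / 26.15)
  p0 <- predict_pka(fitC, 290)
  expect_equal(predict_pka(fitC, 290 + 1 / fitC$a), p0 + 1, tolerance = 1e-12)
})

test_that("fit statistics summarise residual sets correctly", {
  s <- fit_statistics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(s$mue, 0); expect_equal(s$rms, 0)
  expect_equal(s$max_abs_dev, 0)
  s <- fit_statistics(c(11, 19, 21, 29), c(10, 20, 20, 30))
  expect_equal(s$mue, 1); expect_equal(s$rms, 1)
  s <- fit_statistics(c(13, 10, 10, 10), c(10, 10, 10, 10),
                      ids = c("b37", "b1", "b2", "b3"))
  expect_equal(s$mue, 0.75)
  expect_equal(s$rms, 1.5)
  expect_equal(s$max_abs_dev, 3)
  expect_equal(s$max_id, "b37")
  expect_error(fit_statistics(numeric(0), numeric(0)), "at least one")
})

test_that("rms equals mue only when all residual magnitudes are equal", {
  set.seed(33)
  for (i in 1:10) {
    res <- stats::rnorm(6)
    s <- fit_statistics(res, rep(0, 6))
    expect_gte(s$rms + 1e-12, s$mue)
    if (stats::var(abs(res)) > 1e-12) expect_gt(s$rms, s$mue)
  }
  s_eq <- fit_statistics(c(2, -2, 2, -2), rep(0, 4))
  expect_equal(s_eq$rms, s_eq$mue)
})

test_that("shipped presets carry the recommended coefficients", {
  expect_equal(preset_equation("N")$a, 0.601)
  expect_equal(preset_equation("N")$b, -146.8)
  expect_equal(preset_equation("P")$a, 0.636)
  expect_equal(preset_equation("P")$b, -158.5)
  expect_equal(preset_equation("C")$a, 0.705)
  expect_equal(preset_equation("C")$b, -178.3)
  expect_true(preset_equation("P")$preset)
  expect_error(preset_equation("S"), "presets exist")
})

test_that("explicit exclusion removes points; flagging never does", {
  dg <- c(250, 260, 270, 280, 290, 300)
  pka <- 0.64 * dg - 157
  pka[3] <- pka[3] + 8   # gross outlier
  ids <- paste0("b", 1:6)
  fit <- fit_linear_pka(dg, pka, ids = ids)
  expect_equal(fit$n_points, 6)
  expect_true("b3" %in% fit$flagged)
  fit2 <- fit_linear_pka(dg, pka, ids = ids, exclude = "b3")
  expect_equal(fit2$n_points, 5)
  expect_equal(fit2$a, 0.64, tolerance = 1e-9)
})

test_that("energy tables are calibrated per model x class group", {
  cfg <- synthetic_config(noise_sd = 0, seed = 3,
                          scales = c(0.85, 0.95))
  fam <- generate_method_family(cfg)
  fits <- calibrate_energy_table(fam$table)
  expect_length(fits, 2 * 3)   # 2 methods x 3 classes
  expect_setequal(
    vapply(fits, function(f) paste(f$model, f$base_class), ""),
    c(t(outer(c("SIM1", "SIM2"), c("N", "P", "C"), paste))))
  # zero-noise groups lie exactly on a line
  for (f in fits) expect_equal(f$r2, 1, tolerance = 1e-9)
})
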