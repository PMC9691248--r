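test_that("4PL fit recovers exact standards and validates degenerate input", {
  conc <- c(0, 5, 10, 25, 50, 100)
  aa <- fourpl_absorbance(conc, 1.0, 0.1, 25, 1.2)
  cv <- fit_calibration(data.frame(concentration = conc, absorbance = aa))
  expect_true(cv$converged)
  expect_lt(abs(cv$a_top - 1.0), 1e-6)
  expect_lt(abs(cv$a_bottom - 0.1), 1e-6)
  expect_lt(abs(cv$ic50 - 25) / 25, 1e-6)
  expect_lt(abs(cv$h - 1.2) / 1.2, 1e-6)

  expect_error(
    fit_calibration(data.frame(concentration = conc, absorbance = rep(0.5, 6))),
    "constant", class = "ilx_validation_error")
  expect_error(
    fit_calibration(data.frame(concentration = conc, absorbance = rev(aa))),
    "increases", class = "ilx_validation_error")
  expect_error(
    fit_calibration(data.frame(concentration = conc[1:3], absorbance = aa[1:3])),
    class = "ilx_validation_error")
})

test_that("invert_calibration is the analytic inverse on the open range", {
  cv <- calibration_curve(1.0, 0.1, 25, 1.3)
  expect_equal(invert_calibration(cv, fourpl_absorbance(25, 1.0, 0.1, 25, 1.3)),
               25, tolerance = 1e-10)
  # A near the top plateau maps to a concentration near 0
  expect_lt(invert_calibration(cv, 1.0 - 1e-9), 1e-5)
  set.seed(3)
  cc <- runif(1000, 1, 100)
  back <- invert_calibration(cv, fourpl_absorbance(cc, 1.0, 0.1, 25, 1.3))
  expect_lt(max(abs(back - cc) / cc), 1e-9)
  expect_error(invert_calibration(cv, 1.0), "top plateau",
               class = "ilx_validation_error")
  expect_error(invert_calibration(cv, 0.05), "bottom plateau",
               class = "ilx_validation_error")
})

test_that("4PL fit recovers IC50 from noisy duplicate-standard plates", {
  cfg <- default_cfg()
  est <- vapply(1:40, function(i) {
    plate <- make_plate(cfg, seed = 300 + i)
    quantify_plate(plate)$curve$ic50
  }, numeric(1))
  expect_lt(abs(median(est) - cfg$elisa$ic50) / cfg$elisa$ic50, 0.10)
})

test_that("replicate_stats computes mean, sample SD, CV% and signed RE%", {
  r <- replicate_stats(replicate_set(c(21.904, 19.950, 22.971), nominal = 20))
  expect_equal(round_half_up(r$mean, 3), 21.608)
  expect_equal(round_half_up(r$sd, 3), 1.532)
  expect_equal(round_half_up(r$cv_percent, 3), 7.090)
  expect_equal(round_half_up(r$relative_error_percent, 2), 8.04)

  r2 <- replicate_stats(replicate_set(c(20.515, 20.145, 19.287), nominal = 20))
  expect_equal(round_half_up(r2$mean, 3), 19.982)
  expect_equal(round_half_up(r2$sd, 3), 0.630)
  expect_equal(round_half_up(r2$cv_percent, 3), 3.153)
  expect_equal(round_half_up(r2$relative_error_percent, 2), -0.09)

  r3 <- replicate_stats(replicate_set(c(5, 5, 5), nominal = 5))
  expect_equal(r3$sd, 0)
  expect_equal(r3$cv_percent, 0)
  expect_equal(r3$relative_error_percent, 0)

  expect_error(replicate_set(7, nominal = 5), class = "ilx_validation_error")
})

test_that("CV% is scale invariant", {
  x <- c(18.2, 21.7, 20.4, 19.9)
  base_cv <- replicate_stats(replicate_set(x, nominal = 20))$cv_percent
  for (alpha in c(0.2, 3, 17)) {
    cv <- replicate_stats(replicate_set(alpha * x,
                                        nominal = alpha * 20))$cv_percent
    expect_equal(cv, base_cv, tolerance = 1e-12)
  }
})

test_that("accuracy_comparison reports signed improvements", {
  mk <- function(re, cv = 5) {
    # build a replicate set with the requested relative error
    mean_target <- 20 * (1 + re / 100)
    spread <- mean_target * cv / 100
    structure(list(mean = mean_target, sd = spread, cv_percent = cv,
                   relative_error_percent = re, n = 3, nominal = 20,
                   condition = ""),
              class = "ilx_accuracy_report")
  }
  cmp <- accuracy_comparison(mk(32.18), mk(-0.09, cv = 3))
  expect_equal(cmp$decrease_points, 32.27)
  expect_true(cmp$cv_improved)
  cmp2 <- accuracy_comparison(mk(16.23), mk(10.66))
  expect_equal(cmp2$decrease_points, 5.57)
  cmp3 <- accuracy_comparison(mk(12.5), mk(12.5))
  expect_equal(cmp3$decrease_points, 0)
  bad <- mk(5); bad$nominal <- 10
  expect_error(accuracy_comparison(mk(5), bad), class = "ilx_validation_error")
})

test_that("plate reader validates roles and quantify_plate back-calculates", {
  cfg <- default_cfg()
  plate <- make_plate(cfg, nominal = 20, hb_level = 0, noise_cv = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(plate, path, row.names = FALSE, quote = FALSE)
  plate2 <- read_plate(path)
  qp <- quantify_plate(plate2)
  expect_equal(qp$reports[["20"]]$mean, 20, tolerance = 1e-6)

  plate_bad <- plate
  plate_bad$role[3] <- "mystery"
  write.csv(plate_bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_plate(path), "invalid role", class = "ilx_parse_error")
})
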