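test_that("closed form satisfies the boundary condition and limiting cases", {
  sys <- default_system()
  m <- kinetic_model(0.5, 0.2, sys)
  expect_equal(caq_closed_form(m, 0), sys$q / sys$v_aq)
  # k2 = 0: pure first-order decay
  m0 <- kinetic_model(0.7, 0, sys)
  tt <- c(0, 1, 3, 10)
  expect_equal(caq_closed_form(m0, tt), sys$q / sys$v_aq * exp(-0.7 * tt))
  # degenerate model
  expect_error(caq_closed_form(kinetic_model(0, 0, sys), 1),
               class = "ilx_validation_error")
})

test_that("closed form agrees with numerical integration of the rate equation", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  for (i in 1:25) {
    k1 <- runif(1, 0.05, 2)
    k2 <- runif(1, 0.005, 1)
    v_aq <- runif(1, 1, 5)
    v_il <- runif(1, 0.2, 2)
    q <- runif(1, 0.05, 1)
    sys <- extraction_system(v_aq = v_aq, q = q, v_il = v_il)
    m <- kinetic_model(k1, k2, sys)
    times <- c(0, 0.5, 2, 5, 20)
    ode <- deSolve::ode(
      y = c(C = q / v_aq), times = times,
      func = function(t, y, p) list(-k1 * y + k2 * (q - y * v_aq) / v_il),
      parms = NULL, rtol = 1e-12, atol = 1e-14)
    cf <- caq_closed_form(m, times)
    expect_lt(max(abs(cf - ode[, "C"]) / pmax(abs(ode[, "C"]), 1e-12)), 1e-8)
    # mass balance: C_aq V_aq + C_IL V_IL = q at every time
    c_il <- c_il_from_balance(sys, cf)
    expect_lt(max(abs(cf * v_aq + c_il * v_il - q)) / q, 1e-10)
    # monotone between C0 and Cinf
    expect_true(all(diff(cf) <= 1e-14) || all(diff(cf) >= -1e-14))
  }
})

test_that("the t -> infinity state is the linear partition regime S = k1/k2", {
  sys <- default_system()
  m <- kinetic_model(0.8, 0.3, sys)
  caq_inf <- caq_closed_form(m, 1e6)
  cil_inf <- c_il_from_balance(sys, caq_inf)
  expect_equal(cil_inf / caq_inf, 0.8 / 0.3, tolerance = 1e-9)
  expect_equal(kinetic_separation_ratio(m), 0.8 / 0.3)
  # the matching linear partition model reproduces the same equilibrium
  pm <- partition_model("linear", s0 = kinetic_separation_ratio(m))
  pred <- predict_depletion(pm, sys)
  expect_equal(pred$c_aq_eq, caq_inf, tolerance = 1e-9)
})

test_that("simulated traces are deterministic, mean-unbiased and exact at zero noise", {
  sys <- default_system()
  m <- kinetic_model(0.8, 0.3, sys)
  times <- c(0, 0.5, 1, 2, 4, 10)
  tr0 <- simulate_trace(m, times, noise_sd = 0)
  expect_equal(tr0$c_aq, caq_closed_form(m, times))
  a <- simulate_trace(m, times, noise_sd = 0.01, seed = 7)
  b <- simulate_trace(m, times, noise_sd = 0.01, seed = 7)
  expect_identical(a$c_aq, b$c_aq)
  expect_error(simulate_trace(m, numeric(0)), class = "ilx_validation_error")
  # Monte-Carlo mean at a single time within 3 standard errors
  n <- 1000
  tr <- simulate_trace(m, rep(5, n), noise_sd = 0.01, seed = 21)
  truth <- caq_closed_form(m, 5)
  expect_lt(abs(mean(tr$c_aq) - truth), 3 * 0.01 / sqrt(n))
})

test_that("fit_kinetics recovers exact parameters from noiseless data", {
  sys <- default_system()
  m <- kinetic_model(0.8, 0.3, sys)
  tr <- simulate_trace(m, c(0, 0.25, 0.5, 1, 2, 4, 10, 20), noise_sd = 0)
  fit <- fit_kinetics(tr, sys)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$k1 - 0.8) / 0.8, 1e-6)
  expect_lt(abs(fit$model$k2 - 0.3) / 0.3, 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fit_kinetics flags degenerate and insufficient input", {
  sys <- default_system()
  expect_error(fit_kinetics(kinetic_trace(c(0, 5), c(0.125, 0.1)), sys),
               class = "ilx_validation_error")
  # constant trace: no decay, k1 ~ 0 with uninformative (large) standard error
  tr <- kinetic_trace(seq(0, 20, 2.5), rep(sys$q / sys$v_aq, 9))
  fit <- fit_kinetics(tr, sys)
  expect_lt(fit$model$k1, 1e-4)
  expect_true(is.infinite(fit$se["k1"]) || fit$se["k1"] > 100 * max(fit$model$k1, 1e-8))
})

test_that("equilibration time has the closed form and scaling law", {
  sys <- default_system()
  m <- kinetic_model(0.8, 0.3, sys)
  a <- 0.8 + 0.3 * sys$v_aq / sys$v_il
  expect_equal(equilibration_time(m, 1 - exp(-1)), 1 / a)
  m2 <- kinetic_model(1.6, 0.6, sys) # a doubled
  expect_equal(equilibration_time(m2, 0.99),
               equilibration_time(m, 0.99) / 2)
  expect_error(equilibration_time(m, 1), class = "ilx_validation_error")
  # definition check: at t*, the remaining departure is (1-fraction) of initial
  t95 <- equilibration_time(m, 0.95)
  cinf <- caq_closed_form(m, 1e9)
  c0 <- sys$q / sys$v_aq
  expect_equal(abs(caq_closed_form(m, t95) - cinf), 0.05 * abs(c0 - cinf),
               tolerance = 1e-9)
})

test_that("scenario kinetics plateau by 5 minutes", {
  cfg <- default_cfg()
  tr <- make_kinetic_trace(cfg, noise_sd = 0)
  fit <- fit_kinetics(tr, cfg$system)
  expect_lte(equilibration_time(fit$model, 0.95), 5)
})

test_that("trace CSV I/O round-trips and reports malformed lines", {
  tr <- kinetic_trace(c(0, 1, 5), c(0.125, 0.1, 0.08))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinetic_trace(tr, path)
  tr2 <- read_kinetic_trace(path)
  expect_identical(tr2$times, tr$times)
  expect_identical(tr2$c_aq, tr$c_aq)
  writeLines(c("time_min,c_aq_mg_per_ml", "0,0.125", "x,0.1"), path)
  expect_error(read_kinetic_trace(path), "line 3", class = "ilx_parse_error")
})
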