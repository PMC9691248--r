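#' Biphasic extraction system
#'
#' Geometry and composition of one liquid-liquid extraction experiment: an
#' aqueous (serum) phase of volume `v_aq`, an ionic-liquid phase of volume
#' `v_il`, and a total solute amount `q` distributed between them. Because
#' ionic-liquid amounts are usually weighed, `v_il` may be given as a mass
#' via `il_mass`, converted with the ionic-liquid `density`
#' (default 1.12 g/mL, the density of the hydrophobic imidazolium ionic
#' liquid used for heme depletion).
#'
#' @param v_aq Aqueous-phase volume in mL (> 0).
#' @param q Total solute amount in mg (>= 0).
#' @param v_il Ionic-liquid volume in mL (> 0); computed from `il_mass` if
#'   omitted.
#' @param il_mass Ionic-liquid mass in g (optional).
#' @param density Ionic-liquid density in g/mL (default 1.12).
#' @return An object of class `ilx_system`.
#' @examples
#' extraction_system(v_aq = 3, q = 0.375, il_mass = 0.7)
#' @export
extraction_system <- function(v_aq, q, v_il = NULL, il_mass = NULL,
                              density = 1.12) {
  .check_number(v_aq, "v_aq", lower = 0, strict_lower = TRUE)
  .check_number(q, "q", lower = 0)
  .check_number(density, "density", lower = 0, strict_lower = TRUE)
  if (is.null(v_il)) {
    if (is.null(il_mass)) .stop_validation("supply v_il or il_mass")
    .check_number(il_mass, "il_mass", lower = 0, strict_lower = TRUE)
    v_il <- il_mass / density
  }
  .check_number(v_il, "v_il", lower = 0, strict_lower = TRUE)
  structure(list(v_aq = v_aq, v_il = v_il, q = q,
                 il_mass = il_mass, density = density),
            class = "ilx_system")
}

#' Reversible first-order kinetic model of biphasic extraction
#'
#' The aqueous-phase solute concentration obeys
#' \deqn{dC_{aq}/dt = -k_1 C_{aq} + k_2 (q - C_{aq} V_{aq}) / V_{IL},}
#' i.e. first-order efflux from each phase proportional to the concentration
#' in that phase, with `(q - C_aq V_aq)/V_IL` the ionic-liquid-phase
#' concentration by mass balance. Rate constants are in 1/min, matching
#' shaking-time axes in minutes.
#'
#' @param k1 Forward (aqueous to ionic liquid) rate constant, 1/min (>= 0).
#' @param k2 Reverse rate constant, 1/min (>= 0).
#' @param system An [extraction_system()].
#' @return An object of class `ilx_kinetic_model`.
#' @export
kinetic_model <- function(k1, k2, system) {
  .check_number(k1, "k1", lower = 0)
  .check_number(k2, "k2", lower = 0)
  stopifnot(inherits(system, "ilx_system"))
  structure(list(k1 = k1, k2 = k2, system = system),
            class = "ilx_kinetic_model")
}

# Relaxation rate a = k1 + k2 Vaq/VIL and the two fixed concentrations of the
# closed-form solution C(t) = Cinf + (C0 - Cinf) exp(-a t).
.kinetic_constants <- function(model) {
  sys <- model$system
  a <- model$k1 + model$k2 * sys$v_aq / sys$v_il
  c0 <- sys$q / sys$v_aq
  cinf <- if (a > 0) (model$k2 * sys$q / sys$v_il) / a else NA_real_
  list(a = a, c0 = c0, cinf = cinf)
}

#' Closed-form aqueous-phase concentration
#'
#' Solution of the reversible first-order model with boundary condition
#' `C_aq(0) = q / V_aq` (all solute initially in the aqueous phase):
#' \deqn{C_{aq}(t) = C_\infty + (C_0 - C_\infty) e^{-a t}}
#' with `a = k1 + k2 Vaq/VIL`, `C0 = q/Vaq` and
#' `Cinf = (k2 q / VIL) / a`. Monotone from `C0` toward `Cinf`.
#'
#' @param model An [kinetic_model()].
#' @param t Time(s) in min (>= 0). Vectorized.
#' @return Aqueous concentration(s) in mg/mL.
#' @export
caq_closed_form <- function(model, t) {
  stopifnot(inherits(model, "ilx_kinetic_model"))
  .check_number(t, "t", lower = 0)
  kc <- .kinetic_constants(model)
  if (kc$a <= 0) {
    .stop_validation("degenerate kinetic model: k1 + k2*Vaq/VIL must be > 0")
  }
  kc$cinf + (kc$c0 - kc$cinf) * exp(-kc$a * t)
}

#' Ionic-liquid-phase concentration by mass balance
#'
#' `C_IL = (q - C_aq * V_aq) / V_IL`, so that
#' `C_aq V_aq + C_IL V_IL = q` holds exactly.
#'
#' @param system An [extraction_system()].
#' @param c_aq Aqueous concentration(s) in mg/mL.
#' @return Ionic-liquid concentration(s) in mg/mL.
#' @export
c_il_from_balance <- function(system, c_aq) {
  stopifnot(inherits(system, "ilx_system"))
  .check_number(c_aq, "c_aq", lower = 0)
  (system$q - c_aq * system$v_aq) / system$v_il
}

#' Kinetic time course
#'
#' Pairs of sampling time (min, nondecreasing) and aqueous-phase
#' concentration (mg/mL, nonnegative).
#'
#' @param times Sampling times in min.
#' @param c_aq Aqueous concentrations in mg/mL, same length.
#' @return An object of class `ilx_kinetic_trace`.
#' @export
kinetic_trace <- function(times, c_aq) {
  .check_number(times, "times", lower = 0)
  .check_number(c_aq, "c_aq", lower = 0)
  if (length(times) != length(c_aq)) {
    .stop_validation("times and c_aq must have equal length")
  }
  if (length(times) > 1 && any(diff(times) < 0)) {
    .stop_validation("times must be nondecreasing")
  }
  structure(list(times = as.numeric(times), c_aq = as.numeric(c_aq)),
            class = "ilx_kinetic_trace")
}

#' @rdname kinetic_trace
#' @param path Path to a CSV file with header `time_min,c_aq_mg_per_ml`.
#' @export
read_kinetic_trace <- function(path) {
  df <- .read_numeric_csv(path, c("time_min", "c_aq_mg_per_ml"))
  kinetic_trace(df$time_min, df$c_aq_mg_per_ml)
}

#' @rdname kinetic_trace
#' @param trace A kinetic trace object.
#' @export
write_kinetic_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ilx_kinetic_trace"))
  .write_csv_full(data.frame(time_min = trace$times,
                             c_aq_mg_per_ml = trace$c_aq), path)
}

#' Simulate a noisy kinetic time course
#'
#' Evaluates the closed-form solution at `times` and adds zero-mean Gaussian
#' measurement noise, truncated at zero (concentrations cannot be negative).
#' Fully reproducible under a fixed `seed`.
#'
#' @param model An [kinetic_model()].
#' @param times Sampling times in min (nonempty).
#' @param noise_sd Noise standard deviation in mg/mL (>= 0).
#' @param seed Optional integer seed.
#' @return An [kinetic_trace()].
#' @export
simulate_trace <- function(model, times, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "ilx_kinetic_model"))
  if (length(times) == 0) .stop_validation("times must be nonempty")
  .check_number(noise_sd, "noise_sd", lower = 0)
  mu <- caq_closed_form(model, times)
  obs <- .with_seed(seed, mu + rnorm(length(mu), sd = noise_sd))
  kinetic_trace(times, pmax(obs, 0))
}

#' Fit the reversible kinetic model to a time course
#'
#' Unweighted least squares on the closed-form solution, with `k1, k2`
#' constrained nonnegative (bounded quasi-Newton optimisation). Starting
#' values come from a heuristic (plateau and log-linear relaxation-rate
#' estimates) plus a small log-spaced multi-start grid to avoid local minima.
#' Standard errors are Gauss-Newton approximations from the Jacobian at the
#' optimum; a flat (information-free) direction yields `Inf`.
#'
#' @param trace An [kinetic_trace()] with at least 3 distinct time points.
#' @param system The [extraction_system()] the trace was measured on.
#' @param init Optional starting values `c(k1, k2)`; when supplied, the grid
#'   multi-start is skipped.
#' @return An object of class `ilx_kinetic_fit`: list with `model`
#'   (fitted [kinetic_model()]), `rss`, `se` (named vector for k1, k2),
#'   `converged`, `n`.
#' @export
fit_kinetics <- function(trace, system, init = NULL) {
  stopifnot(inherits(trace, "ilx_kinetic_trace"), inherits(system, "ilx_system"))
  if (length(unique(trace$times)) < 3) {
    .stop_validation("need at least 3 distinct time points to fit (k1, k2)")
  }
  tt <- trace$times
  yy <- trace$c_aq
  ratio <- system$v_aq / system$v_il
  c0 <- system$q / system$v_aq

  predict_c <- function(k) {
    a <- k[1] + k[2] * ratio
    cinf <- if (a > 0) (k[2] * system$q / system$v_il) / a else mean(yy)
    cinf + (c0 - cinf) * exp(-a * tt)
  }
  rss_fun <- function(k) sum((yy - predict_c(k))^2)

  starts <- list()
  if (!is.null(init)) {
    .check_number(init, "init", lower = 0)
    if (length(init) != 2) .stop_validation("init must be c(k1, k2)")
    starts[[1]] <- init
  } else {
    # plateau estimate from the tail, relaxation rate from a log-linear fit
    n <- length(tt)
    cinf_hat <- mean(yy[tt >= max(tt) * 0.75])
    resid0 <- yy - cinf_hat
    ok <- resid0 > 1e-12 * max(c0, 1)
    a_hat <- if (sum(ok) >= 2) {
      fit <- lm(log(resid0[ok]) ~ tt[ok])
      max(-coef(fit)[2], 1e-3)
    } else 0.5
    k2_hat <- max(cinf_hat * a_hat * system$v_il / system$q, 0)
    k1_hat <- max(a_hat - k2_hat * ratio, 1e-6)
    starts[[1]] <- c(k1_hat, k2_hat)
    for (k1g in 10^seq(-2, 1, length.out = 3)) {
      for (k2g in 10^seq(-4, 0, length.out = 3)) {
        starts[[length(starts) + 1]] <- c(k1g, k2g)
      }
    }
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(pmax(s, 0), rss_fun, method = "L-BFGS-B",
            lower = c(0, 0), upper = c(Inf, Inf),
            control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) .stop_validation("kinetic fit failed from all starts")
  # polish the winning start to machine precision (simplex is insensitive to
  # the poor gradient scaling near rss ~ 0; negativity handled by penalty)
  rss_pen <- function(k) if (any(k < 0)) Inf else rss_fun(k)
  for (rep in 1:2) {
    polish <- tryCatch(
      optim(best$par, rss_pen, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) {
      polish$convergence <- min(polish$convergence, best$convergence)
      best <- polish
    }
  }

  k_hat <- best$par
  # Gauss-Newton covariance: sigma^2 (J'J)^{-1} with numeric Jacobian
  eps <- pmax(abs(k_hat), 1e-4) * 1e-6
  jac <- vapply(1:2, function(j) {
    kp <- k_hat; kp[j] <- kp[j] + eps[j]
    km <- k_hat; km[j] <- max(km[j] - eps[j], 0)
    (predict_c(kp) - predict_c(km)) / (kp[j] - km[j])
  }, numeric(length(tt)))
  dof <- max(length(tt) - 2L, 1L)
  sigma2 <- best$value / dof
  se <- tryCatch({
    covm <- sigma2 * solve(crossprod(jac))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) c(Inf, Inf))
  if (anyNA(se)) se <- c(Inf, Inf)

  structure(list(
    model = kinetic_model(k_hat[1], k_hat[2], system),
    rss = best$value,
    se = setNames(se, c("k1", "k2")),
    converged = best$convergence == 0,
    n = length(tt)
  ), class = "ilx_kinetic_fit")
}

#' @export
print.ilx_kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "Reversible first-order extraction fit (n = %d)\n  k1 = %.6g +/- %.3g 1/min\n  k2 = %.6g +/- %.3g 1/min\n  RSS = %.6g, converged: %s\n",
    x$n, x$model$k1, x$se["k1"], x$model$k2, x$se["k2"], x$rss, x$converged))
  invisible(x)
}

#' Time to reach a given fraction of equilibrium
#'
#' Smallest `t` with `|C_aq(t) - Cinf| <= (1 - fraction) |C0 - Cinf|`; for
#' the exponential relaxation this is the closed form
#' `t = -log(1 - fraction) / a`. With the default 0.99 this is the practical
#' shaking time needed before the aqueous phase stops changing.
#'
#' @param model An [kinetic_model()].
#' @param fraction Fraction of the approach to equilibrium, in (0, 1).
#' @return Time in min.
#' @export
equilibration_time <- function(model, fraction = 0.99) {
  stopifnot(inherits(model, "ilx_kinetic_model"))
  .check_number(fraction, "fraction", lower = 0, upper = 1,
                strict_lower = TRUE)
  if (fraction >= 1) .stop_validation("fraction must be < 1")
  kc <- .kinetic_constants(model)
  if (kc$a <= 0) .stop_validation("degenerate kinetic model: relaxation rate is 0")
  -log(1 - fraction) / kc$a
}

#' Equilibrium separation ratio implied by the kinetic model
#'
#' At infinite time the model relaxes to `k1 * C_aq = k2 * C_IL`, i.e. a
#' constant concentration ratio `S = C_IL / C_aq = k1 / k2` — the linear
#' partition regime. This links the kinetic and equilibrium descriptions of
#' the same system.
#'
#' @param model An [kinetic_model()] with `k2 > 0`.
#' @return The unitless separation ratio `k1 / k2`.
#' @export
kinetic_separation_ratio <- function(model) {
  stopifnot(inherits(model, "ilx_kinetic_model"))
  if (model$k2 <= 0) .stop_validation("k2 must be > 0 for a finite separation ratio")
  model$k1 / model$k2
}
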