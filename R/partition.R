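#' Equilibrium isotherm
#'
#' Paired equilibrium concentrations of the solute in the aqueous and
#' ionic-liquid phases, one pair per experiment.
#'
#' @param c_aq Aqueous-phase equilibrium concentrations, mg/mL (>= 0).
#' @param c_il Ionic-liquid-phase equilibrium concentrations, mg/mL (>= 0).
#' @param metadata Free-text description of the system.
#' @return An object of class `ilx_isotherm`.
#' @export
isotherm <- function(c_aq, c_il, metadata = "") {
  .check_number(c_aq, "c_aq", lower = 0)
  .check_number(c_il, "c_il", lower = 0)
  if (length(c_aq) != length(c_il)) {
    .stop_validation("c_aq and c_il must have equal length")
  }
  if (length(c_aq) < 1) .stop_validation("isotherm needs at least one pair")
  structure(list(c_aq = as.numeric(c_aq), c_il = as.numeric(c_il),
                 metadata = as.character(metadata)[1]),
            class = "ilx_isotherm")
}

#' @rdname isotherm
#' @param path Path to a CSV file with header `c_aq_mg_per_ml,c_il_mg_per_ml`.
#' @export
read_isotherm <- function(path) {
  df <- .read_numeric_csv(path, c("c_aq_mg_per_ml", "c_il_mg_per_ml"))
  isotherm(df$c_aq_mg_per_ml, df$c_il_mg_per_ml, metadata = basename(path))
}

#' @rdname isotherm
#' @param iso An isotherm object.
#' @export
write_isotherm <- function(iso, path) {
  stopifnot(inherits(iso, "ilx_isotherm"))
  .write_csv_full(data.frame(c_aq_mg_per_ml = iso$c_aq,
                             c_il_mg_per_ml = iso$c_il), path)
}

#' Equilibrium partition model
#'
#' Two regimes of solute partitioning between serum and ionic liquid:
#' * `linear` — constant separation ratio, `C_IL = S0 * C_aq`, valid at low
#'   solute concentration;
#' * `hyperbolic` — an empirical saturation of the ionic-liquid phase,
#'   `S(C_aq) = S0 / (1 + C_aq / K)`, so `C_IL = S0 C_aq / (1 + C_aq/K)`
#'   rises toward the asymptote `S0 * K` as the aqueous concentration grows.
#'
#' The hyperbolic form is the simplest hyperbola in the separation factor
#' consistent with a decreasing ratio and a solubility-limited ionic-liquid
#' phase; it is isolated behind this interface so alternative saturation
#' laws can be added.
#'
#' @param kind `"linear"` or `"hyperbolic"`.
#' @param s0 Limiting (low-concentration) separation ratio, unitless (> 0).
#' @param k Half-saturation constant in mg/mL (> 0); hyperbolic only.
#' @return An object of class `ilx_partition_model`.
#' @examples
#' m <- partition_model("hyperbolic", s0 = 90, k = 0.1)
#' separation_ratio(m, c(0, 0.1, 1))
#' @export
partition_model <- function(kind = c("linear", "hyperbolic"), s0, k = NULL) {
  kind <- match.arg(kind)
  .check_number(s0, "s0", lower = 0, strict_lower = TRUE)
  if (kind == "hyperbolic") {
    if (is.null(k)) .stop_validation("hyperbolic model needs k")
    .check_number(k, "k", lower = 0, strict_lower = TRUE)
  } else {
    k <- NULL
  }
  structure(list(kind = kind, s0 = s0, k = k), class = "ilx_partition_model")
}

#' @export
print.ilx_partition_model <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("Linear partition model: S0 = %.6g\n", x$s0))
  } else {
    cat(sprintf(
      "Hyperbolic partition model: S0 = %.6g, K = %.6g mg/mL (C_IL asymptote %.6g mg/mL)\n",
      x$s0, x$k, x$s0 * x$k))
  }
  invisible(x)
}

#' Concentration-dependent separation ratio
#'
#' `S(C_aq) = C_IL / C_aq` under the model: the constant `S0` for the linear
#' model, and `S0 / (1 + C_aq / K)` (strictly decreasing) for the hyperbolic
#' saturation model.
#'
#' @param model An [partition_model()].
#' @param c_aq Aqueous concentration(s), mg/mL (>= 0). Vectorized.
#' @return Unitless separation ratio(s).
#' @export
separation_ratio <- function(model, c_aq) {
  stopifnot(inherits(model, "ilx_partition_model"))
  .check_number(c_aq, "c_aq", lower = 0)
  if (model$kind == "linear") rep(model$s0, length(c_aq))
  else model$s0 / (1 + c_aq / model$k)
}

#' Ionic-liquid concentration from aqueous concentration
#'
#' `C_IL = S(C_aq) * C_aq`; saturates at `S0 * K` for the hyperbolic model.
#'
#' @inheritParams separation_ratio
#' @return Ionic-liquid concentration(s), mg/mL.
#' @export
c_il_from_c_aq <- function(model, c_aq) {
  separation_ratio(model, c_aq) * c_aq
}

#' Predict equilibrium depletion for a system
#'
#' Solves the mass balance `q = C_aq V_aq + C_IL(C_aq) V_IL` for the
#' equilibrium aqueous concentration. The linear model has the closed form
#' `C_aq = q / (V_aq + S0 V_IL)`; the hyperbolic model reduces to a quadratic
#' with a unique nonnegative root. Efficiency is the removed fraction,
#' `100 (1 - C_aq V_aq / q)`.
#'
#' @param model An [partition_model()].
#' @param system An [extraction_system()].
#' @return List with `c_aq_eq`, `c_il_eq` (mg/mL) and `efficiency_percent`.
#' @examples
#' sys <- extraction_system(v_aq = 3, q = 0.375, il_mass = 0.7)
#' predict_depletion(partition_model("hyperbolic", s0 = 90, k = 0.1), sys)
#' @export
predict_depletion <- function(model, system) {
  stopifnot(inherits(model, "ilx_partition_model"),
            inherits(system, "ilx_system"))
  q <- system$q; va <- system$v_aq; vi <- system$v_il
  if (q == 0) {
    return(list(c_aq_eq = 0, c_il_eq = 0, efficiency_percent = 0))
  }
  if (model$kind == "linear") {
    c_aq <- q / (va + model$s0 * vi)
  } else {
    # (va/K) C^2 + (va + S0 vi - q/K) C - q = 0, positive root
    A <- va / model$k
    B <- va + model$s0 * vi - q / model$k
    C <- -q
    disc <- B^2 - 4 * A * C
    if (disc < 0) stop("internal error: negative discriminant in mass balance")
    c_aq <- (-B + sqrt(disc)) / (2 * A)
  }
  if (c_aq < 0 || c_aq > q / va + 1e-12) {
    stop("internal error: mass-balance root outside [0, q/V_aq]")
  }
  c_il <- (q - c_aq * va) / vi
  list(c_aq_eq = c_aq, c_il_eq = c_il,
       efficiency_percent = 100 * (1 - c_aq * va / q))
}

#' Fit a partition model to isotherm data
#'
#' Least squares of `C_IL` on `C_aq` (fitting the concentrations rather than
#' their ratio avoids amplifying noise at small `C_aq`). The linear model is
#' a regression through the origin; the hyperbolic model is fitted by
#' Levenberg-Marquardt with positivity bounds. With `kind = "auto"` the
#' hyperbolic model is selected when it lowers the residual sum of squares by
#' more than `improvement` (default 20%) relative to the linear fit,
#' mirroring a two-regime treatment in which saturation is only invoked when
#' the data demand it.
#'
#' @param iso An [isotherm()]; hyperbolic fitting needs >= 2 distinct `c_aq`.
#' @param kind `"auto"`, `"linear"` or `"hyperbolic"`.
#' @param improvement Fractional RSS improvement required to prefer the
#'   hyperbolic model under `"auto"` (default 0.2).
#' @return A fitted [partition_model()] with attributes `rss` and (for
#'   `"auto"`) `rss_linear`, `rss_hyperbolic`.
#' @export
fit_partition <- function(iso, kind = c("auto", "linear", "hyperbolic"),
                          improvement = 0.2) {
  stopifnot(inherits(iso, "ilx_isotherm"))
  kind <- match.arg(kind)
  .check_number(improvement, "improvement", lower = 0)
  x <- iso$c_aq; y <- iso$c_il

  fit_linear <- function() {
    if (sum(x^2) == 0) .stop_validation("all c_aq are zero: cannot fit slope")
    s0 <- sum(x * y) / sum(x^2)
    if (s0 <= 0) .stop_validation("fitted separation ratio is not positive")
    m <- partition_model("linear", s0 = s0)
    attr(m, "rss") <- sum((y - s0 * x)^2)
    m
  }
  fit_hyperbolic <- function() {
    if (length(unique(x)) < 2) {
      .stop_validation("hyperbolic fit needs >= 2 distinct c_aq values")
    }
    # initial slope ~ S0 from the lower half; plateau ~ S0*K from the top
    ord <- order(x)
    lo <- ord[seq_len(max(2, floor(length(x) / 2)))]
    s0_init <- max(sum(x[lo] * y[lo]) / sum(x[lo]^2), 1e-6)
    k_init <- max(max(y) / s0_init, min(x[x > 0], na.rm = TRUE), 1e-6)
    df <- data.frame(x = x, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ s0 * x / (1 + x / k), data = df,
        start = list(s0 = s0_init, k = k_init),
        lower = c(1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) .stop_validation("hyperbolic fit failed: ",
                                           conditionMessage(e)))
    cf <- coef(fit)
    m <- partition_model("hyperbolic", s0 = cf[["s0"]], k = cf[["k"]])
    attr(m, "rss") <- sum((y - c_il_from_c_aq(m, x))^2)
    m
  }

  if (kind == "linear") return(fit_linear())
  if (kind == "hyperbolic") return(fit_hyperbolic())
  ml <- fit_linear()
  mh <- tryCatch(fit_hyperbolic(), error = function(e) NULL)
  out <- if (!is.null(mh) &&
             attr(mh, "rss") < (1 - improvement) * attr(ml, "rss")) mh else ml
  attr(out, "rss_linear") <- attr(ml, "rss")
  attr(out, "rss_hyperbolic") <- if (is.null(mh)) NA_real_ else attr(mh, "rss")
  out
}
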