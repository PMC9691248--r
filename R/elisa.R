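#' Four-parameter logistic (4PL) competitive dose-response
#'
#' Absorbance as a function of analyte concentration in a competitive
#' immunoassay: signal is maximal (`a_top`) at zero analyte and decreases
#' sigmoidally toward `a_bottom`,
#' \deqn{A(c) = A_{bot} + \frac{A_{top} - A_{bot}}{1 + (c/IC_{50})^h}.}
#' `IC50` is the concentration at the curve midpoint and `h` the slope.
#' `c = 0` maps exactly to `a_top`, which is why the zero standard anchors
#' the top plateau.
#'
#' @param c Concentration(s), ng/mL (>= 0). Vectorized.
#' @param a_top,a_bottom Upper/lower absorbance plateaus, `a_top > a_bottom >= 0`.
#' @param ic50 Midpoint concentration, ng/mL (> 0).
#' @param h Slope parameter (> 0).
#' @return Absorbance(s).
#' @export
fourpl_absorbance <- function(c, a_top, a_bottom, ic50, h) {
  .check_number(c, "c", lower = 0)
  a_bottom + (a_top - a_bottom) / (1 + (c / ic50)^h)
}

#' Competitive-ELISA calibration curve
#'
#' A fitted 4PL dose-response plus the standards used for the fit.
#'
#' @param a_top,a_bottom,ic50,h 4PL parameters (see [fourpl_absorbance()]).
#' @param standards Data frame with columns `concentration` (ng/mL) and
#'   `absorbance`; must span at least 3 distinct nonzero concentrations.
#' @param converged Logical convergence flag from the fit.
#' @return An object of class `ilx_calibration`.
#' @export
calibration_curve <- function(a_top, a_bottom, ic50, h,
                              standards = NULL, converged = TRUE) {
  .check_number(a_bottom, "a_bottom", lower = 0)
  .check_number(a_top, "a_top", lower = a_bottom, strict_lower = TRUE)
  .check_number(ic50, "ic50", lower = 0, strict_lower = TRUE)
  .check_number(h, "h", lower = 0, strict_lower = TRUE)
  if (!is.null(standards)) {
    stopifnot(is.data.frame(standards),
              all(c("concentration", "absorbance") %in% names(standards)))
    nz <- unique(standards$concentration[standards$concentration > 0])
    if (length(nz) < 3) {
      .stop_validation("standards must span >= 3 distinct nonzero concentrations")
    }
  }
  structure(list(a_top = a_top, a_bottom = a_bottom, ic50 = ic50, h = h,
                 standards = standards, converged = converged),
            class = "ilx_calibration")
}

#' @export
print.ilx_calibration <- function(x, ...) {
  cat(sprintf(
    "4PL calibration: A_top = %.4g, A_bottom = %.4g, IC50 = %.6g ng/mL, slope = %.4g (converged: %s)\n",
    x$a_top, x$a_bottom, x$ic50, x$h, x$converged))
  invisible(x)
}

#' Fit a 4PL calibration curve to standards
#'
#' Levenberg-Marquardt least squares of absorbance on nominal concentration,
#' with the 1/Y^2 weighting that is standard for immunoassay calibration
#' (absorbance error scales with the signal). Standards must be overall
#' decreasing (competitive format); constant or increasing absorbances fail
#' validation. Non-convergence is flagged on the returned curve, never
#' silent.
#'
#' @param standards Data frame with columns `concentration` (ng/mL, >= 0) and
#'   `absorbance`; at least 4 points, typically including a zero standard
#'   that anchors the top plateau.
#' @return An [calibration_curve()].
#' @examples
#' conc <- c(0, 5, 10, 25, 50, 100)
#' abs_ <- fourpl_absorbance(conc, 1.0, 0.1, 25, 1.0)
#' fit_calibration(data.frame(concentration = conc, absorbance = abs_))
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "absorbance") %in% names(standards)))
  cc <- standards$concentration
  aa <- standards$absorbance
  .check_number(cc, "concentration", lower = 0)
  .check_number(aa, "absorbance")
  if (length(cc) < 4) .stop_validation("need >= 4 standards for a 4PL fit")
  if (diff(range(aa)) < 1e-12 * max(abs(aa), 1)) {
    .stop_validation("standards have constant absorbance: nothing to calibrate")
  }
  agg <- tapply(aa, cc, mean)
  trend <- suppressWarnings(
    stats::cor(as.numeric(names(agg)), as.numeric(agg), method = "spearman"))
  if (!is.na(trend) && trend > 0) {
    .stop_validation("absorbance increases with concentration: ",
                     "not a competitive dose-response")
  }

  a_top0 <- max(aa)
  a_bot0 <- max(min(aa) * 0.9, 0)
  mid <- (a_top0 + a_bot0) / 2
  pos <- cc > 0
  ic50_0 <- if (any(pos)) {
    below <- which(pos & aa <= mid)
    if (length(below)) min(cc[below]) else median(cc[pos])
  } else median(cc)
  df <- data.frame(c = cc, a = aa, w = 1 / pmax(aa, 1e-6)^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ a_bottom + (a_top - a_bottom) / (1 + (c / ic50)^h), data = df,
      weights = df$w,
      start = list(a_top = a_top0, a_bottom = a_bot0,
                   ic50 = max(ic50_0, 1e-3), h = 1),
      lower = c(1e-12, 0, 1e-9, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) .stop_validation("4PL fit failed: ",
                                         conditionMessage(e)))
  cf <- as.list(coef(fit))
  converged <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)
  if (cf$a_top <= cf$a_bottom) .stop_validation("degenerate 4PL fit: A_top <= A_bottom")
  calibration_curve(cf$a_top, cf$a_bottom, cf$ic50, cf$h,
                    standards = data.frame(concentration = cc, absorbance = aa),
                    converged = converged)
}

#' Back-calculate concentration from absorbance
#'
#' Analytic inverse of the 4PL,
#' \deqn{c = IC_{50}\left(\frac{A_{top} - A}{A - A_{bot}}\right)^{1/h},}
#' defined for absorbances strictly between the plateaus. An absorbance at or
#' beyond a plateau means the sample is outside the quantifiable range and
#' raises an error naming the violated bound.
#'
#' @param curve An [calibration_curve()].
#' @param a Absorbance(s), each in `(a_bottom, a_top)`. Vectorized.
#' @return Concentration(s) in ng/mL.
#' @export
invert_calibration <- function(curve, a) {
  stopifnot(inherits(curve, "ilx_calibration"))
  .check_number(a, "absorbance")
  if (any(a >= curve$a_top)) {
    .stop_validation(sprintf(
      "absorbance %.6g at or above the top plateau A_top = %.6g: below-range sample",
      max(a), curve$a_top))
  }
  if (any(a <= curve$a_bottom)) {
    .stop_validation(sprintf(
      "absorbance %.6g at or below the bottom plateau A_bottom = %.6g: above-range sample",
      min(a), curve$a_bottom))
  }
  curve$ic50 * ((curve$a_top - a) / (a - curve$a_bottom))^(1 / curve$h)
}

#' Replicate set of back-calculated determinations
#'
#' Replicate concentrations (and optionally the raw absorbances) measured for
#' one condition, e.g. one hemoglobin level before or after extraction, at a
#' known nominal spike.
#'
#' @param concentrations Back-calculated concentrations, ng/mL (>= 0, n >= 2).
#' @param nominal Nominal (spiked) concentration, ng/mL (> 0).
#' @param condition Free-text condition label.
#' @param absorbances Optional raw absorbances, same length.
#' @return An object of class `ilx_replicates`.
#' @export
replicate_set <- function(concentrations, nominal, condition = "",
                          absorbances = NULL) {
  .check_number(concentrations, "concentrations", lower = 0)
  if (length(concentrations) < 2) {
    .stop_validation("need >= 2 replicates for an SD")
  }
  .check_number(nominal, "nominal", lower = 0, strict_lower = TRUE)
  if (!is.null(absorbances)) {
    .check_number(absorbances, "absorbances")
    if (length(absorbances) != length(concentrations)) {
      .stop_validation("absorbances and concentrations must have equal length")
    }
  }
  structure(list(concentrations = as.numeric(concentrations),
                 nominal = nominal, condition = as.character(condition)[1],
                 absorbances = absorbances),
            class = "ilx_replicates")
}

#' Accuracy and precision statistics for a replicate set
#'
#' Mean, sample standard deviation (n-1 denominator), coefficient of
#' variation `CV% = 100 sd/mean` (precision) and signed relative error
#' `RE% = 100 (mean - nominal)/nominal` (accuracy).
#'
#' @param reps An [replicate_set()].
#' @return An object of class `ilx_accuracy_report`: list with `mean`, `sd`,
#'   `cv_percent`, `relative_error_percent` (signed), `n`, `nominal`,
#'   `condition`.
#' @examples
#' replicate_stats(replicate_set(c(21.904, 19.950, 22.971), nominal = 20))
#' @export
replicate_stats <- function(reps) {
  stopifnot(inherits(reps, "ilx_replicates"))
  x <- reps$concentrations
  m <- mean(x)
  s <- sd(x)
  structure(list(
    mean = m, sd = s,
    cv_percent = 100 * s / m,
    relative_error_percent = 100 * (m - reps$nominal) / reps$nominal,
    n = length(x), nominal = reps$nominal, condition = reps$condition
  ), class = "ilx_accuracy_report")
}

#' @export
print.ilx_accuracy_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "%s (n = %d, nominal %.6g ng/mL)\n  mean %.3f  sd %.3f  CV%% %.3f  RE%% %+.2f (|RE%%| %.2f)\n",
    if (nzchar(x$condition)) x$condition else "replicate set",
    x$n, x$nominal,
    round_half_up(x$mean, 3), round_half_up(x$sd, 3),
    round_half_up(x$cv_percent, 3),
    round_half_up(x$relative_error_percent, 2),
    round_half_up(abs(x$relative_error_percent), 2)))
  invisible(x)
}

#' Before/after extraction accuracy comparison
#'
#' Compares accuracy reports for the same nominal concentration measured
#' before and after heme/hemoglobin depletion. Reports both signed relative
#' errors, their signed difference (`before - after`, the "improvement by"
#' figure), the change in absolute relative error, and whether precision
#' (CV%) also improved.
#'
#' @param before,after [replicate_stats()] reports at the same nominal.
#' @return List with `re_before`, `re_after` (signed %), `decrease_points`
#'   (`re_before - re_after`), `abs_re_change_points`
#'   (`|re_before| - |re_after|`), `cv_before`, `cv_after`, `cv_improved`.
#' @export
accuracy_comparison <- function(before, after) {
  stopifnot(inherits(before, "ilx_accuracy_report"),
            inherits(after, "ilx_accuracy_report"))
  if (!isTRUE(all.equal(before$nominal, after$nominal))) {
    .stop_validation("reports have different nominal concentrations")
  }
  list(
    nominal = before$nominal,
    re_before = before$relative_error_percent,
    re_after = after$relative_error_percent,
    decrease_points = before$relative_error_percent - after$relative_error_percent,
    abs_re_change_points = abs(before$relative_error_percent) -
      abs(after$relative_error_percent),
    cv_before = before$cv_percent,
    cv_after = after$cv_percent,
    cv_improved = after$cv_percent < before$cv_percent
  )
}

#' Read an ELISA plate table
#'
#' CSV with header `well,role,nominal_ng_per_ml,absorbance`, role one of
#' `standard`, `sample`, `blank`. For standards, `nominal_ng_per_ml` is the
#' standard concentration; for samples it is the spiked (expected)
#' concentration.
#'
#' @param path Path to the plate CSV.
#' @return Data frame with the four columns, roles validated.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) .stop_parse("file not found: ", path)
  df <- tryCatch(read.csv(path, colClasses = "character", check.names = FALSE),
                 error = function(e) .stop_parse("cannot read ", path, ": ",
                                                 conditionMessage(e)))
  need <- c("well", "role", "nominal_ng_per_ml", "absorbance")
  if (!identical(names(df), need)) {
    .stop_parse(path, ": expected header '", paste(need, collapse = ","), "'")
  }
  bad_role <- which(!df$role %in% c("standard", "sample", "blank"))
  if (length(bad_role)) {
    .stop_parse(path, ": invalid role '", df$role[bad_role[1]], "' at line ",
                bad_role[1] + 1L)
  }
  for (col in c("nominal_ng_per_ml", "absorbance")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(df[[col]]))
    if (length(bad)) {
      .stop_parse(path, ": malformed value '", df[[col]][bad[1]],
                  "' in column ", col, " at line ", bad[1] + 1L)
    }
    df[[col]] <- vals
  }
  df
}

#' Quantify the samples on a plate
#'
#' Fits the 4PL calibration to the `standard` rows and back-calculates every
#' `sample` row, returning per-condition accuracy reports.
#'
#' @param plate Data frame as returned by [read_plate()].
#' @return List with `curve` (the fitted [calibration_curve()]) and `reports`
#'   (one [replicate_stats()] report per distinct sample nominal).
#' @export
quantify_plate <- function(plate) {
  std <- plate[plate$role == "standard", , drop = FALSE]
  smp <- plate[plate$role == "sample", , drop = FALSE]
  if (nrow(std) < 4) .stop_validation("plate has fewer than 4 standards")
  if (nrow(smp) < 1) .stop_validation("plate has no sample wells")
  curve <- fit_calibration(data.frame(concentration = std$nominal_ng_per_ml,
                                      absorbance = std$absorbance))
  reports <- lapply(split(smp, smp$nominal_ng_per_ml), function(g) {
    conc <- invert_calibration(curve, g$absorbance)
    replicate_stats(replicate_set(conc, nominal = g$nominal_ng_per_ml[1],
                                  condition = paste0("nominal ",
                                                     g$nominal_ng_per_ml[1],
                                                     " ng/mL"),
                                  absorbances = g$absorbance))
  })
  list(curve = curve, reports = reports)
}

#' Reference replicate panel: cotinine in hemolysed serum
#'
#' Triplicate competitive-ELISA determinations of cotinine (nominal
#' 20 ng/mL, the smoker/non-smoker decision level) in serum spiked with
#' hemoglobin at 0, 0.05, 0.1 and 0.2 mg/mL, measured before and after
#' depleting the heme/hemoglobin by ionic-liquid extraction. Concentrations
#' are back-calculated from the kit's calibration curve; raw well
#' absorbances (450 nm) are included. The hemoglobin-free condition was only
#' measured without extraction.
#'
#' @return Data frame with columns `hb_mg_per_ml`, `extracted` (logical),
#'   `replicate`, `absorbance`, `concentration_ng_per_ml` and
#'   `nominal_ng_per_ml`.
#' @examples
#' panel <- cotinine_replicates()
#' sub <- panel[panel$hb_mg_per_ml == 0.2 & !panel$extracted, ]
#' replicate_stats(replicate_set(sub$concentration_ng_per_ml, nominal = 20))
#' @export
cotinine_replicates <- function() {
  before <- data.frame(
    hb_mg_per_ml = rep(c(0, 0.05, 0.1, 0.2), each = 3),
    extracted = FALSE,
    replicate = rep(1:3, 4),
    absorbance = c(0.562, 0.652, 0.517,
                   0.560, 0.519, 0.445,
                   0.465, 0.521, 0.580,
                   0.345, 0.442, 0.396),
    concentration_ng_per_ml = c(21.904, 19.950, 22.971,
                                21.955, 22.917, 24.867,
                                24.314, 22.891, 21.496,
                                28.042, 24.953, 26.314)
  )
  after <- data.frame(
    hb_mg_per_ml = rep(c(0.05, 0.1, 0.2), each = 3),
    extracted = TRUE,
    replicate = rep(1:3, 3),
    absorbance = c(0.625, 0.546, 0.493,
                   0.830, 0.803, 0.759,
                   0.625, 0.642, 0.684),
    concentration_ng_per_ml = c(20.523, 22.288, 23.588,
                                16.464, 16.964, 17.793,
                                20.515, 20.145, 19.287)
  )
  out <- rbind(before, after)
  out$nominal_ng_per_ml <- 20
  out
}
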